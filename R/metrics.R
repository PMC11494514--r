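#' Connectance
#'
#' Proportion of realized links among all possible plant x pollinator links,
#' L / (P * A).
#'
#' @param M a `bipartite_matrix`.
#' @return Numeric fraction in (0, 1].
#' @export
connectance <- function(M) {
  stopifnot(inherits(M, "bipartite_matrix"))
  P <- length(M$plants); A <- length(M$pollinators)
  if (P < 1L || A < 1L || sum(M$cells) == 0L) {
    stop("connectance undefined for an empty matrix", call. = FALSE)
  }
  sum(M$cells) / (P * A)
}

#' Species connectivity (degree) table
#'
#' Connectivity s of a species is its number of interaction partners. The
#' plant-side mean equals L/P and the pollinator-side mean L/A.
#'
#' @param M a `bipartite_matrix`.
#' @return Data frame with columns `species`, `side`
#'   (`"plants"`/`"pollinators"`), `degree`.
#' @export
species_connectivity <- function(M) {
  stopifnot(inherits(M, "bipartite_matrix"))
  rbind(
    data.frame(species = M$plants, side = "plants",
               degree = as.integer(rowSums(M$cells)),
               stringsAsFactors = FALSE),
    data.frame(species = M$pollinators, side = "pollinators",
               degree = as.integer(colSums(M$cells)),
               stringsAsFactors = FALSE)
  )
}

#' Percentage of extreme specialists (one-link species)
#'
#' @param M a `bipartite_matrix`.
#' @param side which guild to assess; pollinators by default.
#' @return Percentage (0-100) of species on `side` with degree exactly 1.
#' @export
extreme_specialist_pct <- function(M, side = c("pollinators", "plants")) {
  side <- match.arg(side)
  deg <- if (side == "pollinators") colSums(M$cells) else rowSums(M$cells)
  100 * mean(deg == 1)
}

#' Freeman degree centralization of the bipartite graph
#'
#' The network is treated as a single graph over the N = P + A species;
#' centralization is sum_i (d_max - d_i) / ((N - 1)(N - 2)). A star network
#' (one hub linked to every other node, no other links) scores exactly 1;
#' a degree-regular network scores 0.
#'
#' @param M a `bipartite_matrix`.
#' @return Numeric in \[0, 1\].
#' @export
degree_centralization <- function(M) {
  stopifnot(inherits(M, "bipartite_matrix"))
  d <- c(rowSums(M$cells), colSums(M$cells))
  N <- length(d)
  if (N < 3L) stop("degree centralization needs at least 3 species",
                   call. = FALSE)
  sum(max(d) - d) / ((N - 1) * (N - 2))
}

#' NODF nestedness
#'
#' Nestedness based on overlap and decreasing fill. For every unordered
#' pair of rows (and of columns) whose marginal totals differ, the pair
#' contributes 100 * |overlap| / (smaller marginal total); equal totals
#' contribute 0 (strict decreasing-fill rule). NODF is the mean contribution
#' over all row pairs and column pairs, ranging 0 (no nesting) to 100
#' (perfect nesting).
#'
#' @param M a `bipartite_matrix` or a 0/1 matrix.
#' @return Numeric in \[0, 100\].
#' @export
nodf <- function(M) {
  A <- if (inherits(M, "bipartite_matrix")) M$cells else as.matrix(M)
  if (nrow(A) < 2L && ncol(A) < 2L) {
    stop("NODF undefined for a 1x1 matrix", call. = FALSE)
  }
  (sum(.nodf_pairs(A)) + sum(.nodf_pairs(t(A)))) /
    (choose(nrow(A), 2L) + choose(ncol(A), 2L))
}

# paired nestedness terms over rows of X; order-free formulation:
# pairs with unequal fill contribute 100 * overlap / min(fill), ties 0
.nodf_pairs <- function(X) {
  n <- nrow(X)
  if (n < 2L) return(0)
  ft <- rowSums(X)
  ov <- X %*% t(X)               # pairwise overlaps
  contrib <- matrix(0, n, n)
  mn <- outer(ft, ft, pmin)
  ok <- outer(ft, ft, "!=") & mn > 0
  contrib[ok] <- 100 * ov[ok] / mn[ok]
  contrib[upper.tri(contrib)]
}

#' Structural summary of a network
#'
#' @param M a `bipartite_matrix`.
#' @param specialist_side guild for the extreme-specialist percentage.
#' @return Object of class `metrics_report`: list with `name`, `P`, `A`,
#'   `L`, `connectance`, `S_P` (mean plant connectivity), `S_A` (mean
#'   pollinator connectivity), `pct_extreme_specialists`, `DC`, `NODF`.
#' @export
metrics_report <- function(M, specialist_side = "pollinators") {
  stopifnot(inherits(M, "bipartite_matrix"))
  P <- length(M$plants); A <- length(M$pollinators); L <- sum(M$cells)
  structure(list(
    name = M$name, P = P, A = A, L = L,
    connectance = connectance(M),
    S_P = L / P,
    S_A = L / A,
    pct_extreme_specialists = extreme_specialist_pct(M, specialist_side),
    DC = degree_centralization(M),
    NODF = nodf(M)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    paste0("network '%s': %d plants, %d pollinators, %d links\n",
           "  connectance %.3f | S_P %.2f | S_A %.2f | %%1-link %s %.2f\n",
           "  DC %.2f | NODF %.2f\n"),
    x$name, x$P, x$A, x$L, x$connectance, x$S_P, x$S_A,
    "pollinators", x$pct_extreme_specialists, x$DC, x$NODF))
  invisible(x)
}
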