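#' Sample a random contingency table with fixed margins
#'
#' Draws a nonnegative integer table with exactly the given row and column
#' totals from the multiple hypergeometric distribution (each admissible
#' table weighted by its token-pairing multiplicity): the F row tokens are
#' paired uniformly at random with the F column tokens and pairings are
#' tabulated. This is the same law as Patefield's algorithm
#' (`stats::r2dtable`).
#'
#' @param row_margins,col_margins nonnegative integer vectors with equal
#'   sums F > 0.
#' @param rng_seed optional integer seed; when `NULL` the current RNG
#'   stream is used.
#' @return Integer matrix with the requested margins.
#' @export
patefield_sample <- function(row_margins, col_margins, rng_seed = NULL) {
  row_margins <- as.integer(row_margins)
  col_margins <- as.integer(col_margins)
  stopifnot(all(row_margins >= 0L), all(col_margins >= 0L))
  F <- sum(row_margins)
  if (F != sum(col_margins) || F == 0L) {
    stop("row and column margins must have equal positive sums",
         call. = FALSE)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  nr <- length(row_margins); nc <- length(col_margins)
  rows <- rep.int(seq_len(nr), row_margins)
  cols <- rep.int(seq_len(nc), col_margins)[sample.int(F)]
  matrix(tabulate(rows + (cols - 1L) * nr, nbins = nr * nc), nr, nc)
}

#' Null-model test of a binary network statistic
#'
#' Standardizes an observed statistic against an ensemble of fixed-margin
#' random networks. Null margins are the observed binary degree sums; each
#' sampled integer table is binarized (cell > 0 becomes 1) before the
#' binary statistic is computed, so null networks conserve total
#' interaction tokens rather than binary degrees exactly. The empirical p
#' is one-sided with add-one correction,
#' p = (1 + #\{null >= observed\}) / (n_reps + 1), appropriate for NODF and
#' modularity, which exceed their null expectation in structured networks.
#'
#' @param M a `bipartite_matrix`.
#' @param statistic `"nodf"` or `"modularity"`, or any function of a 0/1
#'   matrix via `stat_fun`.
#' @param n_reps number of null draws (default 1000).
#' @param seed integer seed for the ensemble.
#' @param stat_fun optional function(matrix) -> numeric overriding
#'   `statistic`.
#' @param stat_args extra arguments passed to the statistic (e.g.
#'   `n_restarts` for modularity).
#' @return Object of class `null_ensemble`: list with `statistic`,
#'   `observed`, `n_reps`, `null` (vector), `z`, `p_emp`, `seed`,
#'   `degenerate` (TRUE when the null sd is 0 and z is undefined).
#' @export
null_test <- function(M, statistic = c("nodf", "modularity"),
                      n_reps = 1000L, seed = 1L, stat_fun = NULL,
                      stat_args = list()) {
  stopifnot(inherits(M, "bipartite_matrix"), n_reps >= 1L)
  if (is.null(stat_fun)) {
    statistic <- match.arg(statistic)
    stat_fun <- switch(statistic,
      nodf = function(A, ...) nodf(A),
      modularity = function(A, ...) {
        optimize_modules(A, seed = NULL, ...)$Q
      })
  } else {
    statistic <- if (is.character(statistic)) statistic[1L] else "custom"
  }
  rm <- as.integer(rowSums(M$cells))
  cm <- as.integer(colSums(M$cells))
  observed <- do.call(stat_fun, c(list(M$cells), stat_args))
  set.seed(seed)
  null <- vapply(seq_len(n_reps), function(i) {
    tab <- patefield_sample(rm, cm)
    stopifnot(identical(as.integer(rowSums(tab)), rm),
              identical(as.integer(colSums(tab)), cm))
    B <- (tab > 0L) + 0L
    dimnames(B) <- dimnames(M$cells)
    do.call(stat_fun, c(list(B), stat_args))
  }, numeric(1))
  sd_null <- stats::sd(null)
  degenerate <- !is.finite(sd_null) || sd_null == 0
  z <- if (degenerate) NA_real_ else (observed - mean(null)) / sd_null
  structure(list(statistic = statistic, observed = observed,
                 n_reps = n_reps, null = null, z = z,
                 p_emp = (1 + sum(null >= observed)) / (n_reps + 1),
                 seed = seed, degenerate = degenerate),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "null ensemble (%s, %d reps, seed %d): observed %.4f, null %.4f +/- %.4f, z = %s, p = %.4g%s\n",
    x$statistic, x$n_reps, x$seed, x$observed, mean(x$null),
    stats::sd(x$null), ifelse(x$degenerate, "undefined (sd 0)",
                              sprintf("%.2f", x$z)),
    x$p_emp, if (x$degenerate) " [degenerate null]" else ""))
  invisible(x)
}
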