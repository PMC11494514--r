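# Independent oracles and fixture builders shared across the suite.

# wrap a plain 0/1 matrix as a bipartite_matrix with a single layer
bmat <- function(A, name = "test", layer = "V_d") {
  if (is.null(rownames(A))) rownames(A) <- sprintf("p%02d", seq_len(nrow(A)))
  if (is.null(colnames(A))) colnames(A) <- sprintf("a%02d", seq_len(ncol(A)))
  idx <- which(A == 1, arr.ind = TRUE)
  links <- data.frame(plant = rownames(A)[idx[, 1]],
                      pollinator = colnames(A)[idx[, 2]],
                      layer = layer, stringsAsFactors = FALSE)
  pollinet:::new_bipartite_matrix(links, name)
}

# random 0/1 matrix with no empty rows or columns
rand_binary <- function(nr, nc, fill = 0.4) {
  repeat {
    A <- matrix(rbinom(nr * nc, 1, fill), nr, nc)
    if (all(rowSums(A) > 0) && all(colSums(A) > 0)) return(A)
  }
}

# NODF computed from the definition by explicit enumeration after sorting
# rows/columns by decreasing totals (independent of the packaged min-fill
# formulation)
nodf_oracle <- function(A) {
  A <- A[order(-rowSums(A)), order(-colSums(A)), drop = FALSE]
  pair_terms <- function(X) {
    n <- nrow(X)
    out <- numeric(0)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        fi <- sum(X[i, ]); fj <- sum(X[j, ])
        out <- c(out, if (fi > fj && fj > 0) {
          100 * sum(X[i, ] == 1 & X[j, ] == 1) / fj
        } else 0)
      }
    }
    out
  }
  (sum(pair_terms(A)) + sum(pair_terms(t(A)))) /
    (choose(nrow(A), 2) + choose(ncol(A), 2))
}

# all set partitions of n items as restricted growth strings
all_partitions <- function(n) {
  res <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      res[[length(res) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1)) {
      rec(c(prefix, lab), max(maxlab, lab))
    }
  }
  rec(1L, 1L)
  res
}

# global optimum of Barber modularity by exhaustive partition search
barber_optimum <- function(A) {
  S <- nrow(A) + ncol(A)
  best <- -Inf
  for (g in all_partitions(S)) {
    q <- barber_q(A, setNames(g, c(rownames(A), colnames(A))))
    if (q > best) best <- q
  }
  best
}

# normalized mutual information between two labelings
nmi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij); pj <- colSums(pij)
  I <- sum(ifelse(pij > 0, pij * log(pij / outer(pi, pj)), 0))
  Ha <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  Hb <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  I / sqrt(Ha * Hb)
}

# Monte-Carlo oracle for expected richness under subsampling without
# replacement
mc_rarefy <- function(x, m, reps = 10000) {
  pool <- rep(seq_along(x), x)
  draws <- replicate(reps, length(unique(sample(pool, m))))
  c(mean = mean(draws), se = sd(draws) / sqrt(reps))
}

# minimal valid visit-record data frame from (plant, pollinator) pairs
visits_of <- function(plant, pollinator, group = "hoverflies") {
  n <- length(plant)
  data.frame(census = rep_len(1:5, n),
             meadow = rep_len("meadow_1", n),
             plant = plant,
             specimen_id = sprintf("V%04d", seq_len(n)),
             pollinator = pollinator,
             group = rep_len(group, n), stringsAsFactors = FALSE)
}

# minimal pollen-record data frame
pollen_of <- function(specimen_id, pollinator, plant, grains,
                      period = "diurnal") {
  data.frame(specimen_id = specimen_id, pollinator = pollinator,
             period = period, plant = plant, grains = grains,
             stringsAsFactors = FALSE)
}
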