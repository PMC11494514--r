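#' Interaction abundance vector
#'
#' Treats each distinct (plant, pollinator) link as a "species" and each
#' sampling unit as an "individual": a visitation event, or a pollen-load
#' specimen evidencing the link with at least `min_grains` grains. Visit
#' and pollen data may be pooled; counts for the same link add up.
#'
#' @param visits optional visitation events ([as_visit_records()]).
#' @param pollen optional pollen records ([as_pollen_records()]);
#'   all periods present are used — filter beforehand for a single layer.
#' @param min_grains evidence threshold for pollen specimens (default 5).
#' @return Object of class `interaction_abundance`: list with `x` (named
#'   per-link unit counts), `n` (total units, `sum(x)`), `s_obs` (distinct
#'   links).
#' @export
interaction_abundances <- function(visits = NULL, pollen = NULL,
                                   min_grains = 5L) {
  counts <- integer(0)
  if (!is.null(visits)) {
    visits <- as_visit_records(visits)
    key <- paste(visits$plant, visits$pollinator, sep = " :: ")
    tab <- table(key)
    counts <- stats::setNames(as.integer(tab), names(tab))
  }
  if (!is.null(pollen)) {
    pollen <- as_pollen_records(pollen)
    agg <- stats::aggregate(grains ~ specimen_id + pollinator + plant,
                            data = pollen, FUN = sum)
    agg <- agg[agg$grains >= min_grains, , drop = FALSE]
    if (nrow(agg) > 0L) {
      key <- paste(agg$plant, agg$pollinator, sep = " :: ")
      tab <- table(key)
      for (k in names(tab)) {
        counts[k] <- (if (k %in% names(counts)) counts[k] else 0L) +
          as.integer(tab[[k]])
      }
    }
  }
  if (length(counts) == 0L) stop("no sampling records", call. = FALSE)
  structure(list(x = counts, n = sum(counts), s_obs = length(counts)),
            class = "interaction_abundance")
}

#' Expected interaction richness under subsampling (Hurlbert rarefaction)
#'
#' E\[S(m)\] = sum_i (1 - C(n - x_i, m) / C(n, m)), evaluated with
#' log-gamma arithmetic for numerical stability. No extrapolation: m must
#' not exceed n.
#'
#' @param ab an `interaction_abundance`.
#' @param m_grid sample sizes (default: ~25 sizes from 1 to n).
#' @return Object of class `rarefaction_curve`: data frame with columns
#'   `m`, `estimate` (and `lo`/`hi` when produced by [rarefy_ci()]).
#' @export
rarefy <- function(ab, m_grid = NULL) {
  stopifnot(inherits(ab, "interaction_abundance"))
  if (is.null(m_grid)) {
    m_grid <- unique(round(seq(1, ab$n, length.out = min(25L, ab$n))))
  }
  if (any(m_grid > ab$n)) {
    stop("rarefaction is interpolation only: m must not exceed n",
         call. = FALSE)
  }
  stopifnot(all(m_grid >= 1))
  est <- vapply(m_grid, function(m) .hurlbert(ab$x, ab$n, m), numeric(1))
  structure(data.frame(m = m_grid, estimate = est),
            class = c("rarefaction_curve", "data.frame"))
}

.hurlbert <- function(x, n, m) {
  # lchoose(a, m) = -Inf for a < m, so absent-term probability is exactly 0
  sum(1 - exp(lchoose(n - x, m) - lchoose(n, m)))
}

#' Rarefaction curve with bootstrap confidence band
#'
#' Point estimates from [rarefy()]; uncertainty from a multinomial
#' bootstrap of the record-to-link assignment (B resamples of the n units
#' with probabilities x/n). The 95% band is the 2.5/97.5 percentile of the
#' bootstrap deviations, centred on the point estimate so the band always
#' contains it (in particular at m = n, where E\[S(n)\] = S_obs).
#'
#' @param ab an `interaction_abundance`.
#' @param m_grid sample sizes (default as in [rarefy()]).
#' @param B bootstrap replicates (default 200, minimum 50).
#' @param seed RNG seed.
#' @return A `rarefaction_curve` data frame with columns `m`, `estimate`,
#'   `lo`, `hi` and attributes `B`, `seed`.
#' @export
rarefy_ci <- function(ab, m_grid = NULL, B = 200L, seed = 1L) {
  stopifnot(B >= 50L)
  pt <- rarefy(ab, m_grid)
  m_grid <- pt$m
  set.seed(seed)
  boots <- vapply(seq_len(B), function(b) {
    xb <- as.integer(stats::rmultinom(1L, ab$n, ab$x / ab$n))
    xb <- xb[xb > 0L]
    vapply(m_grid, function(m) .hurlbert(xb, ab$n, m), numeric(1))
  }, numeric(length(m_grid)))
  boots <- matrix(boots, nrow = length(m_grid))
  dev <- boots - rowMeans(boots)
  lo <- pt$estimate + apply(dev, 1L, stats::quantile, probs = 0.025)
  hi <- pt$estimate + apply(dev, 1L, stats::quantile, probs = 0.975)
  pt$lo <- pmin(lo, pt$estimate)
  pt$hi <- pmax(hi, pt$estimate)
  attr(pt, "B") <- B
  attr(pt, "seed") <- seed
  pt
}
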