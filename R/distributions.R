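#' Cumulative connectivity distribution
#'
#' For each observed degree k on one side of the network, the fraction of
#' species on that side with degree >= k.
#'
#' @param M a `bipartite_matrix`.
#' @param side `"pollinators"` or `"plants"`.
#' @return Object of class `degree_distribution`: list with `side`, `k`
#'   (sorted distinct degrees) and `p` (P(degree >= k), non-increasing,
#'   `p[1] == 1`).
#' @export
cumulative_distribution <- function(M, side = c("pollinators", "plants")) {
  side <- match.arg(side)
  deg <- if (side == "pollinators") colSums(M$cells) else rowSums(M$cells)
  if (length(deg) < 2L) {
    stop("cumulative distribution needs at least 2 species", call. = FALSE)
  }
  k <- sort(unique(deg))
  structure(list(side = side, k = as.numeric(k),
                 p = vapply(k, function(kk) mean(deg >= kk), numeric(1))),
            class = "degree_distribution")
}

#' Fit candidate models to a cumulative connectivity distribution
#'
#' Least-squares fits in log space of the three classical candidates for
#' pollination-web degree distributions:
#' exponential `log10 P = a - k / gamma`, power law
#' `log10 P = a - b log10 k`, and truncated power law
#' `log10 P = a - b log10 k - k / k_x` (linear in all parameters, so all
#' three are ordinary least squares). Models are compared by
#' `AIC = n log(RSS / n) + 2 p`; the truncated model nests the power law
#' (`k_x -> Inf`). The truncated fit is skipped (with a notice in the
#' result) when fewer than 4 distinct degrees are available.
#'
#' @param dist a `degree_distribution`.
#' @return Object of class `connectivity_fits`: data frame with one row per
#'   fitted model (`model`, `a`, `b`, `gamma`, `k_x`, `rss`, `aic`,
#'   `selected`) and attribute `skipped` naming any skipped model.
#' @export
fit_connectivity_models <- function(dist) {
  stopifnot(inherits(dist, "degree_distribution"))
  k <- dist$k; p <- dist$p
  if (length(k) < 2L) {
    stop("degenerate distribution: need at least 2 distinct degrees",
         call. = FALSE)
  }
  y <- log10(p); lk <- log10(k)
  n <- length(k)
  # RSS floored at numerical noise (~1e-10 per point) so that on exact
  # synthetic data the nested models tie on fit and the most parsimonious
  # wins by its parameter penalty
  aic_of <- function(rss, npar) n * log(max(rss, n * 1e-20) / n) + 2 * npar
  rows <- list()
  f_exp <- stats::lm(y ~ k)
  rows$exponential <- data.frame(
    model = "exponential", a = unname(stats::coef(f_exp)[1L]), b = NA_real_,
    gamma = -1 / unname(stats::coef(f_exp)[2L]), k_x = NA_real_,
    rss = sum(stats::resid(f_exp)^2),
    aic = aic_of(sum(stats::resid(f_exp)^2), 2L), stringsAsFactors = FALSE)
  f_pow <- stats::lm(y ~ lk)
  rows$power_law <- data.frame(
    model = "power_law", a = unname(stats::coef(f_pow)[1L]),
    b = -unname(stats::coef(f_pow)[2L]), gamma = NA_real_, k_x = NA_real_,
    rss = sum(stats::resid(f_pow)^2),
    aic = aic_of(sum(stats::resid(f_pow)^2), 2L), stringsAsFactors = FALSE)
  skipped <- character(0)
  if (n >= 4L) {
    f_tr <- stats::lm(y ~ lk + k)
    ck <- unname(stats::coef(f_tr)[3L])
    rows$truncated_power_law <- data.frame(
      model = "truncated_power_law", a = unname(stats::coef(f_tr)[1L]),
      b = -unname(stats::coef(f_tr)[2L]), gamma = NA_real_,
      k_x = if (is.na(ck) || ck >= 0) Inf else -1 / ck,
      rss = sum(stats::resid(f_tr)^2),
      aic = aic_of(sum(stats::resid(f_tr)^2), 3L), stringsAsFactors = FALSE)
  } else {
    skipped <- "truncated_power_law"
  }
  out <- do.call(rbind, rows)
  out$selected <- out$aic == min(out$aic)
  rownames(out) <- NULL
  structure(out, skipped = skipped, class = c("connectivity_fits",
                                              "data.frame"))
}

#' Log-log regression of connectivity on interaction frequency
#'
#' Ordinary least squares of log10 s on log10 f: does a species'
#' connectivity scale with how often it was recorded interacting? Species
#' with nonpositive f or s are excluded (log-undefined) with a warning.
#'
#' @param f per-species interaction frequencies (visit events).
#' @param s per-species connectivity (degree).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value` (two-sided
#'   slope t-test), `n`, `n_excluded`.
#' @export
fs_regression <- function(f, s) {
  stopifnot(length(f) == length(s))
  ok <- is.finite(f) & is.finite(s) & f > 0 & s > 0
  if (any(!ok)) {
    warning(sprintf("fs_regression: excluding %d species with nonpositive f or s",
                    sum(!ok)), call. = FALSE)
  }
  f <- f[ok]; s <- s[ok]
  if (length(f) < 3L) stop("fs_regression needs >= 3 usable species",
                           call. = FALSE)
  fit <- stats::lm(log10(s) ~ log10(f))
  sm <- summary(fit)
  r2 <- sm$r.squared
  pv <- unname(sm$coefficients[2L, 4L])
  if (!is.finite(r2)) {        # constant response: no variance to explain
    r2 <- 0
    pv <- 1
  }
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2,
       p_value = pv,
       n = length(f), n_excluded = sum(!ok))
}

#' Test heterogeneity of f-s regression slopes across networks
#'
#' ANCOVA-style comparison: the full model log10 s ~ log10 f * group is
#' tested against the common-slope model log10 s ~ log10 f + group. With G
#' groups and N usable points the F statistic has (G - 1, N - 2G) degrees
#' of freedom.
#'
#' @param groups named list; each element a data frame (or list) with
#'   components `f` and `s`.
#' @return Object of class `slope_comparison`: list with `per_group` (data
#'   frame of slopes/intercepts/R2), `F`, `df1`, `df2`, `p_value`, `n`.
#' @export
compare_slopes <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  dat <- do.call(rbind, lapply(names(groups), function(nm) {
    gd <- groups[[nm]]
    ok <- is.finite(gd$f) & is.finite(gd$s) & gd$f > 0 & gd$s > 0
    data.frame(group = nm, f = gd$f[ok], s = gd$s[ok],
               stringsAsFactors = FALSE)
  }))
  dat$group <- factor(dat$group, levels = names(groups))
  full <- stats::lm(log10(s) ~ log10(f) * group, data = dat)
  reduced <- stats::lm(log10(s) ~ log10(f) + group, data = dat)
  an <- stats::anova(reduced, full)
  per_group <- do.call(rbind, lapply(names(groups), function(nm) {
    r <- fs_regression(groups[[nm]]$f, groups[[nm]]$s)
    data.frame(group = nm, slope = r$slope, intercept = r$intercept,
               r_squared = r$r_squared, n = r$n, stringsAsFactors = FALSE)
  }))
  Fst <- an$F[2L]
  structure(list(per_group = per_group,
                 F = if (is.na(Fst)) 0 else Fst,
                 df1 = an$Df[2L], df2 = full$df.residual,
                 p_value = an$`Pr(>F)`[2L], n = nrow(dat)),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("slope heterogeneity: F_(%d,%d) = %.3f, p = %.4g (n = %d)\n",
              x$df1, x$df2, x$F, x$p_value, x$n))
  print(x$per_group)
  invisible(x)
}

#' Per-species interaction frequencies from visitation events
#'
#' f for a pollinator is its number of visit events; f for a plant the
#' number of events it received. Pollen records contribute links (s) but no
#' frequencies: only direct visitation yields event counts.
#'
#' @param records validated visitation events.
#' @param side `"pollinators"` or `"plants"`.
#' @return Named integer vector of event counts.
#' @export
interaction_frequency <- function(records,
                                  side = c("pollinators", "plants")) {
  side <- match.arg(side)
  records <- as_visit_records(records)
  col <- if (side == "pollinators") "pollinator" else "plant"
  tab <- table(records[[col]])
  stats::setNames(as.integer(tab), names(tab))
}
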