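#' Study configuration
#'
#' Seeds, replication counts and thresholds for [run_study()]. Disable a
#' stage by setting its replication/restart count to 0.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param min_grains pollen evidence threshold.
#' @param null_reps null-model draws for the NODF z-scores (0 = skip).
#' @param module_restarts annealing restarts for module detection
#'   (0 = skip modules, roles and link gain).
#' @param link_gain_perms permutations for the within/between-module
#'   link-gain test.
#' @param rarefaction_reps bootstrap replicates for rarefaction bands
#'   (0 = skip).
#' @param fit_distributions fit connectivity-distribution models?
#' @return A `study_config` list.
#' @export
study_config <- function(seed = 1L, min_grains = 5L, null_reps = 1000L,
                         module_restarts = 10L, link_gain_perms = 5000L,
                         rarefaction_reps = 200L,
                         fit_distributions = TRUE) {
  structure(list(seed = as.integer(seed), min_grains = as.integer(min_grains),
                 null_reps = as.integer(null_reps),
                 module_restarts = as.integer(module_restarts),
                 link_gain_perms = as.integer(link_gain_perms),
                 rarefaction_reps = as.integer(rarefaction_reps),
                 fit_distributions = isTRUE(fit_distributions)),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' @param path YAML file whose keys match [study_config()] arguments.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

#' Run the full network-comparison workflow
#'
#' Builds the five binary matrices — diurnal visitation (V_d), diurnal
#' pollen (P_d), their union (V_dP_d), nocturnal pollen (P_n), and the
#' three-way union (V_dP_dP_n) — then computes the comparative structure
#' report: per-matrix metrics, the provenance overlap tally, the
#' fold-change of interaction counts over V_d, and (as configured) NODF
#' null-model z-scores, module partitions with species roles and
#' within/between-module link gain, connectivity-distribution fits with
#' f-s slope comparison, and rarefaction curves.
#'
#' @param visits visitation events (data frame or CSV path).
#' @param pollen pollen records (data frame or CSV path).
#' @param config a [study_config()] (or YAML path).
#' @return Object of class `study_report`.
#' @export
run_study <- function(visits, pollen, config = study_config()) {
  if (is.character(visits)) visits <- read_visit_records(visits)
  if (is.character(pollen)) pollen <- read_pollen_records(pollen)
  if (is.character(config)) config <- read_study_config(config)
  visits <- as_visit_records(visits)
  pollen <- as_pollen_records(pollen)

  vd <- build_visitation_matrix(visits)
  pd <- build_pollen_matrix(pollen, "diurnal", config$min_grains)
  pn <- build_pollen_matrix(pollen, "nocturnal", config$min_grains)
  vdpd <- superimpose(list(vd, pd), "V_dP_d")
  vdpdpn <- superimpose(list(vdpd, pn), "V_dP_dP_n")
  mats <- list(V_d = vd, P_d = pd, V_dP_d = vdpd, P_n = pn,
               V_dP_dP_n = vdpdpn)

  report <- list(config = unclass(config),
                 metrics = lapply(mats, metrics_report),
                 overlap = overlap_tally(vdpdpn),
                 fold_change = n_links(vdpdpn) / n_links(vd))

  if (config$null_reps > 0L) {
    report$null_nodf <- lapply(seq_along(mats), function(i) {
      null_test(mats[[i]], "nodf", n_reps = config$null_reps,
                seed = config$seed + i)
    })
    names(report$null_nodf) <- names(mats)
  }

  if (config$module_restarts > 0L) {
    parts <- lapply(seq_along(mats), function(i) {
      optimize_modules(mats[[i]], n_restarts = config$module_restarts,
                       seed = config$seed + 100L + i)
    })
    names(parts) <- names(mats)
    report$modules <- parts
    report$roles <- lapply(names(mats), function(nm) {
      species_roles(mats[[nm]], parts[[nm]])
    })
    names(report$roles) <- names(mats)
    added_d <- .links_added(vdpd, vd)
    added_n <- .links_added(vdpdpn, vdpd)
    report$link_gain <- list(
      diurnal_pollen = link_gain_by_module(
        parts$V_d, added_d, n_perm = config$link_gain_perms,
        seed = config$seed + 200L),
      nocturnal_pollen = link_gain_by_module(
        parts$V_dP_d, added_n, n_perm = config$link_gain_perms,
        seed = config$seed + 201L))
  }

  if (isTRUE(config$fit_distributions)) {
    report$fits <- lapply(mats, function(M) {
      lapply(c(pollinators = "pollinators", plants = "plants"),
             function(sd) fit_connectivity_models(
               cumulative_distribution(M, sd)))
    })
    report$fs <- .fs_comparison(visits, mats)
  }

  if (config$rarefaction_reps > 0L) {
    pol_d <- pollen[pollen$period == "diurnal", , drop = FALSE]
    pol_n <- pollen[pollen$period == "nocturnal", , drop = FALSE]
    ab <- list(
      V_d = interaction_abundances(visits = visits),
      P_d = interaction_abundances(pollen = pol_d,
                                   min_grains = config$min_grains),
      V_dP_d = interaction_abundances(visits, pol_d, config$min_grains),
      P_n = interaction_abundances(pollen = pol_n,
                                   min_grains = config$min_grains),
      V_dP_dP_n = interaction_abundances(visits, pollen,
                                         config$min_grains))
    report$rarefaction <- lapply(seq_along(ab), function(i) {
      rarefy_ci(ab[[i]], B = config$rarefaction_reps,
                seed = config$seed + 300L + i)
    })
    names(report$rarefaction) <- names(ab)
  }

  structure(report, class = "study_report")
}

# links present in `after` but not `before`
.links_added <- function(after, before) {
  la <- as.data.frame(after)[, c("plant", "pollinator")]
  lb <- as.data.frame(before)[, c("plant", "pollinator")]
  key_a <- paste(la$plant, la$pollinator, sep = " :: ")
  key_b <- paste(lb$plant, lb$pollinator, sep = " :: ")
  la[!(key_a %in% key_b), , drop = FALSE]
}

# f-s regressions per matrix and slope comparison across the three
# visitation-anchored matrices, per guild
.fs_comparison <- function(visits, mats) {
  out <- list()
  for (sd in c("pollinators", "plants")) {
    f <- interaction_frequency(visits, sd)
    mk <- function(M) {
      con <- species_connectivity(M)
      con <- con[con$side == sd, ]
      sp <- intersect(con$species, names(f))
      list(f = as.numeric(f[sp]),
           s = as.numeric(con$degree[match(sp, con$species)]))
    }
    groups <- lapply(mats[c("V_d", "V_dP_d", "V_dP_dP_n")], mk)
    out[[sd]] <- list(
      regressions = lapply(groups, function(g) fs_regression(g$f, g$s)),
      comparison = compare_slopes(groups))
  }
  out
}

#' Table-style comparative summary of a study report
#'
#' @param report a `study_report`.
#' @return Data frame with one row per structure parameter and one column
#'   per matrix, in the fixed order V_d, P_d, V_dP_d, P_n, V_dP_dP_n.
#' @export
study_table <- function(report) {
  stopifnot(inherits(report, "study_report"))
  m <- report$metrics
  row <- function(f, digits) {
    vapply(m, function(x) round(f(x), digits), numeric(1))
  }
  tab <- rbind(
    `Plant species` = row(function(x) x$P, 0),
    `Pollinator species` = row(function(x) x$A, 0),
    `Interactions recorded` = row(function(x) x$L, 0),
    `Connectance` = row(function(x) x$connectance, 3),
    `Mean plant connectivity (S_P)` = row(function(x) x$S_P, 2),
    `Mean pollinator connectivity (S_A)` = row(function(x) x$S_A, 2),
    `% Extreme pollinator specialists` =
      row(function(x) x$pct_extreme_specialists, 2),
    `NODF` = row(function(x) x$NODF, 2),
    `Degree centralization (DC)` = row(function(x) x$DC, 2))
  if (!is.null(report$modules)) {
    tab <- rbind(tab,
      `Modularity (M)` = vapply(report$modules, function(p)
        round(p$Q, 2), numeric(1)),
      `Number of modules` = vapply(report$modules, function(p)
        as.numeric(p$n_modules), numeric(1)))
  }
  as.data.frame(tab)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Comparative pollination-network structure report\n")
  print(study_table(x))
  cat(sprintf("\nFold-change of interactions vs V_d: %.2f\n",
              x$fold_change))
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' Writes a deterministic JSON rendering (full metric precision, stable
#' field order) so identical inputs and configuration give byte-identical
#' output.
#'
#' @param report a `study_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  x <- list(
    config = report$config,
    table = study_table(report),
    overlap = as.list(unclass(report$overlap)),
    fold_change = report$fold_change)
  if (!is.null(report$null_nodf)) {
    x$null_nodf <- lapply(report$null_nodf, function(ne)
      list(observed = ne$observed, z = ne$z, p_emp = ne$p_emp,
           degenerate = ne$degenerate))
  }
  if (!is.null(report$modules)) {
    x$modularity <- lapply(report$modules, function(p)
      list(Q = p$Q, n_modules = p$n_modules))
    x$link_gain <- lapply(report$link_gain, function(lg)
      list(pct_within = lg$pct_within, pct_between = lg$pct_between,
           p_perm = lg$p_perm,
           n_new_species_links = lg$n_new_species_links))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, na = "null")
  invisible(path)
}
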