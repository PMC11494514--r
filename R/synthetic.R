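#' Configuration for a synthetic plant-pollinator community
#'
#' Defaults emulate an intensively sampled subalpine-meadow community: 41
#' plant species, 115 diurnal and 46 nocturnal pollinator species, lognormal
#' species abundances, five planted modules with moderate within-module
#' link bias, a markedly more specialized nocturnal guild
#' (Dirichlet concentration kappa_n << kappa_d), 1693 visitation events,
#' 272 diurnal and 753 nocturnal pollen-load specimens, and overdispersed
#' (negative binomial) grain counts around a mean comfortably above the
#' 5-grain evidence threshold.
#'
#' @param n_plants,n_diurnal_pollinators,n_nocturnal_pollinators species
#'   richness per guild.
#' @param abundance_sigma sd of log abundances (lognormal, mean log 0).
#' @param n_modules planted module count G.
#' @param module_strength lambda >= 0; within-module link propensity is
#'   multiplied by (1 + lambda).
#' @param kappa_d,kappa_n Dirichlet concentrations of diurnal/nocturnal
#'   pollinator visit profiles (smaller = more specialized).
#' @param n_visit_events diurnal visitation events to draw.
#' @param n_diurnal_specimens,n_nocturnal_specimens pollen-load specimens.
#' @param grain_mean,grain_dispersion negative-binomial mean and size for
#'   grains per contacted plant.
#' @param contact_rate nu; plants contacted per specimen ~ 1 + Poisson(nu).
#' @param seed community RNG seed.
#' @return A `community_config` list.
#' @export
community_config <- function(n_plants = 41L, n_diurnal_pollinators = 115L,
                             n_nocturnal_pollinators = 46L,
                             abundance_sigma = 1.0, n_modules = 5L,
                             module_strength = 2.0, kappa_d = 5.0,
                             kappa_n = 0.1, n_visit_events = 1693L,
                             n_diurnal_specimens = 272L,
                             n_nocturnal_specimens = 753L,
                             grain_mean = 20, grain_dispersion = 1.0,
                             contact_rate = 2.0, seed = 1L) {
  cfg <- list(n_plants = as.integer(n_plants),
              n_diurnal_pollinators = as.integer(n_diurnal_pollinators),
              n_nocturnal_pollinators = as.integer(n_nocturnal_pollinators),
              abundance_sigma = abundance_sigma,
              n_modules = as.integer(n_modules),
              module_strength = module_strength,
              kappa_d = kappa_d, kappa_n = kappa_n,
              n_visit_events = as.integer(n_visit_events),
              n_diurnal_specimens = as.integer(n_diurnal_specimens),
              n_nocturnal_specimens = as.integer(n_nocturnal_specimens),
              grain_mean = grain_mean,
              grain_dispersion = grain_dispersion,
              contact_rate = contact_rate, seed = as.integer(seed))
  stopifnot(cfg$n_plants > 0L, cfg$n_diurnal_pollinators > 0L,
            cfg$n_nocturnal_pollinators > 0L, cfg$n_modules > 0L,
            cfg$module_strength >= 0, cfg$kappa_d > 0, cfg$kappa_n > 0,
            cfg$abundance_sigma > 0, cfg$grain_mean > 0,
            cfg$grain_dispersion > 0, cfg$contact_rate >= 0)
  structure(cfg, class = "community_config")
}

#' Simulate a latent community with planted module structure
#'
#' Species abundances a_i (plants) and b_j (pollinators) are lognormal;
#' link propensity is w_ij = a_i * b_j * (1 + lambda * \[same module\]).
#' Plants and pollinators are assigned round-robin to the G planted
#' modules, which are recorded as ground truth for recovery tests. Each
#' pollinator taxon also receives a visit profile drawn from a Dirichlet
#' centred on its propensity column with guild-specific concentration
#' (kappa), so a low-kappa guild is specialized at the taxon level.
#' Nocturnal pollinators are assigned the "moths" functional group,
#' diurnal ones a group drawn from the remaining vocabulary.
#'
#' @param cfg a [community_config()].
#' @return Object of class `synthetic_community`: list with `cfg`, `plants`
#'   (data frame: taxon, abundance, module), `pollinators` (data frame:
#'   taxon, guild, group, abundance, module), `w` (plants x all pollinators
#'   propensity matrix) and `profiles` (per-taxon visit profiles, columns
#'   summing to 1).
#' @export
simulate_community <- function(cfg = community_config()) {
  stopifnot(inherits(cfg, "community_config"))
  n_pol <- cfg$n_diurnal_pollinators + cfg$n_nocturnal_pollinators
  if (cfg$n_modules > min(cfg$n_plants, n_pol)) {
    stop("n_modules exceeds the smaller guild's species count",
         call. = FALSE)
  }
  set.seed(cfg$seed)
  plants <- sprintf("plant_%02d", seq_len(cfg$n_plants))
  pol <- c(sprintf("dipol_%03d", seq_len(cfg$n_diurnal_pollinators)),
           sprintf("nopol_%03d", seq_len(cfg$n_nocturnal_pollinators)))
  guild <- rep(c("diurnal", "nocturnal"),
               c(cfg$n_diurnal_pollinators, cfg$n_nocturnal_pollinators))
  group <- ifelse(guild == "nocturnal", "moths",
                  sample(setdiff(pollinator_groups, "moths"),
                         n_pol, replace = TRUE))
  a <- stats::rlnorm(cfg$n_plants, 0, cfg$abundance_sigma)
  b <- stats::rlnorm(n_pol, 0, cfg$abundance_sigma)
  mod_p <- rep_len(seq_len(cfg$n_modules), cfg$n_plants)
  mod_a <- rep_len(seq_len(cfg$n_modules), n_pol)
  w <- outer(a, b) * (1 + cfg$module_strength * outer(mod_p, mod_a, "=="))
  dimnames(w) <- list(plants, pol)
  # per-taxon visit profile: Dirichlet around the propensity column, with
  # guild-specific concentration (kappa_n << kappa_d makes a nocturnal
  # taxon's whole population specialize on the same few plants)
  profiles <- vapply(seq_len(n_pol), function(j) {
    kappa <- if (guild[j] == "diurnal") cfg$kappa_d else cfg$kappa_n
    alpha <- kappa * w[, j] / mean(w[, j])
    pr <- stats::rgamma(cfg$n_plants, shape = alpha)
    if (sum(pr) == 0) pr <- alpha               # extreme-kappa underflow
    pr <- pr + 1e-12 * max(pr)                  # keep all plants samplable
    pr / sum(pr)
  }, numeric(cfg$n_plants))
  dimnames(profiles) <- dimnames(w)
  structure(list(
    cfg = cfg,
    plants = data.frame(taxon = plants, abundance = a, module = mod_p,
                        stringsAsFactors = FALSE),
    pollinators = data.frame(taxon = pol, guild = guild, group = group,
                             abundance = b, module = mod_a,
                             stringsAsFactors = FALSE),
    w = w, profiles = profiles), class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf(
    "synthetic community: %d plants, %d+%d pollinators, %d planted modules (lambda = %g)\n",
    nrow(x$plants), sum(x$pollinators$guild == "diurnal"),
    sum(x$pollinators$guild == "nocturnal"), x$cfg$n_modules,
    x$cfg$module_strength))
  invisible(x)
}

#' Simulate diurnal visitation events
#'
#' Events are drawn i.i.d. over (plant, diurnal pollinator) cells with
#' probability proportional to the propensity w; census and meadow labels
#' are cosmetic round-robin assignments.
#'
#' @param comm a `synthetic_community`.
#' @param n_events number of events (defaults to the config value).
#' @param seed RNG seed (defaults to config seed + 1).
#' @return Data frame of visitation events (see [as_visit_records()]).
#' @export
simulate_visitation <- function(comm, n_events = comm$cfg$n_visit_events,
                                seed = comm$cfg$seed + 1L) {
  stopifnot(inherits(comm, "synthetic_community"))
  if (n_events < 1L) stop("n_events must be >= 1", call. = FALSE)
  set.seed(seed)
  di <- comm$pollinators$guild == "diurnal"
  wd <- comm$w[, di, drop = FALSE]
  cells <- sample.int(length(wd), n_events, replace = TRUE,
                      prob = as.vector(wd))
  pi <- (cells - 1L) %% nrow(wd) + 1L
  pj <- (cells - 1L) %/% nrow(wd) + 1L
  grp <- comm$pollinators$group[di]
  as_visit_records(data.frame(
    census = rep_len(1:5, n_events),
    meadow = rep_len(sprintf("meadow_%d", 1:6), n_events),
    plant = rownames(wd)[pi],
    specimen_id = sprintf("V%05d", seq_len(n_events)),
    pollinator = colnames(wd)[pj],
    group = grp[pj], stringsAsFactors = FALSE))
}

#' Simulate pollen loads on captured specimens
#'
#' Each specimen's taxon is drawn proportional to pollinator abundance
#' within the guild; the plants it contacts are sampled from its taxon's
#' Dirichlet visit profile (kappa_d for diurnal, kappa_n for nocturnal, so
#' the nocturnal guild concentrates loads on fewer plants); the number of
#' contacted plants is 1 + Poisson(nu), and grains per contacted plant are
#' negative binomial with mean proportional to the plant's profile share,
#' so a specialist's grain mass piles onto its dominant plant.
#'
#' @param comm a `synthetic_community`.
#' @param n_specimens number of captured specimens.
#' @param period `"diurnal"` or `"nocturnal"`.
#' @param seed RNG seed (defaults to config seed + 2 or + 3 by period).
#' @return Data frame of pollen records (see [as_pollen_records()]); one
#'   row per (specimen, contacted plant), including sub-threshold loads.
#' @export
simulate_pollen_loads <- function(comm, n_specimens = NULL,
                                  period = c("diurnal", "nocturnal"),
                                  seed = NULL) {
  stopifnot(inherits(comm, "synthetic_community"))
  period <- match.arg(period)
  cfg <- comm$cfg
  if (is.null(n_specimens)) {
    n_specimens <- if (period == "diurnal") cfg$n_diurnal_specimens
                   else cfg$n_nocturnal_specimens
  }
  if (n_specimens < 1L) stop("n_specimens must be >= 1", call. = FALSE)
  if (is.null(seed)) {
    seed <- cfg$seed + if (period == "diurnal") 2L else 3L
  }
  set.seed(seed)
  gi <- comm$pollinators$guild == period
  taxa <- comm$pollinators$taxon[gi]
  abund <- comm$pollinators$abundance[gi]
  prof <- comm$profiles[, gi, drop = FALSE]
  P <- nrow(prof)
  rows <- vector("list", n_specimens)
  prefix <- if (period == "diurnal") "D" else "N"
  for (s in seq_len(n_specimens)) {
    j <- sample.int(length(taxa), 1L, prob = abund)
    profile <- prof[, j]
    n_contact <- min(P, 1L + stats::rpois(1L, cfg$contact_rate))
    contacted <- sample.int(P, n_contact, prob = profile)
    # grain mass follows the visit profile: a specialist's load piles onto
    # its dominant plant, so low kappa yields single-plant (thresholdable)
    # loads even when several plants were brushed
    share <- profile[contacted] / sum(profile[contacted])
    grains <- stats::rnbinom(n_contact,
                             mu = cfg$grain_mean * n_contact * share,
                             size = cfg$grain_dispersion)
    rows[[s]] <- data.frame(
      specimen_id = sprintf("%s%05d", prefix, s),
      pollinator = taxa[j], period = period,
      plant = rownames(prof)[contacted], grains = grains,
      stringsAsFactors = FALSE)
  }
  as_pollen_records(do.call(rbind, rows))
}
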