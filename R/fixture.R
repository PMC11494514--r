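#' Reference count structure for a five-matrix study design
#'
#' Species richness, link counts and between-method overlaps of a
#' well-sampled subalpine meadow community observed by diurnal visitation
#' plus diurnal and nocturnal pollen analysis: 25 plants / 115 pollinators
#' / 352 links by visitation; 38 plants (22 shared) / 59 pollinators (all
#' shared) / 413 links (183 shared) by diurnal pollen; 18 plants (all
#' shared) / 46 pollinators (8 shared) / 96 links (13 shared with the
#' diurnal union) by nocturnal pollen. The implied unions are 41 x 115
#' with 582 links and 41 x 153 with 665 links.
#'
#' @return Named list of counts consumed by [simulate_reference_records()].
#' @export
reference_counts <- function() {
  list(
    vd = list(n_plants = 25L, n_pollinators = 115L, n_links = 352L),
    pd = list(n_plants = 38L, n_shared_plants = 22L, n_pollinators = 59L,
              n_links = 413L, n_shared_links = 183L),
    pn = list(n_plants = 18L, n_pollinators = 46L,
              n_shared_pollinators = 8L, n_links = 96L,
              n_shared_links = 13L)
  )
}

#' Generate sampling records realizing a fixed overlap structure
#'
#' Deterministically (given `seed`) constructs visitation events and
#' diurnal/nocturnal pollen-load records whose binary matrices reproduce
#' the species, link and overlap counts of [reference_counts()] exactly:
#' the construction places the shared links first, covers every species,
#' fills the remaining quota at random, and asserts every target count
#' before returning. Visit events beyond one-per-link are allocated with
#' lognormal link weights, giving a right-skewed interaction frequency
#' distribution; pollen records include sub-threshold (< 5 grain) loads
#' that must be filtered out by the evidence threshold.
#'
#' @param counts count structure, see [reference_counts()].
#' @param n_visit_events total visitation events (default 1693).
#' @param seed RNG seed.
#' @return List with `visits` and `pollen` record data frames.
#' @export
simulate_reference_records <- function(counts = reference_counts(),
                                       n_visit_events = 1693L, seed = 1L) {
  set.seed(seed)
  cv <- counts$vd; cd <- counts$pd; cn <- counts$pn
  stopifnot(cd$n_shared_plants <= cv$n_plants,
            cd$n_pollinators <= cv$n_pollinators,
            cn$n_plants <= cd$n_shared_plants,
            cn$n_shared_pollinators <= cd$n_pollinators,
            cn$n_shared_links <= cd$n_shared_links,
            n_visit_events >= cv$n_links)
  n_plants_all <- cv$n_plants + (cd$n_plants - cd$n_shared_plants)
  plants <- sprintf("plant_%02d", seq_len(n_plants_all))
  n_pol_all <- cv$n_pollinators +
    (cn$n_pollinators - cn$n_shared_pollinators)
  polls <- sprintf("pol_%03d", seq_len(n_pol_all))
  # index sets -------------------------------------------------------------
  vd_p <- seq_len(cv$n_plants)
  pd_p <- c(seq_len(cd$n_shared_plants),
            cv$n_plants + seq_len(cd$n_plants - cd$n_shared_plants))
  pn_p <- seq_len(cn$n_plants)
  vd_a <- seq_len(cv$n_pollinators)
  pd_a <- seq_len(cd$n_pollinators)
  pn_a_shared <- seq_len(cn$n_shared_pollinators)
  pn_a_new <- cv$n_pollinators +
    seq_len(cn$n_pollinators - cn$n_shared_pollinators)

  cell <- function(p, a) (p - 1L) * n_pol_all + a
  cell_p <- function(id) (id - 1L) %/% n_pol_all + 1L
  cell_a <- function(id) (id - 1L) %% n_pol_all + 1L
  grid <- function(ps, as) as.integer(outer(ps, as, cell))

  # anchors: links shared by all of V_d, P_d (region) and P_n
  anchors <- cell(seq_len(cn$n_shared_links),
                  rep_len(pn_a_shared, cn$n_shared_links))
  # shared V_d/P_d links in the shared region, covering its species
  region <- grid(seq_len(cd$n_shared_plants), pd_a)
  sh <- anchors
  for (p in seq_len(cd$n_shared_plants)) {
    if (!any(cell_p(sh) == p)) sh <- c(sh, cell(p, sample(pd_a, 1L)))
  }
  for (a in pd_a) {
    if (!any(cell_a(sh) == a)) {
      sh <- c(sh, cell(sample(seq_len(cd$n_shared_plants), 1L), a))
    }
  }
  stopifnot(length(sh) <= cd$n_shared_links)
  sh <- c(sh, sample(setdiff(region, sh), cd$n_shared_links - length(sh)))

  # V_d: shared links + coverage of the remaining species + random fill
  lv <- sh
  for (p in setdiff(vd_p, cell_p(lv))) lv <- c(lv, cell(p, sample(vd_a, 1L)))
  for (a in setdiff(vd_a, cell_a(lv))) lv <- c(lv, cell(sample(vd_p, 1L), a))
  stopifnot(length(lv) <= cv$n_links)
  lv <- c(lv, sample(setdiff(grid(vd_p, vd_a), lv),
                     cv$n_links - length(lv)))

  # P_d: shared links + coverage of pollen-only plants + fill off V_d cells
  lpd <- sh
  for (p in setdiff(pd_p, cell_p(lpd))) {
    lpd <- c(lpd, cell(p, sample(pd_a, 1L)))
  }
  stopifnot(!any(lpd[-seq_along(sh)] %in% lv))
  pool <- setdiff(grid(pd_p, pd_a), union(lv, lpd))
  stopifnot(length(lpd) <= cd$n_links)
  lpd <- c(lpd, sample(pool, cd$n_links - length(lpd)))

  # P_n: anchors + new nocturnal pollinators (coverage first) + fill
  lpn <- anchors
  cover_p <- setdiff(pn_p, cell_p(lpn))
  cover_rows <- c(cover_p,
                  sample(pn_p, length(pn_a_new) - length(cover_p),
                         replace = TRUE))
  lpn <- c(lpn, cell(cover_rows, pn_a_new))
  stopifnot(length(lpn) <= cn$n_links)
  lpn <- c(lpn, sample(setdiff(grid(pn_p, pn_a_new), lpn),
                       cn$n_links - length(lpn)))

  stopifnot(!anyDuplicated(lv), !anyDuplicated(lpd), !anyDuplicated(lpn),
            length(intersect(lv, lpd)) == cd$n_shared_links,
            length(intersect(lpn, union(lv, lpd))) == cn$n_shared_links)

  # records ----------------------------------------------------------------
  groups_d <- sample(setdiff(pollinator_groups, "moths"),
                     cv$n_pollinators, replace = TRUE)
  group_of <- c(groups_d, rep("moths", length(pn_a_new)))
  names(group_of) <- polls

  weight <- stats::rlnorm(length(lv), 0, 1)
  extra <- sample(seq_along(lv), n_visit_events - length(lv),
                  replace = TRUE, prob = weight)
  ev <- c(seq_along(lv), extra)
  visits <- data.frame(
    census = rep_len(1:5, length(ev)),
    meadow = rep_len(sprintf("meadow_%d", 1:6), length(ev)),
    plant = plants[cell_p(lv[ev])],
    specimen_id = sprintf("V%05d", seq_along(ev)),
    pollinator = polls[cell_a(lv[ev])],
    group = unname(group_of[polls[cell_a(lv[ev])]]),
    stringsAsFactors = FALSE)

  pollen_rows <- function(ids, period, prefix) {
    df <- data.frame(
      specimen_id = sprintf("%s%05d", prefix, seq_along(ids)),
      pollinator = polls[cell_a(ids)], period = period,
      plant = plants[cell_p(ids)],
      grains = 5L + (seq_along(ids) %% 11L), stringsAsFactors = FALSE)
    # sub-threshold loads that the 5-grain rule must discard
    noise_a <- cell_a(ids[seq_len(min(30L, length(ids)))])
    noise_p <- cell_p(ids[rev(seq_len(min(30L, length(ids))))])
    noise <- data.frame(
      specimen_id = sprintf("%sx%04d", prefix, seq_along(noise_a)),
      pollinator = polls[noise_a], period = period,
      plant = plants[noise_p],
      grains = 1L + (seq_along(noise_a) %% 4L), stringsAsFactors = FALSE)
    rbind(df, noise)
  }
  pollen <- rbind(pollen_rows(lpd, "diurnal", "D"),
                  pollen_rows(lpn, "nocturnal", "N"))

  out <- list(visits = as_visit_records(visits),
              pollen = as_pollen_records(pollen))
  # verify the realized matrices against every target count
  vd <- build_visitation_matrix(out$visits)
  pd <- build_pollen_matrix(out$pollen, "diurnal")
  pn <- build_pollen_matrix(out$pollen, "nocturnal")
  u_d <- superimpose(list(vd, pd), "V_dP_d")
  u_all <- superimpose(list(u_d, pn), "V_dP_dP_n")
  stopifnot(
    length(vd$plants) == cv$n_plants,
    length(vd$pollinators) == cv$n_pollinators, n_links(vd) == cv$n_links,
    length(pd$plants) == cd$n_plants,
    length(pd$pollinators) == cd$n_pollinators, n_links(pd) == cd$n_links,
    length(pn$plants) == cn$n_plants,
    length(pn$pollinators) == cn$n_pollinators, n_links(pn) == cn$n_links,
    n_links(u_d) == cv$n_links + cd$n_links - cd$n_shared_links,
    n_links(u_all) == n_links(u_d) + cn$n_links - cn$n_shared_links)
  out
}
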