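small_cfg <- function(...) {
  community_config(n_plants = 10L, n_diurnal_pollinators = 14L,
                   n_nocturnal_pollinators = 6L, n_modules = 3L,
                   n_visit_events = 300L, n_diurnal_specimens = 40L,
                   n_nocturnal_specimens = 40L, ...)
}

test_that("neutral communities have multiplicative propensities", {
  comm <- simulate_community(small_cfg(module_strength = 0, seed = 5))
  a <- comm$plants$abundance
  b <- comm$pollinators$abundance
  expect_equal(comm$w, outer(a, b),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("generators are bit-reproducible from their seeds", {
  c1 <- simulate_community(small_cfg(seed = 9))
  c2 <- simulate_community(small_cfg(seed = 9))
  expect_identical(c1, c2)
  expect_identical(simulate_visitation(c1, seed = 4),
                   simulate_visitation(c2, seed = 4))
  expect_identical(simulate_pollen_loads(c1, 20, "nocturnal", seed = 4),
                   simulate_pollen_loads(c2, 20, "nocturnal", seed = 4))
})

test_that("module count cannot exceed the smaller guild", {
  expect_error(simulate_community(community_config(
    n_plants = 2L, n_diurnal_pollinators = 5L,
    n_nocturnal_pollinators = 5L, n_modules = 3L)), "n_modules")
})

test_that("visitation event frequencies follow the propensity matrix", {
  comm <- simulate_community(community_config(
    n_plants = 4L, n_diurnal_pollinators = 5L, n_nocturnal_pollinators = 2L,
    n_modules = 2L, seed = 13))
  n <- 50000L
  v <- simulate_visitation(comm, n_events = n, seed = 2)
  di <- comm$pollinators$guild == "diurnal"
  w <- comm$w[, di]
  p <- as.vector(w / sum(w))
  obs <- table(factor(paste(v$plant, v$pollinator),
                      levels = as.vector(outer(rownames(w), colnames(w),
                                               paste))))
  phat <- as.vector(obs) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(phat - p) <= 4 * se + 1e-9))
  expect_error(simulate_visitation(comm, n_events = 0), "n_events")
})

test_that("a single dominant propensity cell monopolises events", {
  comm <- simulate_community(community_config(
    n_plants = 2L, n_diurnal_pollinators = 2L, n_nocturnal_pollinators = 1L,
    n_modules = 1L, seed = 1))
  comm$w[] <- 1e-12
  comm$w[1, 1] <- 1
  v <- simulate_visitation(comm, n_events = 50, seed = 1)
  expect_equal(unique(paste(v$plant, v$pollinator)),
               paste(rownames(comm$w)[1], colnames(comm$w)[1]))
})

test_that("low Dirichlet concentration produces specialist pollen loads", {
  # direction-only check on replicate communities: the kappa_n = 0.1 guild
  # carries a larger one-link share than the kappa_d = 5 guild on average
  pct <- sapply(1:6, function(seed) {
    comm <- simulate_community(community_config(
      n_plants = 15L, n_diurnal_pollinators = 40L,
      n_nocturnal_pollinators = 40L, n_modules = 3L,
      kappa_d = 5, kappa_n = 0.1, seed = seed))
    pd <- simulate_pollen_loads(comm, 60, "diurnal", seed = 30 + seed)
    pn <- simulate_pollen_loads(comm, 60, "nocturnal", seed = 60 + seed)
    c(extreme_specialist_pct(build_pollen_matrix(pd, "diurnal")),
      extreme_specialist_pct(build_pollen_matrix(pn, "nocturnal")))
  })
  expect_gt(mean(pct[2, ]), mean(pct[1, ]))
  # specimen-level specialist limit: nocturnal loads qualify fewer plants
  comm <- simulate_community(community_config(
    n_plants = 15L, n_diurnal_pollinators = 40L,
    n_nocturnal_pollinators = 40L, n_modules = 3L,
    kappa_d = 5, kappa_n = 0.1, seed = 21))
  plants_per_specimen <- function(p) {
    a <- aggregate(grains ~ specimen_id + plant, p, sum)
    mean(table(a$specimen_id[a$grains >= 5]))
  }
  pd <- simulate_pollen_loads(comm, 80, "diurnal", seed = 1)
  pn <- simulate_pollen_loads(comm, 80, "nocturnal", seed = 2)
  expect_gt(plants_per_specimen(pd), plants_per_specimen(pn))
})

test_that("grain means below the threshold thin the pollen matrix", {
  rich <- simulate_community(small_cfg(grain_mean = 40, seed = 8))
  poor <- simulate_community(small_cfg(grain_mean = 2, seed = 8))
  lp_rich <- simulate_pollen_loads(rich, 80, "diurnal", seed = 9)
  lp_poor <- simulate_pollen_loads(poor, 80, "diurnal", seed = 9)
  raw_links <- function(p) nrow(unique(p[p$grains > 0,
                                         c("plant", "pollinator")]))
  m_poor <- build_pollen_matrix(lp_poor, "diurnal")
  expect_lt(n_links(m_poor) / raw_links(lp_poor), 0.5)
  m_rich <- build_pollen_matrix(lp_rich, "diurnal")
  expect_gt(n_links(m_rich) / raw_links(lp_rich),
            n_links(m_poor) / raw_links(lp_poor))
})

test_that("strong module bias concentrates links within planted modules", {
  cfg <- community_config(n_plants = 12L, n_diurnal_pollinators = 18L,
                          n_nocturnal_pollinators = 4L, n_modules = 3L,
                          module_strength = 50, abundance_sigma = 0.5,
                          n_visit_events = 150L, seed = 7)
  comm <- simulate_community(cfg)
  M <- build_visitation_matrix(simulate_visitation(comm))
  truth <- c(setNames(comm$plants$module, comm$plants$taxon),
             setNames(comm$pollinators$module, comm$pollinators$taxon))
  L <- as.data.frame(M)
  expect_gt(mean(truth[L$plant] == truth[L$pollinator]), 0.9)
})

test_that("neutral communities never look significantly modular", {
  # binarizing fixed-margin draws loses a few links to token collisions,
  # so null webs are slightly sparser and their Q slightly higher: the
  # modularity test is conservative. The calibration property that must
  # hold is the absence of spurious module detection on neutral webs.
  ps <- vapply(1:5, function(i) {
    cfg <- community_config(n_plants = 8L, n_diurnal_pollinators = 10L,
                            n_nocturnal_pollinators = 2L, n_modules = 2L,
                            module_strength = 0, n_visit_events = 150L,
                            seed = 40 + i)
    comm <- simulate_community(cfg)
    M <- build_visitation_matrix(simulate_visitation(comm))
    nt <- null_test(M, "modularity", n_reps = 15, seed = 50 + i,
                    stat_args = list(n_restarts = 2L))
    nt$p_emp
  }, numeric(1))
  expect_true(all(ps > 0.1))
})
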