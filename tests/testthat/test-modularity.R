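two_blocks <- function(b = 2) {
  A <- matrix(0L, 2 * b, 2 * b)
  A[seq_len(b), seq_len(b)] <- 1L
  A[b + seq_len(b), b + seq_len(b)] <- 1L
  dimnames(A) <- list(sprintf("p%d", seq_len(2 * b)),
                      sprintf("a%d", seq_len(2 * b)))
  A
}

test_that("Barber Q is 0 for one module and 0.5 for two clean blocks", {
  A <- two_blocks(2)
  sp <- c(rownames(A), colnames(A))
  expect_equal(barber_q(A, setNames(rep(1, 8), sp)), 0)
  planted <- setNames(rep(c(1, 2, 1, 2), each = 2), sp)
  expect_equal(barber_q(A, planted), 0.5)
  expect_error(barber_q(A, setNames(1, "p1")), "missing species")
})

test_that("annealing recovers the planted two-block optimum", {
  A <- two_blocks(3)
  part <- optimize_modules(A, n_restarts = 4, seed = 2)
  expect_equal(part$Q, 0.5, tolerance = 1e-12)
  expect_equal(part$n_modules, 2L)
  g <- part$assignment
  expect_true(all(g[c("p1", "p2", "p3", "a1", "a2", "a3")] ==
                    g[["p1"]]))
})

test_that("a complete bipartite network is effectively unimodular", {
  A <- matrix(1L, 3, 3, dimnames = list(paste0("p", 1:3), paste0("a", 1:3)))
  best <- barber_optimum(A)          # exhaustive over all 6-species partitions
  part <- optimize_modules(A, n_restarts = 3, seed = 5)
  expect_equal(part$Q, best, tolerance = 1e-12)
  expect_lte(part$Q, 1e-9)
})

test_that("annealing attains the exhaustive-search optimum on small webs", {
  set.seed(17)
  for (i in 1:3) {
    A <- rand_binary(4, 3, fill = 0.5)
    dimnames(A) <- list(paste0("p", 1:4), paste0("a", 1:3))
    best <- barber_optimum(A)        # 7 species: full partition enumeration
    part <- optimize_modules(A, n_restarts = 6, seed = 100 + i)
    expect_equal(part$Q, best, tolerance = 1e-10)
  }
})

test_that("module search is deterministic given seed and never below Q = 0", {
  A <- rand_binary(5, 5)
  p1 <- optimize_modules(A, n_restarts = 3, seed = 9)
  p2 <- optimize_modules(A, n_restarts = 3, seed = 9)
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(p1$Q, p2$Q)
  expect_gte(p1$Q, 0)
  expect_equal(max(p1$trace), p1$Q, tolerance = 1e-12)
})

test_that("participation and within-module z follow their definitions", {
  A <- two_blocks(2)
  M <- bmat(A)
  part <- optimize_modules(M, n_restarts = 3, seed = 1)
  roles <- species_roles(M, part)
  # block network: every link is within-module, so c = 0 everywhere
  expect_true(all(roles$c == 0))
  # equal within-module degrees: sd = 0 rule forces z = 0, all peripheral
  expect_true(all(roles$z == 0))
  expect_true(all(roles$role == "peripheral"))
  expect_setequal(roles$species, c(M$plants, M$pollinators))
})

test_that("a species split evenly across two modules has c = 0.5", {
  # rewire a1 to exactly one plant per module: p1 (module 1), p3 (module 2)
  A <- two_blocks(2)
  A[2, 1] <- 0L
  A[3, 1] <- 1L
  M <- bmat(A)
  part <- structure(list(
    name = "planted",
    assignment = setNames(rep(c(1L, 2L, 1L, 2L), each = 2),
                          c(rownames(A), colnames(A))),
    Q = barber_q(A, setNames(rep(c(1L, 2L, 1L, 2L), each = 2),
                             c(rownames(A), colnames(A)))),
    n_modules = 2L, trace = numeric(0), seed = 1L),
    class = "module_partition")
  roles <- species_roles(M, part)
  expect_equal(roles$c[roles$species == "a1"], 0.5)
  expect_true(all(roles$role %in%
    c("peripheral", "connector", "module hub", "network hub")))
})

test_that("link gain is labelled against the base partition", {
  A <- two_blocks(2)
  sp <- c(rownames(A), colnames(A))
  part <- structure(list(
    name = "planted",
    assignment = setNames(rep(c(1L, 2L, 1L, 2L), each = 2), sp),
    Q = 0.5, n_modules = 2L, trace = numeric(0), seed = 1L),
    class = "module_partition")
  # all added links inside module 1
  within_only <- data.frame(plant = c("p1", "p2"), pollinator = c("a2", "a1"))
  lg <- link_gain_by_module(part, within_only, n_perm = 200, seed = 1)
  expect_equal(lg$pct_within, 100)
  expect_equal(lg$n_between, 0L)
  # links to unknown species are excluded and counted
  mixed <- rbind(within_only,
                 data.frame(plant = "p_new", pollinator = "a1"))
  lg2 <- link_gain_by_module(part, mixed, n_perm = 200, seed = 1)
  expect_equal(lg2$n_new_species_links, 1L)
  expect_equal(lg2$n_within + lg2$n_between, 2L)
  # no eligible links: flagged, p undefined
  lg3 <- link_gain_by_module(part,
                             data.frame(plant = "q", pollinator = "b"),
                             n_perm = 200, seed = 1)
  expect_true(is.na(lg3$p_perm))
})

test_that("balanced cross-module link gain is near 50% within", {
  # 2 equal modules; added links = all plant x pollinator pairs
  A <- two_blocks(2)
  sp <- c(rownames(A), colnames(A))
  part <- structure(list(
    name = "planted",
    assignment = setNames(rep(c(1L, 2L, 1L, 2L), each = 2), sp),
    Q = 0.5, n_modules = 2L, trace = numeric(0), seed = 1L),
    class = "module_partition")
  added <- expand.grid(plant = rownames(A), pollinator = colnames(A),
                       stringsAsFactors = FALSE)
  lg <- link_gain_by_module(part, added, n_perm = 500, seed = 2)
  expect_equal(lg$pct_within, 50)
  expect_gt(lg$p_perm, 0.05)
})
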