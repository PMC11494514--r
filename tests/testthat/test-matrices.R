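test_that("visitation matrix collapses events to binary links", {
  v <- visits_of(c("A", "A", "A", "B"), c("x", "x", "y", "x"))
  M <- build_visitation_matrix(v)
  expect_equal(sort(M$plants), c("A", "B"))
  expect_equal(sort(M$pollinators), c("x", "y"))
  expect_equal(n_links(M), 3L)
  expect_true(all(M$layers$V_d[M$cells == 1L]))
})

test_that("matrix construction is deterministic under record shuffling", {
  set.seed(42)
  v <- visits_of(sample(LETTERS[1:6], 40, TRUE),
                 sample(letters[1:8], 40, TRUE))
  M1 <- build_visitation_matrix(v)
  M2 <- build_visitation_matrix(v[sample(nrow(v)), ])
  expect_identical(M1$cells, M2$cells)
})

test_that("pollen threshold applies per specimen on summed grains", {
  # 4 grains on one specimen: below threshold, no link
  expect_error(build_pollen_matrix(pollen_of("S1", "m1", "A", 4), "diurnal"),
               "threshold")
  # rows of the same specimen sum: 3 + 2 = 5 grains establishes the link
  p <- pollen_of(c("S1", "S1"), c("m1", "m1"), c("A", "A"), c(3, 2))
  expect_equal(n_links(build_pollen_matrix(p, "diurnal")), 1L)
  # 3 and 5 grains on two specimens of one taxon: second qualifies
  p2 <- pollen_of(c("S1", "S2", "S3"), c("m1", "m1", "m2"),
                  c("A", "A", "B"), c(3, 5, 9))
  M <- build_pollen_matrix(p2, "diurnal")
  expect_equal(n_links(M), 2L)
  expect_true(all(M$layers$P_d[M$cells == 1L]))
})

test_that("min_grains = 1 keeps every positive load; threshold is monotone", {
  set.seed(7)
  p <- pollen_of(sprintf("S%d", 1:40), sample(letters[1:5], 40, TRUE),
                 sample(LETTERS[1:6], 40, TRUE), sample(0:9, 40, TRUE))
  pos <- p[p$grains > 0, ]
  expect_equal(n_links(build_pollen_matrix(p, "diurnal", min_grains = 1)),
               nrow(unique(pos[, c("plant", "pollinator")])))
  links_at <- function(th) n_links(build_pollen_matrix(p, "diurnal", th))
  counts <- vapply(1:9, links_at, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("superimpose matches brute-force set union on random inputs", {
  set.seed(11)
  for (rep in 1:10) {
    A <- rand_binary(4, 5); B <- rand_binary(3, 6)
    MA <- bmat(A, "A", "V_d"); MB <- bmat(B, "B", "P_d")
    U <- superimpose(list(MA, MB), "U")
    key <- function(M) {
      L <- as.data.frame(M)
      paste(L$plant, L$pollinator)
    }
    expect_setequal(key(U), union(key(MA), key(MB)))
    expect_equal(n_links(U), length(union(key(MA), key(MB))))
  }
})

test_that("superimposing a matrix with itself is the identity on links", {
  M <- bmat(rand_binary(4, 4))
  U <- superimpose(list(M, M), "U")
  expect_equal(n_links(U), n_links(M))
  expect_identical(U$cells[M$plants, M$pollinators], M$cells)
})

test_that("superimposed links carry the union of provenance tags", {
  MA <- bmat(matrix(1, 1, 1, dimnames = list("A", "x")), layer = "V_d")
  MB <- bmat(matrix(1, 1, 1, dimnames = list("A", "x")), layer = "P_n")
  U <- superimpose(list(MA, MB), "U")
  expect_equal(as.data.frame(U)$provenance, "V_d+P_n")
})

test_that("overlap tally yields disjoint categories summing to the union", {
  links <- rbind(
    data.frame(plant = "A", pollinator = "x", layer = "V_d"),
    data.frame(plant = "A", pollinator = "y", layer = "P_d"),
    data.frame(plant = "B", pollinator = "x", layer = c("V_d", "P_d")))
  M <- pollinet:::new_bipartite_matrix(links, "mix")
  tal <- overlap_tally(M)
  expect_equal(unname(tal[c("V_d", "P_d", "V_d+P_d")]), c(1L, 1L, 1L))
  expect_equal(sum(tal), attr(tal, "total"))
  only_v <- bmat(rand_binary(3, 3), layer = "V_d")
  tv <- overlap_tally(only_v)
  expect_equal(unname(tv["V_d"]), n_links(only_v))
  expect_equal(sum(tv[-1L]), 0L)
})

test_that("matrix CSV + sidecar round-trip preserves links and provenance", {
  fx <- list(bmat(rand_binary(3, 4), "a", "V_d"),
             bmat(rand_binary(4, 3), "b", "P_n"))
  U <- superimpose(fx, "U")
  path <- tempfile(fileext = ".csv")
  write_bipartite_matrix(U, path)
  U2 <- read_bipartite_matrix(path)
  expect_identical(U2$cells, U$cells)
  expect_identical(as.data.frame(U2), as.data.frame(U))
})
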