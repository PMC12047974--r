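test_that("the identity rotation yields the identity permutation", {
  sch <- make_parcel_scheme(40, 7, seed = 1)
  spins <- spin_permutation_indices(sch, 1, seed = 1,
                                    rotations = list(diag(3)))
  expect_equal(spins$perm[1, ], seq_len(40))
})

test_that("spins stay within hemisphere and index validly", {
  sch <- make_parcel_scheme(50, 7, seed = 1)
  spins <- spin_permutation_indices(sch, 20, seed = 2)
  left <- which(sch$hemisphere == "L")
  right <- which(sch$hemisphere == "R")
  for (k in 1:20) {
    expect_true(all(spins$perm[k, left] %in% left))
    expect_true(all(spins$perm[k, right] %in% right))
  }
  # deterministic given seed
  again <- spin_permutation_indices(sch, 20, seed = 2)
  expect_identical(spins$perm, again$perm)
})

test_that("a half-turn about z maps parcels to their azimuthal antipodes", {
  # custom symmetric scheme: equatorial square per hemisphere
  pts <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  sch <- data.frame(parcel_id = 0:7,
                    network = factor(rep(c("A", "B"), 4)),
                    hemisphere = rep(c("L", "R"), each = 4),
                    cx = c(pts[, 1], -pts[, 1]),
                    cy = rep(pts[, 2], 2), cz = rep(pts[, 3], 2))
  class(sch) <- c("parcel_scheme", "data.frame")
  rz <- diag(c(-1, -1, 1))  # rotation by pi about the z-axis
  spins <- spin_permutation_indices(sch, 1, seed = 1, rotations = list(rz))
  # left square (+x,+y,-x,-y) -> each parcel inherits its antipode
  expect_equal(spins$perm[1, 1:4], c(3, 4, 1, 2))
  # mirrored rotation acts equivalently on the right hemisphere
  expect_equal(spins$perm[1, 5:8], c(7, 8, 5, 6))
})

test_that("the one-to-one variant is a true permutation; nearest allows duplicates", {
  sch <- make_parcel_scheme(60, 7, seed = 1)
  one <- spin_permutation_indices(sch, 10, seed = 3, method = "one_to_one")
  for (k in 1:10) {
    expect_equal(sort(one$perm[k, ]), seq_len(60))
  }
  set.seed(44)
  vals <- rnorm(60)
  spun <- vals[one$perm[4, ]]
  expect_equal(sort(spun), sort(vals))  # multiset exactly preserved
  nn <- spin_permutation_indices(sch, 10, seed = 3, method = "nearest")
  expect_true(all(nn$perm %in% seq_len(60)))
})

test_that("spatial correlation test honours its formula bounds", {
  sch <- make_parcel_scheme(50, 7, seed = 1)
  spins <- spin_permutation_indices(sch, 99, seed = 4)
  a <- simulate_smooth_map(sch, seed = 5)
  st <- spatial_correlation_test(a, a, spins)
  expect_equal(st$r, 1)
  expect_gte(st$p_spin, 1 / 100)  # never below 1/(n_perm + 1)
  b <- simulate_smooth_map(sch, seed = 6)
  st2 <- spatial_correlation_test(a, b, spins)
  st3 <- spatial_correlation_test(2 * a - 5, 0.1 * b + 2, spins)
  expect_equal(st2$p_spin, st3$p_spin)
  expect_equal(abs(st2$r), abs(st3$r), tolerance = 1e-12)
  expect_error(spatial_correlation_test(rep(1, 50), b, spins), "constant")
})

test_that("receptor-type averaging is mean-of-z", {
  sch <- make_parcel_scheme(30, 7, seed = 1)
  m1 <- simulate_smooth_map(sch, seed = 7)
  m2 <- simulate_smooth_map(sch, seed = 8)
  m3 <- simulate_smooth_map(sch, seed = 9)
  avg <- average_receptor_maps(list(a = m1, b = m1), c("t1", "t1"))
  expect_equal(avg$t1, as.vector(scale(m1)))
  opp <- average_receptor_maps(list(a = m1, b = -m1), c("t1", "t1"))
  expect_equal(opp$t1, rep(0, 30))
  three <- average_receptor_maps(list(m1, m2, m3), c("t", "t", "t"))
  brute <- (scale(m1) + scale(m2) + scale(m3)) / 3
  expect_equal(three$t, as.vector(brute), tolerance = 1e-12)
  expect_error(average_receptor_maps(list(m1, m2[1:10]), c("a", "b")),
               "mismatched")
})

test_that("receptor association finds a planted spatial correlate", {
  sch <- make_parcel_scheme(80, 7, seed = 1)
  spins <- spin_permutation_indices(sch, 500, seed = 10)
  tmap <- simulate_smooth_map(sch, seed = 11)
  set.seed(12)
  noisy <- 0.8 * as.vector(scale(tmap)) + sqrt(1 - 0.64) * rnorm(80)
  nulls <- lapply(13:16, function(s) simulate_smooth_map(sch, seed = s))
  rec <- c(list(planted = noisy), setNames(nulls, paste0("null", 1:4)))
  out <- receptor_association(list(t1 = tmap), rec, spins)
  expect_equal(nrow(out), 5)
  expect_lt(out$q[out$receptor == "planted"], .05)
})

test_that("spins on independent smooth maps are not anticonservative", {
  sch <- make_parcel_scheme(100, 7, seed = 1)
  spins <- spin_permutation_indices(sch, 300, seed = 20)
  rej <- vapply(1:80, function(i) {
    a <- simulate_smooth_map(sch, seed = 7000 + 2 * i)
    b <- simulate_smooth_map(sch, seed = 7001 + 2 * i)
    spatial_correlation_test(a, b, spins)$p_spin < .05
  }, logical(1))
  expect_lte(mean(rej), 0.1)
})
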