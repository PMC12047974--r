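# independent dense diffusion-map oracle: literal textbook construction,
# written without reference to the package implementation
oracle_diffusion <- function(w, n_comp, alpha = 0.5) {
  if (min(w) < 0) w <- w + abs(min(w))
  p <- nrow(w)
  d <- rowSums(w)
  w2 <- diag(d^-alpha) %*% w %*% diag(d^-alpha)
  d2 <- rowSums(w2)
  markov <- diag(1 / d2) %*% w2
  e <- eigen(markov)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values)[ord]
  vecs <- Re(e$vectors)[, ord, drop = FALSE]
  # rescale each right eigenvector to the unit-norm symmetric-conjugate
  # convention, then divide by the trivial eigenvector
  for (k in seq_len(ncol(vecs))) {
    vk <- sqrt(d2) * vecs[, k]
    vecs[, k] <- vecs[, k] / sqrt(sum(vk^2))
  }
  psi <- vecs / vecs[, 1]
  out <- psi[, 2:(n_comp + 1), drop = FALSE] *
    rep(vals[2:(n_comp + 1)] / (1 - vals[2:(n_comp + 1)]), each = p)
  for (j in seq_len(ncol(out))) {
    if (out[which.max(abs(out[, j])), j] < 0) out[, j] <- -out[, j]
  }
  out
}

random_affinity <- function(p, seed) {
  set.seed(seed)
  m <- matrix(runif(p * p, 0.05, 1), p)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

test_that("a two-block affinity separates blocks in gradient 1", {
  eps <- 0.01
  w <- matrix(eps, 6, 6)
  w[1:3, 1:3] <- 1
  w[4:6, 4:6] <- 1
  g <- diffusion_embed(w, n_components = 2)
  s <- sign(g$scores[, 1])
  expect_true(all(s[1:3] == s[1]) && all(s[4:6] == -s[1]))
})

test_that("embedding matches the dense oracle on random affinities", {
  for (seed in 1:5) {
    p <- sample(10:50, 1)
    w <- random_affinity(p, seed)
    g <- diffusion_embed(w, n_components = 4)
    o <- oracle_diffusion(w, 4)
    for (j in 1:4) {
      expect_lt(min(max(abs(g$scores[, j] - o[, j])),
                    max(abs(g$scores[, j] + o[, j]))), 1e-6)
    }
  }
})

test_that("explained variance ratios follow the eigenvalue definition", {
  w <- random_affinity(20, 9)
  g <- diffusion_embed(w, n_components = 5)
  expect_equal(g$explained_variance,
               g$eigenvalues / sum(g$eigenvalues), tolerance = 1e-12)
  expect_equal(sum(g$explained_variance), 1, tolerance = 1e-10)
  expect_true(all(diff(g$eigenvalues) <= 1e-12))
  # a (2, 1, 1) spectrum gives ratios (0.5, 0.25, 0.25)
  expect_equal(c(2, 1, 1) / sum(c(2, 1, 1)), c(0.5, 0.25, 0.25))
})

test_that("embedding is deterministic and rejects bad inputs", {
  w <- random_affinity(15, 2)
  expect_identical(diffusion_embed(w, 3), diffusion_embed(w, 3))
  expect_error(diffusion_embed(w, 15), "n_components")
  expect_error(diffusion_embed(w, 3, alpha = 1.5), "alpha")
  expect_error(diffusion_embed(w[1:10, 1:12]), "symmetric")
  block <- matrix(0, 6, 6)
  block[1:3, 1:3] <- 1; block[4:6, 4:6] <- 1
  expect_error(diffusion_embed(block, 2), "disconnected")
})

test_that("column signs put the largest-magnitude score positive", {
  w <- random_affinity(25, 4)
  g <- diffusion_embed(w, n_components = 6)
  for (j in 1:6) {
    expect_gt(g$scores[which.max(abs(g$scores[, j])), j], 0)
  }
})

test_that("Procrustes recovers swaps, sign flips and rotations exactly", {
  w <- random_affinity(30, 7)
  ref <- diffusion_embed(w, n_components = 4)

  # swap columns 1-2 and negate column 1
  perm <- ref
  perm$scores <- ref$scores[, c(2, 1, 3, 4)]
  perm$scores[, 1] <- -perm$scores[, 1]
  out <- procrustes_align(perm, ref)
  expect_equal(out$scores, ref$scores, tolerance = 1e-10, ignore_attr = TRUE)

  # identity
  same <- procrustes_align(ref, ref)
  expect_equal(same$scores, ref$scores, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(same$rotation, diag(4), tolerance = 1e-8)

  # 37-degree rotation in the (g1, g2) plane
  th <- 37 * pi / 180
  rot <- diag(4)
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  spun <- ref
  spun$scores <- ref$scores %*% rot
  back <- procrustes_align(spun, ref)
  for (j in 1:4) {
    expect_equal(cor(back$scores[, j], ref$scores[, j]), 1, tolerance = 1e-10)
  }
  # orthogonality: Frobenius norm unchanged
  expect_equal(sum(back$scores^2), sum(spun$scores^2), tolerance = 1e-10)
  expect_error(procrustes_align(back, ref), "already aligned")
})

test_that("reference construction averages control matrices", {
  sch <- tiny_scheme(30, 7)
  gt <- plant_ground_truth(sch, null_effect_config(), seed = 1)
  fc1 <- compute_fc(synthesize_timeseries(gt, "HC", n_timepoints = 100, seed = 1))
  fc2 <- compute_fc(synthesize_timeseries(gt, "HC", n_timepoints = 100, seed = 2))
  solo <- build_reference(list(fc1), density = 0.2)
  own <- diffusion_embed(cosine_affinity(threshold_rows(fc1, 0.2)))
  expect_equal(solo$scores, own$scores, tolerance = 1e-12)
  dup <- build_reference(list(fc1, fc1), density = 0.2)
  expect_equal(dup$scores, solo$scores, tolerance = 1e-12)
  expect_error(build_reference(list(fc1, fc2[1:10, 1:10])), "mismatch")
})

test_that("aligned gradients recover planted geometry on a small cohort", {
  sch <- make_parcel_scheme(80, 7, seed = 1)
  gt <- plant_ground_truth(sch, null_effect_config(noise_sd = 0.05), seed = 1)
  fc <- lapply(1:8, function(i) {
    compute_fc(synthesize_timeseries(gt, "HC", n_timepoints = 200, seed = 400 + i))
  })
  ref <- build_reference(fc, density = 0.10)
  r <- sapply(fc, function(m) {
    a <- procrustes_align(
      diffusion_embed(cosine_affinity(threshold_rows(m, 0.10))), ref)
    c(abs(cor(a$scores[, 1], gt$latent[, 1])),
      abs(cor(a$scores[, 2], gt$latent[, 2])))
  })
  expect_gt(min(r[1, ]), 0.9)
  expect_gt(min(r[2, ]), 0.9)
})

test_that("explained-variance table is tidy and guards component counts", {
  w1 <- random_affinity(20, 11); w2 <- random_affinity(20, 12)
  g1 <- diffusion_embed(w1, 5); g2 <- diffusion_embed(w2, 5)
  tab <- explained_variance_table(list(a = g1, b = g2))
  expect_equal(names(tab), c("subject_id", "ev_g1", "ev_g2"))
  expect_true(all(tab$ev_g1 >= 0 & tab$ev_g1 <= 1))
  expect_equal(tab$ev_g1[1], g1$explained_variance[1])
  g3 <- diffusion_embed(w2, 3)
  expect_error(explained_variance_table(list(g1, g3)), "different component")
})

test_that("gradient labels track the network contrasts they are named for", {
  sch <- make_parcel_scheme(70, 7, seed = 1)
  net <- as.character(sch$network)
  fake <- list(scores = cbind(
    (net == "VN") - (net == "SMN") + rnorm(70, sd = 0.01),
    (net %in% c("VN", "SMN")) - (net %in% c("DMN", "CN")) + rnorm(70, sd = 0.01)))
  expect_equal(label_gradients(fake, sch),
               c("visual-to-sensorimotor", "association-to-sensory"))
})
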