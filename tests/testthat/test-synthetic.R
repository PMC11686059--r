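test_that("parcellations are near-balanced, named, and seeded", {
  p <- make_parcellation(229, 10, seed = 1)
  sizes <- table(p$network_label)
  expect_setequal(names(sizes), ne_networks(10))
  expect_true(all(sizes %in% c(22, 23)))
  p2 <- make_parcellation(9, 3, seed = 2)
  expect_true(all(table(p2$network_label) == 3))
  expect_identical(make_parcellation(50, 5, seed = 7),
                   make_parcellation(50, 5, seed = 7))
  expect_false(identical(make_parcellation(50, 5, seed = 7)$network_label,
                         make_parcellation(50, 5, seed = 8)$network_label))
  expect_error(make_parcellation(8, 3), ">= 3 regions")
})

test_that("simulated matrices are valid signed correlation matrices", {
  p <- synthetic_params(n_subjects = 1, n_regions = 40, n_networks = 5,
                        t_points = 100, seed = 1)
  m <- simulate_fc(p, "rest", seed = 3)
  w <- m$weights
  expect_identical(w, t(w))
  expect_equal(diag(w), rep(0, 40), ignore_attr = TRUE)
  expect_true(all(w >= -1 & w <= 1))
  expect_true(any(w < 0))                      # anti-correlated pairs exist
  # deterministic given the seed
  expect_identical(simulate_fc(p, "rest", seed = 3)$weights, w)
})

test_that("the coherent single-network limit approaches U = -1", {
  p <- synthetic_params(n_subjects = 1, n_regions = 10, n_networks = 1,
                        t_points = 100, noise_sd = 1e-6,
                        conflict_kappa = flat_kappa(0), seed = 1)
  m <- simulate_fc(p, "rest", seed = 5)
  expect_gt(min(m$weights[upper.tri(m$weights)]), 0.999)
  expect_lt(network_energy(m), -0.999)
})

test_that("median energy rises strictly with the conflict probability", {
  p <- synthetic_params(n_subjects = 1, n_regions = 50, n_networks = 5,
                        t_points = 150, seed = 1)
  med <- vapply(c(0, 0.25, 0.5), function(k) {
    us <- vapply(1:20, function(s)
      network_energy(simulate_fc(p, "rest", seed = 8000 + s, kappa = k)),
      numeric(1))
    stats::median(us)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("cohorts have the right shape and are reproducible", {
  prm <- synthetic_params(n_subjects = 4, n_regions = 30, n_networks = 3,
                          t_points = 80, seed = 9)
  co <- generate_cohort(prm)
  expect_equal(nrow(co$subjects), 4)
  expect_true(all(co$subjects$age >= 20 & co$subjects$age <= 86))
  expect_equal(sum(lengths(co$matrices)), 4 * 7)
  for (m in co$matrices[[1]])
    expect_s3_class(m, "connectivity_matrix")
  co2 <- generate_cohort(prm)
  expect_identical(co$matrices$sub001$rest$weights,
                   co2$matrices$sub001$rest$weights)
  expect_identical(co$subjects$age, co2$subjects$age)
})

test_that("without an age effect, energy is uncorrelated with age", {
  prm <- synthetic_params(n_subjects = 20, n_regions = 40, n_networks = 4,
                          t_points = 100, age_effect_beta = 0, seed = 10)
  co <- generate_cohort(prm)
  u <- vapply(co$matrices, function(s) network_energy(s$rest), numeric(1))
  expect_lt(abs(stats::cor(co$subjects$age, u)), 0.45)
  # with a strong age effect the correlation appears
  prm2 <- synthetic_params(n_subjects = 20, n_regions = 40, n_networks = 4,
                           t_points = 100, age_effect_beta = 0.004,
                           seed = 10)
  co2 <- generate_cohort(prm2)
  u2 <- vapply(co2$matrices, function(s) network_energy(s$rest), numeric(1))
  expect_gt(stats::cor(co2$subjects$age, u2), 0.5)
})

test_that("reparcellation shares latents and supports reliability analysis", {
  # region counts must be large enough that the shared latent component
  # dominates region-level sampling noise in U (it does from ~150 up;
  # the acceptance suite exercises the realistic 229/200 pairing)
  prm <- synthetic_params(n_subjects = 12, n_regions = 150, n_networks = 5,
                          t_points = 150, seed = 11)
  co <- generate_cohort(prm)
  cb <- reparcellate(co, 140, seed = 12)
  uA <- vapply(co$matrices, function(s) network_energy(s$rest), numeric(1))
  uB <- vapply(cb$matrices, function(s) network_energy(s$rest), numeric(1))
  expect_gt(stats::cor(uA, uB), 0.7)
  # independent latents decouple the pair
  ci <- reparcellate(co, 150, seed = 14, independent = TRUE)
  uI <- vapply(ci$matrices, function(s) network_energy(s$rest), numeric(1))
  expect_lt(abs(stats::cor(uA, uI)), 0.6)
  co$latents <- NULL
  expect_error(reparcellate(co, 150, seed = 15), "latent")
})
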