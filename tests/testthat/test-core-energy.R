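test_that("signed_cbrt is the real cube root and multiplicative", {
  expect_identical(signed_cbrt(0.125), 0.5)
  expect_identical(signed_cbrt(-1), -1)
  expect_identical(signed_cbrt(0), 0)
  set.seed(1)
  x <- runif(50, -2, 2); y <- runif(50, -2, 2); z <- runif(50, -2, 2)
  expect_equal(signed_cbrt(x * y * z),
               signed_cbrt(x) * signed_cbrt(y) * signed_cbrt(z),
               tolerance = 1e-12)
  expect_error(signed_cbrt(NaN), "finite")
  expect_error(signed_cbrt(Inf), "finite")
})

complete_matrix <- function(n, w = 1) {
  m <- matrix(w, n, n); diag(m) <- 0; m
}

test_that("network energy attains its analytic values on small networks", {
  expect_equal(network_energy(complete_matrix(3, 1)), -1)
  expect_equal(network_energy(complete_matrix(3, -1)), 1)
  expect_equal(network_energy(complete_matrix(3, 0.5)), -0.5)
  expect_equal(network_energy(complete_matrix(4, 1)), -1)
  # single imbalanced triangle: one negative edge
  w <- complete_matrix(3, 1); w[1, 2] <- w[2, 1] <- -1
  expect_equal(network_energy(w), 1)
  expect_equal(brute_force_energy(complete_matrix(3, 1)), -1)
  expect_equal(brute_force_energy(complete_matrix(5, -1)), 1)
})

test_that("trace-based energy matches enumeration oracles on random matrices", {
  # pure-R oracle on a handful of sizes (slow path), C++ enumeration on more
  for (n in c(3, 7, 12, 20)) {
    w <- rand_sym_matrix(n, seed = 100 + n)
    u <- network_energy(w)
    expect_equal(u, oracle_energy(w), tolerance = 1e-10)
    expect_equal(u, brute_force_energy(w), tolerance = 1e-10)
  }
  for (s in 1:20) {
    n <- sample(3:40, 1)
    w <- rand_sym_matrix(n, seed = 900 + s)
    expect_equal(network_energy(w), brute_force_energy(w), tolerance = 1e-10)
  }
})

test_that("matrix validation enforces the container invariants", {
  expect_error(connectivity_matrix(matrix(0, 2, 2)), "3 regions")
  w <- rand_sym_matrix(5, 1); w[1, 2] <- w[1, 2] + 1e-3
  expect_error(connectivity_matrix(w), "asymmetry")
  w2 <- rand_sym_matrix(5, 2); w2[1, 3] <- w2[3, 1] <- NA
  expect_error(connectivity_matrix(w2), "non-finite")
  w3 <- rand_sym_matrix(5, 3); w3[2, 4] <- w3[4, 2] <- 1.7
  expect_error(connectivity_matrix(w3), "\\[-1, 1\\]")
  expect_silent(connectivity_matrix(w3, allow_out_of_range = TRUE))
  # correlation-style diagonal is zeroed on ingest
  w4 <- rand_sym_matrix(5, 4); diag(w4) <- 1
  expect_equal(diag(connectivity_matrix(w4)$weights), rep(0, 5),
               ignore_attr = TRUE)
  # sub-tolerance asymmetry is symmetrised by averaging
  w5 <- rand_sym_matrix(4, 5); w5[1, 2] <- w5[1, 2] + 1e-10
  m5 <- connectivity_matrix(w5)
  expect_identical(m5$weights, t(m5$weights))
})

test_that("energy invariants: bounds, scaling, sign flip, relabeling", {
  for (s in 1:25) {
    n <- sample(3:40, 1)
    w <- rand_sym_matrix(n, seed = 3000 + s)
    u <- network_energy(w)
    expect_true(u >= -1 && u <= 1)
    c0 <- runif(1, 0.1, 1)
    expect_equal(network_energy(c0 * w), c0 * u, tolerance = 1e-12)
    expect_equal(network_energy(-w), -u, tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(network_energy(w[perm, perm]), u, tolerance = 1e-12)
  }
})

test_that("triangle census classifies and sums consistently with energy", {
  cen <- triangle_census(complete_matrix(4, 1))
  expect_equal(cen$n_balanced, 4)
  expect_equal(cen$n_imbalanced, 0)
  w <- complete_matrix(3, 1); w[1, 2] <- w[2, 1] <- -1
  cen2 <- triangle_census(w)
  expect_equal(cen2$n_balanced, 0)
  expect_equal(cen2$n_imbalanced, 1)
  # zero-product triangles are counted as neither
  w0 <- complete_matrix(3, 1); w0[1, 2] <- w0[2, 1] <- 0
  cen0 <- triangle_census(w0)
  expect_equal(cen0$n_balanced + cen0$n_imbalanced, 0)

  w15 <- rand_sym_matrix(15, seed = 7)
  cen3 <- triangle_census(w15)
  orc <- oracle_census(w15)
  expect_equal(cen3$n_balanced, orc$n_balanced)
  expect_equal(cen3$n_imbalanced, orc$n_imbalanced)
  expect_equal(cen3$intensity_balanced, orc$intensity_balanced,
               tolerance = 1e-10)
  expect_equal(cen3$intensity_imbalanced, orc$intensity_imbalanced,
               tolerance = 1e-10)
  expect_equal(-(cen3$intensity_balanced - cen3$intensity_imbalanced) /
                 cen3$n_triangles,
               network_energy(w15), tolerance = 1e-10)
})

test_that("sub-network energy equals energy of the sliced submatrix", {
  p <- make_parcellation(30, 3, seed = 5)
  w <- rand_sym_matrix(30, seed = 6)
  m <- connectivity_matrix(w, region_ids = p$region_id)
  expect_equal(subnetwork_energy(m, p, whole_brain()), network_energy(m))
  for (net in unique(p$network_label)) {
    keep <- m$region_ids %in% p$region_id[p$network_label == net]
    expect_equal(subnetwork_energy(m, p, net),
                 oracle_energy(w[keep, keep]), tolerance = 1e-10)
  }
  # an all-positive 3-region clique inside a larger matrix scores -1
  p6 <- parcellation(sprintf("R%03d", 1:6), c("A", "A", "A", "B", "B", "B"))
  w6 <- rand_sym_matrix(6, seed = 8)
  w6[1:3, 1:3] <- 1; diag(w6) <- 0
  expect_equal(subnetwork_energy(connectivity_matrix(w6), p6, "A"), -1)
  expect_error(subnetwork_energy(connectivity_matrix(w6), p6, "ZZZ"), "ZZZ")
  p_small <- parcellation(sprintf("R%03d", 1:6),
                          c("A", "A", "A", "A", "B", "B"))
  expect_error(subnetwork_energy(connectivity_matrix(w6), p_small, "B"), "B")
})

test_that("energy_delta is the endpoint difference", {
  expect_equal(energy_delta(-0.2, -0.4), 0.2)
  expect_equal(energy_delta(0.3, 0.3), 0)
  expect_equal(energy_delta(0.1, -0.2), -energy_delta(-0.2, 0.1))
  expect_error(energy_delta(NA, 0), "finite")
})

test_that("energy_table produces one record per subject x condition x scope", {
  co <- small_cohort()
  # 2 subjects restricted, 7 conditions, 1 + 5 scopes
  sub2 <- co$matrices[1:2]
  et <- energy_table(sub2, co$parcellation)
  expect_equal(nrow(et), 2 * 7 * 6)
  expect_true(all(et$U >= -1 & et$U <= 1))
  expect_true(all(is.na(et$dU[et$condition == "rest"])))
  expect_true(all(!is.na(et$dU[et$condition != "rest"])))
  # identical matrices across conditions give all-zero deltas
  m <- sub2[[1]][["rest"]]
  same <- list(subjA = stats::setNames(rep(list(m), 7), ne_conditions()))
  et2 <- energy_table(same, co$parcellation, scopes = whole_brain())
  expect_equal(et2$dU[et2$condition != "rest"], rep(0, 6))
  # missing rest errors and names the subject
  norest <- list(subjX = sub2[[1]][c("nback0", "shifting")])
  expect_error(energy_table(norest, co$parcellation), "subjX")
  expect_silent(energy_table(norest, co$parcellation, delta = FALSE))
})

test_that("condition-dependent coherence raises task energy above rest", {
  co <- small_cohort()
  et <- energy_table(co, co$parcellation, scopes = whole_brain())
  dblk <- energy_block(et, value = "dU")
  expect_true(all(apply(dblk, 2, stats::median) > 0))
})
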