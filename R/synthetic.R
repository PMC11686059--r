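# Synthetic cohort generator: signed FC-like correlation matrices with
# community structure over canonical networks, controllable triangle
# imbalance, condition effects, and an age covariate.
#
# Imbalance mechanism. Flipping the overall sign (polarity) of a
# region's signal is a gauge transformation: every triangle product
# picks up (s_i s_j s_k)^2 = 1, so polarity flips cannot change balance
# or energy. Frustrated (imbalanced) triads are instead planted by
# letting a "conflict" region load on its network's two latent signals
# at a 120-degree phase angle: correlations behave like cos of angle
# differences, and three regions at mutually distinct angles in
# {0, 120, 240} degrees give a negative triangle product
# (cos 120)^3 = -1/8 while the output remains a true correlation matrix
# (positive semidefinite). `conflict_kappa` is the per-region
# probability of adopting a conflict phase; kappa = 0 yields
# sign-coherent blocks and strongly negative energy, larger kappa moves
# energy toward 0.

#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate the shape of the cognitive-control FC dataset the
#' pipeline targets: 229 regions over ten canonical networks, seven
#' conditions per subject, ages 20-86, with rest the most coherent
#' (lowest-energy) condition and the shifting task intermediate between
#' rest and the other tasks.
#'
#' @param n_subjects Number of subjects.
#' @param n_regions Regions per matrix (default 229).
#' @param n_networks Canonical networks (default 10; labelled via
#'   [ne_networks()]).
#' @param t_points Latent time-series length (default 200) from which
#'   Pearson correlations are computed; controls sampling noise of the
#'   correlations.
#' @param conflict_kappa Named vector over [ne_conditions()]: per-region
#'   probability of adopting a conflicting phase, in \eqn{[0, 1]}.
#'   Drives the planted triangle imbalance and hence the energy level.
#' @param within_coupling Coupling of a region to its own network's
#'   latent signal, in (0, 1).
#' @param cross_coupling Coupling to the fixed signed cross-network
#'   mixing matrix (includes anti-correlated network pairs, so negative
#'   edges exist even at kappa = 0).
#' @param noise_sd Regional noise standard deviation (> 0) relative to a
#'   unit-variance latent signal.
#' @param age_range Uniform age range in years.
#' @param age_effect_beta Linear shift of kappa per year of age relative
#'   to the midpoint of `age_range` (0 = no age effect).
#' @param seed Integer root seed; the whole cohort is reproducible from
#'   it.
#' @return Validated list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_subjects,
                             n_regions = 229L,
                             n_networks = 10L,
                             t_points = 200L,
                             conflict_kappa = c(nback0 = 0.25, nback1 = 0.25,
                                                nback2 = 0.25,
                                                gng_initiation = 0.25,
                                                gng_inhibition = 0.25,
                                                shifting = 0.15, rest = 0.05),
                             within_coupling = 0.9,
                             cross_coupling = 0.35,
                             noise_sd = 1,
                             age_range = c(20, 86),
                             age_effect_beta = 0,
                             seed = 1L) {
  stopifnot(n_subjects >= 1, n_regions >= 3, n_networks >= 1)
  if (t_points <= n_networks)
    stop("t_points must exceed n_networks")
  if (is.null(names(conflict_kappa)) ||
      !all(ne_conditions() %in% names(conflict_kappa)))
    stop("conflict_kappa must be named over all conditions: ",
         paste(ne_conditions(), collapse = ", "))
  if (any(conflict_kappa < 0 | conflict_kappa > 1))
    stop("conflict_kappa values must lie in [0, 1]")
  if (within_coupling <= 0 || within_coupling >= 1)
    stop("within_coupling must lie in (0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (length(age_range) != 2L || diff(age_range) < 0)
    stop("age_range must be an ordered pair")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_regions = as.integer(n_regions),
                 n_networks = as.integer(n_networks),
                 t_points = as.integer(t_points),
                 conflict_kappa = conflict_kappa[ne_conditions()],
                 within_coupling = within_coupling,
                 cross_coupling = cross_coupling,
                 noise_sd = noise_sd,
                 age_range = as.numeric(age_range),
                 age_effect_beta = age_effect_beta,
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

#' Near-balanced random parcellation
#'
#' Assigns `n_regions` regions to `n_networks` named networks with
#' sizes differing by at most one, in seeded random order.
#'
#' @param n_regions Total regions (>= 3 per network).
#' @param n_networks Number of networks (>= 2 for a meaningful
#'   parcellation; 1 is allowed for single-block simulations).
#' @param seed Integer seed.
#' @return A [parcellation()].
#' @export
make_parcellation <- function(n_regions, n_networks = 10L, seed = 1L) {
  if (n_regions < 3L * n_networks)
    stop(sprintf("n_regions = %d cannot give every one of %d networks >= 3 regions",
                 n_regions, n_networks))
  labels <- ne_networks(n_networks)
  base <- rep(labels, length.out = n_regions)     # sizes differ by <= 1
  rng <- local_rng(seed)
  assignment <- rng(function() sample(base))
  parcellation(sprintf("R%03d", seq_len(n_regions)), assignment,
               atlas_name = sprintf("synthetic-%d", n_regions))
}

# fixed signed cross-network mixing matrix: alternating-sign coupling,
# so anti-correlated network pairs exist at kappa = 0
mixing_matrix <- function(n_networks) {
  idx <- seq_len(n_networks)
  m <- 0.5 * outer(idx, idx, function(a, b) (-1)^(a + b))
  diag(m) <- 0
  m
}

# core generator; assumes the RNG is already positioned. `latents` may
# carry G/H from a previous draw (shared-latents reparcellation).
simulate_fc_core <- function(p, parc, kappa, subject_id, condition,
                             latents = NULL) {
  nets <- ne_networks(p$n_networks)
  net_idx <- match(parc$network_label, nets)
  tp <- p$t_points
  if (is.null(latents)) {
    latents <- list(G = matrix(stats::rnorm(tp * p$n_networks), tp),
                    H = matrix(stats::rnorm(tp * p$n_networks), tp))
  }
  G <- latents$G; H <- latents$H
  n <- nrow(parc)
  conflict <- stats::runif(n) < kappa
  phase_sign <- sample(c(-1, 1), n, replace = TRUE)
  theta <- ifelse(conflict, phase_sign * 2 * pi / 3, 0)
  cross_term <- G %*% mixing_matrix(p$n_networks)
  u <- G[, net_idx, drop = FALSE] * rep(cos(theta), each = tp) +
       H[, net_idx, drop = FALSE] * rep(sin(theta), each = tp)
  x <- p$within_coupling * u +
       p$cross_coupling * cross_term[, net_idx, drop = FALSE] +
       p$noise_sd * matrix(stats::rnorm(tp * n), tp)
  s <- stats::cor(x)
  diag(s) <- 0
  list(matrix = connectivity_matrix(s, region_ids = parc$region_id,
                                    subject_id = subject_id,
                                    condition = condition),
       latents = latents)
}

#' Simulate one signed FC matrix
#'
#' Draws latent per-network signals, assigns each region a coherent or
#' conflicting phase with probability `kappa`, mixes in the fixed
#' signed cross-network coupling, adds regional noise, and returns the
#' region-wise Pearson correlation matrix (zero diagonal). See the file
#' header of the synthetic module for why conflict phases, not polarity
#' flips, are the imbalance mechanism.
#'
#' @param p A [synthetic_params()].
#' @param condition Condition label; its entry of `p$conflict_kappa` is
#'   used unless `kappa` is given.
#' @param seed Integer seed for this matrix.
#' @param kappa Optional explicit conflict probability overriding the
#'   condition's.
#' @param parc Optional [parcellation()]; default
#'   `make_parcellation(p$n_regions, p$n_networks, seed)`.
#' @param subject_id Subject label to attach.
#' @return A [connectivity_matrix()] with the generating latents in
#'   `attr(, "latents")`.
#' @export
simulate_fc <- function(p, condition = "rest", seed = 1L, kappa = NULL,
                        parc = NULL, subject_id = "sim") {
  stopifnot(inherits(p, "synthetic_params"))
  if (!condition %in% ne_conditions()) stop("unknown condition: ", condition)
  if (is.null(kappa)) kappa <- unname(p$conflict_kappa[condition])
  if (is.null(parc)) parc <- make_parcellation(p$n_regions, p$n_networks, seed)
  rng <- local_rng(seed)
  res <- rng(function()
    simulate_fc_core(p, parc, kappa, subject_id, condition))
  out <- res$matrix
  attr(out, "latents") <- res$latents
  out
}

#' Generate a full synthetic cohort
#'
#' Ages are drawn uniformly from `p$age_range`; each subject receives
#' the seven condition matrices with condition-specific conflict
#' probability (rest lowest by default, so whole-brain energy is lowest
#' at rest), optionally shifted linearly with age. Latent signals are
#' retained per subject x condition so that [reparcellate()] can build a
#' paired cohort for reliability analysis. Fully reproducible from
#' `p$seed`.
#'
#' @param p A [synthetic_params()].
#' @return List of class `synthetic_cohort`: `params`, `parcellation`,
#'   `subjects` (data.frame id, age), `matrices`
#'   (`[[subject]][[condition]]`), `kappa` (realised per-matrix conflict
#'   probability), `latents`.
#' @export
generate_cohort <- function(p) {
  stopifnot(inherits(p, "synthetic_params"))
  rng <- local_rng(p$seed)
  rng(function() {
    parc <- make_parcellation(p$n_regions, p$n_networks,
                              seed = stats::runif(1) * 1e6)
    ages <- stats::runif(p$n_subjects, p$age_range[1], p$age_range[2])
    ids <- sprintf("sub%03d", seq_len(p$n_subjects))
    mid_age <- mean(p$age_range)
    matrices <- list(); latents <- list()
    kap <- matrix(NA_real_, p$n_subjects, length(ne_conditions()),
                  dimnames = list(ids, ne_conditions()))
    for (i in seq_len(p$n_subjects)) {
      for (cond in ne_conditions()) {
        kc <- p$conflict_kappa[cond] +
          p$age_effect_beta * (ages[i] - mid_age)
        kc <- min(1, max(0, kc))
        kap[i, cond] <- kc
        res <- simulate_fc_core(p, parc, kc, ids[i], cond)
        matrices[[ids[i]]][[cond]] <- res$matrix
        latents[[ids[i]]][[cond]] <- res$latents
      }
    }
    structure(list(params = p, parcellation = parc,
                   subjects = data.frame(subject_id = ids, age = ages,
                                         stringsAsFactors = FALSE),
                   matrices = matrices, kappa = kap, latents = latents),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects x %d conditions, %d regions / %d networks (seed %d)\n",
              nrow(x$subjects), length(ne_conditions()),
              x$params$n_regions, x$params$n_networks, x$params$seed))
  invisible(x)
}

#' Re-parcellate a cohort from its shared latent signals
#'
#' Builds a paired cohort under a second parcellation (typically a
#' different region count) by re-sampling region-level signals from the
#' \emph{same} latent network signals, with freshly drawn region phases
#' and noise. The pair emulates two atlases applied to the same
#' underlying brain activity and is the input for the ICC reliability
#' analysis. Pass `independent = TRUE` to redraw the latents as well
#' (null pairing; ICC should be near 0).
#'
#' @param cohort A [generate_cohort()] result (latents retained).
#' @param n_regions_b Region count of the second parcellation.
#' @param seed Integer seed for the re-sampling.
#' @param independent Redraw latents instead of sharing them.
#' @return A new `synthetic_cohort` under the second parcellation.
#' @export
reparcellate <- function(cohort, n_regions_b, seed = 1L,
                         independent = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$latents) || length(cohort$latents) == 0L)
    stop("cohort carries no latent signals; regenerate with generate_cohort()")
  p <- cohort$params
  p2 <- p
  p2$n_regions <- as.integer(n_regions_b)
  rng <- local_rng(seed)
  rng(function() {
    parc <- make_parcellation(n_regions_b, p$n_networks,
                              seed = stats::runif(1) * 1e6)
    matrices <- list(); latents <- list()
    for (sid in cohort$subjects$subject_id) {
      for (cond in ne_conditions()) {
        lat <- if (independent) NULL else cohort$latents[[sid]][[cond]]
        res <- simulate_fc_core(p2, parc, cohort$kappa[sid, cond],
                                sid, cond, latents = lat)
        matrices[[sid]][[cond]] <- res$matrix
        latents[[sid]][[cond]] <- res$latents
      }
    }
    structure(list(params = p2, parcellation = parc,
                   subjects = cohort$subjects, matrices = matrices,
                   kappa = cohort$kappa, latents = latents),
              class = "synthetic_cohort")
  })
}
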