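# Shared synthetic fixtures, built once per test run and cached.
# Scales are kept small: region counts and time series lengths are
# reduced relative to the 229-region default so the suite stays fast;
# the acceptance tests use larger, criterion-stated scales.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

flat_kappa <- function(k) stats::setNames(rep(k, 7L), ne_conditions())

# small coherent cohort, condition effect present (rest most coherent)
small_cohort <- function() fixture("small_cohort", function() {
  kap <- flat_kappa(0.25); kap["rest"] <- 0.05; kap["shifting"] <- 0.15
  generate_cohort(synthetic_params(
    n_subjects = 6, n_regions = 40, n_networks = 5, t_points = 120,
    conflict_kappa = kap, seed = 42))
})

# no-condition-effect cohort for null/chance checks
null_cohort <- function() fixture("null_cohort", function() {
  generate_cohort(synthetic_params(
    n_subjects = 10, n_regions = 60, n_networks = 6, t_points = 150,
    conflict_kappa = flat_kappa(0.2), seed = 505))
})

# strongly separable cohort: the low-noise, large-effect limit
separable_cohort <- function() fixture("separable_cohort", function() {
  generate_cohort(synthetic_params(
    n_subjects = 12, n_regions = 229, n_networks = 10, t_points = 500,
    within_coupling = 0.95, cross_coupling = 0.3, noise_sd = 0.2,
    conflict_kappa = c(nback0 = 0.6, nback1 = 0.6, nback2 = 0.6,
                       gng_initiation = 0.9, gng_inhibition = 0.9,
                       shifting = 0.3, rest = 0.02),
    seed = 404))
})

separable_report <- function() fixture("separable_report", function() {
  co <- separable_cohort()
  et <- energy_table(co, co$parcellation)
  ft <- build_features(et, task = "classify_state", subset = "NE")
  classify_states(ft, seed = 11)
})

# fabricated long-format energy table (no simulation; plumbing tests)
fake_energy_table <- function(n_subjects, n_networks = 10, seed = 1) {
  set.seed(seed)
  scopes <- c(whole_brain(), ne_networks(n_networks))
  grid <- expand.grid(subject_id = sprintf("s%02d", seq_len(n_subjects)),
                      condition = ne_conditions(), scope = scopes,
                      stringsAsFactors = FALSE)
  grid$U <- stats::runif(nrow(grid), -0.5, 0)
  grid
}

fake_measures_table <- function(n_subjects, n_networks = 10, seed = 2) {
  set.seed(seed)
  scopes <- c(whole_brain(), ne_networks(n_networks))
  grid <- expand.grid(subject_id = sprintf("s%02d", seq_len(n_subjects)),
                      condition = ne_conditions(), scope = scopes,
                      stringsAsFactors = FALSE)
  grid$gcc <- stats::runif(nrow(grid))
  grid$ge <- stats::runif(nrow(grid))
  grid$gm <- stats::runif(nrow(grid), -0.1, 0.6)
  grid
}
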