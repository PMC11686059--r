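# End-to-end orchestration: energies -> nulls -> graph measures ->
# statistics -> (optional) predictive models, with a checksummed
# artifact manifest. All randomness flows from a single root seed,
# split per stage, so a rerun with the same seed is byte-identical.

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

seed_for_stage <- function(root_seed, stage) {
  offsets <- c(energies = 0L, nulls = 1000L, measures = 2000L,
               stats = 3000L, ml = 4000L, simulate = 5000L)
  as.integer(root_seed) + offsets[[stage]]
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a cohort of connectivity matrices: energy
#' table with rest-to-task deltas, whole-brain null ensembles,
#' comparator graph measures, Friedman + pairwise Wilcoxon +
#' actual-vs-null statistics, optional state classification and age
#' regression, and a manifest listing every artifact with its MD5
#' checksum. Stages are independent where possible: a failure (e.g. a
#' missing rest condition breaking the delta computation) is recorded
#' in the manifest and later independent stages still run.
#'
#' @param cohort Nested list `[[subject]][[condition]]` of
#'   [connectivity_matrix()] objects, a [generate_cohort()] result, or
#'   `NULL` with `matrices_dir` given.
#' @param p A [parcellation()] (taken from a synthetic cohort
#'   automatically).
#' @param out_dir Output directory (created if needed).
#' @param matrices_dir Directory of `<subject>_<condition>.csv` files,
#'   used when `cohort` is NULL.
#' @param seed Root seed.
#' @param n_perms Surrogates per network for the null stage.
#' @param scheme Null randomisation scheme ([permute_weights()]).
#' @param correction Multiplicity correction for pairwise tests.
#' @param scopes Scopes for the energy/measure tables (default all).
#' @param ml Run the predictive-modelling stage.
#' @param ages data.frame (`subject_id`, `age`) enabling age
#'   regression; taken from a synthetic cohort automatically.
#' @return Invisibly, the manifest list (`artifacts`, `errors`,
#'   `seed`).
#' @export
run_full_pipeline <- function(cohort = NULL, p = NULL, out_dir,
                              matrices_dir = NULL, seed = 1L,
                              n_perms = 1L, scheme = "weight-permute",
                              correction = "holm", scopes = NULL,
                              ml = FALSE, ages = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  errors <- list()
  note <- function(path) artifacts <<- c(artifacts, path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      message(sprintf("[pipeline] stage '%s' failed: %s", name,
                      conditionMessage(e)))
      NULL
    })
  }

  if (is.null(cohort)) {
    if (is.null(matrices_dir)) stop("need a cohort or matrices_dir")
    cohort <- read_matrix_dir(matrices_dir)
  }
  if (inherits(cohort, "synthetic_cohort")) {
    if (is.null(p)) p <- cohort$parcellation
    if (is.null(ages)) ages <- cohort$subjects
    cohort <- cohort$matrices
  }
  if (is.null(p)) stop("a parcellation is required")

  # -- energies (deltas degrade gracefully to plain energies) ---------
  etab <- stage("energies_delta", energy_table(cohort, p, scopes = scopes,
                                               delta = TRUE))
  if (is.null(etab))
    etab <- stage("energies", energy_table(cohort, p, scopes = scopes,
                                           delta = FALSE))
  if (!is.null(etab)) {
    note(write_csv_plain(etab, file.path(out_dir, "energies.csv")))
    if ("dU" %in% names(etab))
      note(write_csv_plain(etab[!is.na(etab$dU), ],
                           file.path(out_dir, "deltas.csv")))
  }

  # -- null ensembles (whole brain) -----------------------------------
  ntab <- stage("nulls", {
    s0 <- seed_for_stage(seed, "nulls")
    rows <- list(); i <- 0L
    for (sid in names(cohort)) for (cond in names(cohort[[sid]])) {
      i <- i + 1L
      m <- cohort[[sid]][[cond]]
      ens <- null_energy_ensemble(m, n_perms = n_perms,
                                  base_seed = s0 + i * 10000L,
                                  scheme = scheme)
      rows[[i]] <- data.frame(subject_id = sid, condition = cond,
                              actual_U = network_energy(m),
                              perm = seq_len(n_perms), seed = ens$seeds,
                              null_U = ens$null_energies,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  if (!is.null(ntab))
    note(write_csv_plain(ntab, file.path(out_dir, "nulls.csv")))

  # -- graph measures -------------------------------------------------
  mtab <- stage("measures",
                measures_table(cohort, p, scopes = scopes,
                               seed = seed_for_stage(seed, "measures")))
  if (!is.null(mtab))
    note(write_csv_plain(mtab, file.path(out_dir, "measures.csv")))

  # -- statistics -----------------------------------------------------
  if (!is.null(etab)) stage("stats", {
    blk <- energy_block(etab, scope = whole_brain())
    fr <- friedman_test(blk)
    note(write_csv_plain(
      data.frame(scope = whole_brain(), statistic = fr$statistic,
                 df = fr$df, p = fr$p.value),
      file.path(out_dir, "friedman.csv")))
    note(write_csv_plain(pairwise_wilcoxon(blk, method = correction),
                         file.path(out_dir, "pairwise.csv")))
    if (!is.null(ntab)) {
      nt <- lapply(intersect(ne_conditions(), unique(ntab$condition)),
                   function(cond) {
        d <- ntab[ntab$condition == cond, ]
        nm <- tapply(d$null_U, d$subject_id, stats::median)
        act <- tapply(d$actual_U, d$subject_id, unique)
        res <- actual_vs_null_test(as.numeric(act), as.numeric(nm))
        data.frame(condition = cond, statistic = res$statistic,
                   p = res$p.value, direction = res$direction,
                   stringsAsFactors = FALSE)
      })
      note(write_csv_plain(do.call(rbind, nt),
                           file.path(out_dir, "nulltest.csv")))
    }
  })

  # -- predictive models ----------------------------------------------
  if (ml && !is.null(etab) && !is.null(mtab)) stage("ml", {
    s_ml <- seed_for_stage(seed, "ml")
    ftc <- build_features(etab, mtab, task = "classify_state")
    rep_c <- classify_states(ftc, seed = s_ml)
    note(write_csv_plain(as.data.frame.matrix(rep_c$confusion),
                         file.path(out_dir, "confusion.csv")))
    report <- list(balanced_accuracy = rep_c$balanced_accuracy,
                   per_class_accuracy = as.list(rep_c$per_class_accuracy),
                   tuned_C = as.list(rep_c$tuned_C), seed = s_ml)
    if (!is.null(ages)) {
      ftr <- build_features(etab, mtab, task = "predict_age", ages = ages)
      rep_r <- predict_age(ftr, seed = s_ml)
      report$regression <- list(r2 = rep_r$r2, r2_sse = rep_r$r2_sse,
                                mae = rep_r$mae)
      note(write_csv_plain(rep_r$predictions,
                           file.path(out_dir, "age_predictions.csv")))
    }
    jsonlite::write_json(report, file.path(out_dir, "ml_report.json"),
                         auto_unbox = TRUE, digits = NA)
    note(file.path(out_dir, "ml_report.json"))
  })

  manifest <- list(
    seed = as.integer(seed),
    artifacts = lapply(artifacts, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))),
    errors = errors)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Reshape an energy table into a subjects x conditions block
#'
#' @param etab An [energy_table()] data.frame.
#' @param scope Scope to extract (default whole brain).
#' @param value Column to spread (`"U"` or `"dU"`).
#' @return Numeric matrix, rows = subjects, columns = conditions in
#'   [ne_conditions()] order (dropping conditions absent from the
#'   table, and rest when `value = "dU"`).
#' @export
energy_block <- function(etab, scope = whole_brain(), value = "U") {
  d <- etab[etab$scope == scope, ]
  conds <- intersect(ne_conditions(), unique(d$condition))
  if (value == "dU") conds <- setdiff(conds, "rest")
  subjects <- sort(unique(d$subject_id))
  blk <- matrix(NA_real_, length(subjects), length(conds),
                dimnames = list(subjects, conds))
  for (i in seq_len(nrow(d))) {
    if (d$condition[i] %in% conds)
      blk[d$subject_id[i], d$condition[i]] <- d[[value]][i]
  }
  if (any(is.na(blk)))
    stop("incomplete block: missing (subject, condition) cells for scope ",
         scope)
  blk
}

#' Write a synthetic cohort to disk in the pipeline's input format
#'
#' One `<subject>_<condition>.csv` per matrix, a parcellation TSV,
#' subject metadata CSV, and a provenance JSON with parameters and
#' seed.
#'
#' @param cohort A [generate_cohort()] result.
#' @param out_dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$matrices))
    for (cond in names(cohort$matrices[[sid]]))
      utils::write.table(cohort$matrices[[sid]][[cond]]$weights,
                         file.path(out_dir, sprintf("%s_%s.csv", sid, cond)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
  write_parcellation(cohort$parcellation,
                     file.path(out_dir, "parcellation.tsv"))
  write_csv_plain(cohort$subjects, file.path(out_dir, "subjects.csv"))
  prov <- cohort$params
  class(prov) <- NULL
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
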