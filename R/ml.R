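# Feature-based predictive modelling: 4-class cognitive-state
# classification and chronological-age regression with an RBF SVM,
# subject-wise leave-one-out cross-validation, inner-resampling C
# tuning, and permutation feature importance.

#' Map scan conditions to cognitive states
#'
#' The 4-class target of state classification: the three n-back loads
#' collapse to working memory, the two go/no-go conditions to inhibitory
#' control, shifting to cognitive flexibility, rest stays rest.
#'
#' @param condition Character vector of condition labels.
#' @return Character vector of state labels.
#' @export
condition_state <- function(condition) {
  map <- c(nback0 = "working_memory", nback1 = "working_memory",
           nback2 = "working_memory",
           gng_initiation = "inhibitory_control",
           gng_inhibition = "inhibitory_control",
           shifting = "cognitive_flexibility", rest = "rest")
  unknown <- setdiff(unique(condition), names(map))
  if (length(unknown) > 0L)
    stop("unknown condition(s): ", paste(unknown, collapse = ", "))
  unname(map[condition])
}

#' Assemble a feature table from energy and graph-measure tables
#'
#' Combines the long-format [energy_table()] (measure type `NE`) and
#' [measures_table()] (`GCC`, `GE`, `GM`) into the sample x feature
#' matrix the predictive models consume.
#' \itemize{
#'   \item `task = "classify_state"`: one sample per subject x
#'     condition, feature per (measure, scope); target is the cognitive
#'     state of the condition ([condition_state()]).
#'   \item `task = "predict_age"`: one sample per subject, feature per
#'     (measure, scope, condition); target is age, taken from `ages`.
#' }
#'
#' @param energies [energy_table()] output (needed for subset `NE`).
#' @param measures [measures_table()] output (needed for `GCC`/`GE`/`GM`).
#' @param task `"classify_state"` or `"predict_age"`.
#' @param subset Measure types to include, from `c("NE","GCC","GE","GM")`.
#' @param ages data.frame with `subject_id`, `age` (regression only).
#' @return List of class `feature_table`: `x` (numeric matrix), `y`
#'   (factor of states or numeric ages), `subject` (group key per row),
#'   `task`, `subset`.
#' @export
build_features <- function(energies = NULL, measures = NULL,
                           task = c("classify_state", "predict_age"),
                           subset = c("NE", "GCC", "GE", "GM"),
                           ages = NULL) {
  task <- match.arg(task)
  subset <- match.arg(subset, several.ok = TRUE)
  long <- list()
  if ("NE" %in% subset) {
    if (is.null(energies)) stop("subset includes NE but no energy table given")
    long$NE <- data.frame(subject_id = energies$subject_id,
                          condition = energies$condition,
                          scope = energies$scope, measure = "NE",
                          value = energies$U, stringsAsFactors = FALSE)
  }
  for (ms in intersect(subset, c("GCC", "GE", "GM"))) {
    if (is.null(measures))
      stop("subset includes ", ms, " but no measures table given")
    col <- c(GCC = "gcc", GE = "ge", GM = "gm")[[ms]]
    long[[ms]] <- data.frame(subject_id = measures$subject_id,
                             condition = measures$condition,
                             scope = measures$scope, measure = ms,
                             value = measures[[col]],
                             stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, long)
  subjects <- sort(unique(long$subject_id))
  conds <- intersect(ne_conditions(), unique(long$condition))
  scopes <- unique(long$scope)

  full <- expand.grid(subject_id = subjects, condition = conds,
                      scope = scopes, measure = subset,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject_id, d$condition, d$scope, d$measure)
  missing <- full[!(key(full) %in% key(long)), ]
  if (nrow(missing) > 0L)
    stop("incomplete feature inputs; first gaps: ",
         paste(utils::head(key(missing), 5L), collapse = "; "))

  if (task == "classify_state") {
    long$feat <- paste(long$measure, long$scope, sep = ".")
    wide <- stats::reshape(
      long[, c("subject_id", "condition", "feat", "value")],
      idvar = c("subject_id", "condition"), timevar = "feat",
      direction = "wide")
    featcols <- setdiff(names(wide), c("subject_id", "condition"))
    x <- as.matrix(wide[, featcols])
    colnames(x) <- sub("^value\\.", "", featcols)
    y <- factor(condition_state(wide$condition))
    out <- list(x = x, y = y, subject = wide$subject_id,
                condition = wide$condition, task = task, subset = subset)
  } else {
    if (is.null(ages) || !all(c("subject_id", "age") %in% names(ages)))
      stop("predict_age needs ages = data.frame(subject_id, age)")
    long$feat <- paste(long$measure, long$scope, long$condition, sep = ".")
    wide <- stats::reshape(
      long[, c("subject_id", "feat", "value")],
      idvar = "subject_id", timevar = "feat", direction = "wide")
    featcols <- setdiff(names(wide), "subject_id")
    x <- as.matrix(wide[, featcols])
    colnames(x) <- sub("^value\\.", "", featcols)
    idx <- match(wide$subject_id, ages$subject_id)
    if (any(is.na(idx)))
      stop("ages missing for subject(s): ",
           paste(wide$subject_id[is.na(idx)], collapse = ", "))
    y <- ages$age[idx]
    out <- list(x = x, y = y, subject = wide$subject_id,
                condition = NULL, task = task, subset = subset)
  }
  class(out) <- "feature_table"
  out
}

# z-scoring with training-fold statistics; constant columns pass through
fold_scaler <- function(xtrain) {
  mu <- colMeans(xtrain)
  sdv <- apply(xtrain, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(center = mu, scale = sdv,
       apply = function(x) sweep(sweep(x, 2L, mu), 2L, sdv, "/"))
}

subject_splits <- function(subjects, reps, holdout_frac = 0.2) {
  uniq <- unique(subjects)
  n_hold <- max(1L, round(holdout_frac * length(uniq)))
  lapply(seq_len(reps), function(i) sample(uniq, n_hold))
}

#' Cognitive-state classification with subject-wise LOOCV
#'
#' Outer loop: all samples of one subject are held out. Within each
#' training fold features are z-scored (fold statistics only -- no
#' leakage), the RBF bandwidth is held fixed (median-of-pairwise-
#' distances heuristic on the fold unless `fixed_sigma` is given), and C
#' is tuned by repeated subject-wise resampling, maximising accuracy.
#' Held-out predictions are aggregated into the report.
#'
#' @param ft A `classify_state` [build_features()] table.
#' @param fixed_sigma Optional fixed RBF bandwidth.
#' @param c_grid Candidate C values (default powers of 2 from 2^-2 to
#'   2^7).
#' @param seed Integer seed (resampling splits).
#' @param inner_reps Inner resampling repetitions per C.
#' @return List of class `ne_classification`: `balanced_accuracy`,
#'   `per_class_accuracy` (recalls), `confusion` (row-normalised %),
#'   `confusion_counts`, `tuned_C` (per fold), `predictions`, and
#'   internals (`folds`, `ft`) reused by [feature_importance()].
#' @export
classify_states <- function(ft, fixed_sigma = NULL, c_grid = 2^(-2:7),
                            seed = 1L, inner_reps = 5L) {
  stopifnot(inherits(ft, "feature_table"), ft$task == "classify_state")
  y <- factor(ft$y)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  subjects <- unique(ft$subject)
  if (length(subjects) < 5L) stop("need at least 5 subjects")
  rng <- local_rng(seed)
  rng(function() {
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    folds <- list()
    for (s in subjects) {
      test <- ft$subject == s
      xtr <- ft$x[!test, , drop = FALSE]; ytr <- droplevels(y[!test])
      if (nlevels(ytr) < nlevels(y))
        stop(sprintf("class(es) absent from training fold without subject %s", s))
      sc <- fold_scaler(xtr)
      xtr_s <- sc$apply(xtr)
      sigma <- if (is.null(fixed_sigma)) median_heuristic_sigma(xtr_s)
               else fixed_sigma
      best_c <- tune_c(xtr_s, ytr, ft$subject[!test], c_grid, sigma,
                       inner_reps, metric = "accuracy")
      model <- rbf_svm(xtr_s, ytr, type = "C-classification",
                       C = best_c, sigma = sigma)
      pred[test] <- predict(model, sc$apply(ft$x[test, , drop = FALSE]))
      folds[[s]] <- list(model = model, center = sc$center,
                         scale = sc$scale, test = which(test),
                         sigma = sigma, C = best_c)
    }
    cm <- table(actual = y, predicted = pred)
    recalls <- diag(cm) / rowSums(cm)
    out <- list(balanced_accuracy = mean(recalls),
                per_class_accuracy = recalls,
                confusion = 100 * sweep(cm, 1L, rowSums(cm), "/"),
                confusion_counts = cm,
                tuned_C = vapply(folds, `[[`, numeric(1), "C"),
                predictions = data.frame(subject_id = ft$subject,
                                         condition = if (is.null(ft$condition))
                                           NA_character_ else ft$condition,
                                         actual = y, predicted = pred,
                                         stringsAsFactors = FALSE),
                folds = folds, ft = ft, seed = seed)
    class(out) <- "ne_classification"
    out
  })
}

# inner C tuning by repeated subject-wise holdout; assumes RNG positioned
tune_c <- function(x, y, subject, c_grid, sigma, reps, metric,
                   epsilon = 0.01) {
  splits <- subject_splits(subject, reps)
  scores <- matrix(NA_real_, reps, length(c_grid))
  for (r in seq_len(reps)) {
    hold <- subject %in% splits[[r]]
    if (all(hold) || !any(hold)) next
    if (metric == "accuracy" && nlevels(droplevels(factor(y[!hold]))) <
        nlevels(factor(y))) next
    for (ci in seq_along(c_grid)) {
      if (metric == "accuracy") {
        fit <- rbf_svm(x[!hold, , drop = FALSE], y[!hold],
                       type = "C-classification", C = c_grid[ci],
                       sigma = sigma)
        pr <- predict(fit, x[hold, , drop = FALSE])
        scores[r, ci] <- mean(pr == y[hold])
      } else {
        fit <- rbf_svm(x[!hold, , drop = FALSE], y[!hold],
                       type = "eps-regression", C = c_grid[ci],
                       sigma = sigma, epsilon = epsilon)
        pr <- predict(fit, x[hold, , drop = FALSE])
        scores[r, ci] <- -mean(abs(pr - y[hold]))   # negative MAE
      }
    }
  }
  mean_scores <- colMeans(scores, na.rm = TRUE)
  if (all(!is.finite(mean_scores))) return(c_grid[1L])
  c_grid[which.max(mean_scores)]    # ties resolve to the smallest C
}

#' Chronological-age regression with subject-wise LOOCV
#'
#' Epsilon-insensitive RBF SVM regression, one sample per subject, with
#' the same fold discipline as [classify_states()]: per-fold z-scoring
#' of features and target, fixed bandwidth, C tuned by inner resampling
#' minimising MAE. Reports \eqn{R^2} as the squared Pearson correlation
#' between held-out predictions and actual ages (the convention used
#' with predicted-vs-actual scatter plots) alongside the
#' \eqn{1 - SSE/SST} variant, and MAE in years.
#'
#' @param ft A `predict_age` [build_features()] table.
#' @inheritParams classify_states
#' @param epsilon Insensitive-tube half width on the z-scored target.
#' @return List of class `ne_regression`: `r2`, `r2_sse`, `mae`,
#'   `predictions`, `tuned_C`, plus internals for
#'   [feature_importance()].
#' @export
predict_age <- function(ft, fixed_sigma = NULL, c_grid = 2^(-2:7),
                        seed = 1L, inner_reps = 5L, epsilon = 0.01) {
  stopifnot(inherits(ft, "feature_table"), ft$task == "predict_age")
  y <- as.numeric(ft$y)
  if (stats::sd(y) == 0) stop("constant age target")
  subjects <- unique(ft$subject)
  if (length(subjects) < 5L) stop("need at least 5 subjects")
  rng <- local_rng(seed)
  rng(function() {
    pred <- rep(NA_real_, length(y))
    folds <- list()
    for (s in subjects) {
      test <- ft$subject == s
      xtr <- ft$x[!test, , drop = FALSE]; ytr <- y[!test]
      sc <- fold_scaler(xtr)
      xtr_s <- sc$apply(xtr)
      y_mu <- mean(ytr); y_sd <- stats::sd(ytr); if (y_sd == 0) y_sd <- 1
      ytr_s <- (ytr - y_mu) / y_sd
      sigma <- if (is.null(fixed_sigma)) median_heuristic_sigma(xtr_s)
               else fixed_sigma
      best_c <- tune_c(xtr_s, ytr_s, ft$subject[!test], c_grid, sigma,
                       inner_reps, metric = "mae", epsilon = epsilon)
      model <- rbf_svm(xtr_s, ytr_s, type = "eps-regression", C = best_c,
                       sigma = sigma, epsilon = epsilon)
      pred[test] <- predict(model, sc$apply(ft$x[test, , drop = FALSE])) *
        y_sd + y_mu
      folds[[s]] <- list(model = model, center = sc$center,
                         scale = sc$scale, test = which(test),
                         y_center = y_mu, y_scale = y_sd,
                         sigma = sigma, C = best_c)
    }
    out <- list(r2 = stats::cor(pred, y)^2,
                r2_sse = 1 - sum((pred - y)^2) / sum((y - mean(y))^2),
                mae = mean(abs(pred - y)),
                predictions = data.frame(subject_id = ft$subject,
                                         actual = y, predicted = pred,
                                         stringsAsFactors = FALSE),
                tuned_C = vapply(folds, `[[`, numeric(1), "C"),
                folds = folds, ft = ft, seed = seed)
    class(out) <- "ne_regression"
    out
  })
}

#' Permutation feature importance
#'
#' Model-agnostic importance: the performance drop when one feature
#' column is shuffled across samples, predictions re-made with the
#' already-fitted per-fold models, and the metric recomputed --
#' averaged over `n_shuffles` seeded shuffles. Classification uses
#' balanced accuracy (importance = drop); regression uses MAE
#' (importance = increase). An RBF kernel has no standardised
#' coefficients, so this is the principled stand-in.
#'
#' @param report An [classify_states()] or [predict_age()] result.
#' @param n_shuffles Shuffles per feature (>= 20 recommended).
#' @param seed Integer seed.
#' @return `data.frame` sorted by descending importance: `feature`,
#'   `importance`.
#' @export
feature_importance <- function(report, n_shuffles = 20L, seed = 1L) {
  stopifnot(inherits(report, c("ne_classification", "ne_regression")))
  ft <- report$ft
  classif <- inherits(report, "ne_classification")
  base_pred <- loo_predict(report, ft$x)
  base <- score_predictions(base_pred, ft$y, classif)
  rng <- local_rng(seed)
  rng(function() {
    imp <- vapply(seq_len(ncol(ft$x)), function(j) {
      drops <- vapply(seq_len(n_shuffles), function(r) {
        xs <- ft$x
        xs[, j] <- xs[sample.int(nrow(xs)), j]
        sc <- score_predictions(loo_predict(report, xs), ft$y, classif)
        if (classif) base - sc else sc - base
      }, numeric(1))
      mean(drops)
    }, numeric(1))
    out <- data.frame(feature = colnames(ft$x), importance = imp,
                      stringsAsFactors = FALSE)
    out[order(-out$importance), , drop = FALSE]
  })
}

# held-out predictions for (possibly modified) feature matrix `x`,
# reusing fitted fold models and fold scalers
loo_predict <- function(report, x) {
  classif <- inherits(report, "ne_classification")
  pred <- if (classif)
    factor(rep(NA_character_, nrow(x)), levels = levels(factor(report$ft$y)))
  else rep(NA_real_, nrow(x))
  for (f in report$folds) {
    xs <- sweep(sweep(x[f$test, , drop = FALSE], 2L, f$center), 2L,
                f$scale, "/")
    p <- predict(f$model, xs)
    if (classif) pred[f$test] <- p
    else pred[f$test] <- p * f$y_scale + f$y_center
  }
  pred
}

score_predictions <- function(pred, y, classif) {
  if (classif) {
    cm <- table(actual = factor(y), predicted = pred)
    mean(diag(cm) / rowSums(cm))          # balanced accuracy
  } else {
    mean(abs(pred - as.numeric(y)))       # MAE
  }
}

#' Chance band for classification via label permutation
#'
#' Holds the classifier's held-out predictions fixed and permutes the
#' labels `n_perms` times, giving the null distribution of balanced
#' accuracy around 1/(number of classes). Used to check that a
#' classifier trained on a no-effect cohort stays within chance.
#'
#' @param report A [classify_states()] result.
#' @param n_perms Number of label permutations.
#' @param seed Integer seed.
#' @return List: `observed`, `null` (vector), `ci` (central 95% of the
#'   null), `within_chance`.
#' @export
permutation_chance_band <- function(report, n_perms = 200L, seed = 1L) {
  stopifnot(inherits(report, "ne_classification"))
  y <- factor(report$predictions$actual)
  pred <- factor(report$predictions$predicted, levels = levels(y))
  rng <- local_rng(seed)
  rng(function() {
    null <- vapply(seq_len(n_perms), function(i) {
      cm <- table(actual = sample(y), predicted = pred)
      mean(diag(cm) / rowSums(cm))
    }, numeric(1))
    ci <- stats::quantile(null, c(0.025, 0.975), names = FALSE)
    list(observed = report$balanced_accuracy, null = null, ci = ci,
         within_chance = report$balanced_accuracy >= ci[1] &&
           report$balanced_accuracy <= ci[2])
  })
}
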