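# Nonparametric group inference for repeated-measures energy tables:
# Friedman omnibus test, pairwise Wilcoxon with multiplicity correction,
# actual-vs-null comparison, and intraclass correlation across
# parcellation atlases.

#' Friedman repeated-measures test
#'
#' Rank-based omnibus test for a condition effect in a complete
#' subjects x conditions block; within-subject ranks, ties mid-ranked,
#' with the usual tie correction. The default p-value is the asymptotic
#' chi-square one; `exact = TRUE` enumerates the full within-subject
#' rank-permutation null (all \eqn{(k!)^n} assignments), feasible for
#' small blocks.
#'
#' @param values Numeric matrix, rows = subjects, columns = conditions
#'   (no missing cells).
#' @param exact Use the exhaustive permutation distribution.
#' @param max_enum Safety cap on \eqn{(k!)^n} for the exact path.
#' @return List with `statistic` (tie-corrected Friedman chi-square),
#'   `df`, `p.value`, `method`, `n`, `k`.
#' @export
friedman_test <- function(values, exact = FALSE, max_enum = 2e6) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("missing or non-finite cells in block")
  n <- nrow(values); k <- ncol(values)
  if (k < 2L) stop("need at least 2 conditions")
  if (n < 2L) stop("need at least 2 subjects")
  r <- t(apply(values, 1L, rank))
  stat_obs <- friedman_statistic(r)
  df <- k - 1L
  if (!exact) {
    return(list(statistic = stat_obs, df = df,
                p.value = stats::pchisq(stat_obs, df, lower.tail = FALSE),
                method = "Friedman rank sum test (asymptotic)",
                n = n, k = k))
  }
  n_comb <- factorial(k)^n
  if (n_comb > max_enum)
    stop(sprintf("exact enumeration needs (k!)^n = %.3g evaluations (cap %g)",
                 n_comb, max_enum))
  perms <- all_permutations(k)            # k! x k column orders
  np <- nrow(perms)
  # per-row matrix of the k! achievable rank vectors (ties preserved)
  row_opts <- lapply(seq_len(n), function(i)
    matrix(r[i, perms], nrow = np))
  idx <- as.matrix(expand.grid(rep(list(seq_len(np)), n)))
  csum <- matrix(0, nrow(idx), k)
  for (i in seq_len(n)) csum <- csum + row_opts[[i]][idx[, i], , drop = FALSE]
  cc <- tie_correction(r)
  stats_all <- 12 * rowSums((csum - n * (k + 1) / 2)^2) / (n * k * (k + 1) * cc)
  p <- mean(stats_all >= stat_obs - 1e-12)
  list(statistic = stat_obs, df = df, p.value = p,
       method = "Friedman rank sum test (exact permutation)", n = n, k = k)
}

friedman_statistic <- function(r) {
  n <- nrow(r); k <- ncol(r)
  cc <- tie_correction(r)
  12 * sum((colSums(r) - n * (k + 1) / 2)^2) / (n * k * (k + 1) * cc)
}

# multiplicative tie correction shared by observed and permuted blocks
tie_correction <- function(r) {
  n <- nrow(r); k <- ncol(r)
  ties <- sum(unlist(lapply(seq_len(n), function(i) {
    tab <- table(r[i, ])
    sum(tab^3 - tab)
  })))
  1 - ties / (n * (k^3 - k))
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    res <- matrix(0L, nrow(sub), k)
    res[, seq_len(k - 1L)] <- sub + (sub >= pos)
    res[, k] <- pos
    res
  }))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences
#' are dropped (Wilcoxon's original treatment) or retained with Pratt's
#' correction. The p-value is exact when the effective sample size is
#' <= `exact_max` and there are no ties among \eqn{|d|}; otherwise the
#' normal approximation with continuity correction is used.
#'
#' @param x,y Paired numeric vectors, or `y = NULL` with `x` the
#'   differences.
#' @param zero_method `"wilcox"` (drop zeros) or `"pratt"`.
#' @param exact_max Largest n for the exact distribution.
#' @return List with `statistic` (V, sum of positive ranks), `p.value`,
#'   `n_effective`, `degenerate` (TRUE when all differences are zero,
#'   in which case `p.value = 1`).
#' @export
signed_rank_test <- function(x, y = NULL, zero_method = c("wilcox", "pratt"),
                             exact_max = 25L) {
  zero_method <- match.arg(zero_method)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (any(!is.finite(d))) stop("non-finite paired differences")
  if (all(d == 0))
    return(list(statistic = NA_real_, p.value = 1, n_effective = 0L,
                degenerate = TRUE))
  if (zero_method == "wilcox") {
    dn <- d[d != 0]
    n <- length(dn)
    ties <- anyDuplicated(abs(dn)) > 0L
    use_exact <- n <= exact_max && !ties
    ht <- suppressWarnings(
      stats::wilcox.test(dn, exact = use_exact, correct = TRUE))
    return(list(statistic = unname(ht$statistic), p.value = ht$p.value,
                n_effective = n, degenerate = FALSE))
  }
  # Pratt: rank |d| with zeros included, then discard zero ranks
  n <- length(d)
  z <- sum(d == 0)
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  mu <- (n * (n + 1) - z * (z + 1)) / 4
  tab <- table(rk[d != 0])
  sig2 <- (n * (n + 1) * (2 * n + 1) - z * (z + 1) * (2 * z + 1)) / 24 -
    sum(tab^3 - tab) / 48
  zs <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
  list(statistic = v, p.value = min(1, 2 * stats::pnorm(-abs(zs))),
       n_effective = n - z, degenerate = FALSE)
}

#' Pairwise Wilcoxon comparisons across conditions
#'
#' Signed-rank test on every pair of columns of a repeated-measures
#' block, with correction for multiplicity over all pairs. Holm (FWER,
#' no independence assumptions) is the default; Benjamini-Hochberg is
#' selectable.
#'
#' @param values Numeric matrix, rows = subjects, columns = conditions
#'   (colnames used as condition labels).
#' @param method Correction method, `"holm"` or `"BH"`.
#' @param zero_method Passed to [signed_rank_test()].
#' @return `data.frame` with one row per pair: `condition_a`,
#'   `condition_b`, `statistic`, `p_raw`, `p_adjusted`, `direction`
#'   (sign of the median paired difference), `degenerate`.
#' @export
pairwise_wilcoxon <- function(values, method = c("holm", "BH"),
                              zero_method = "wilcox") {
  method <- match.arg(method)
  values <- as.matrix(values)
  k <- ncol(values)
  if (k < 2L) stop("need at least 2 conditions")
  labs <- colnames(values)
  if (is.null(labs)) labs <- paste0("cond", seq_len(k))
  pairs <- utils::combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(q) {
    a <- pairs[1L, q]; b <- pairs[2L, q]
    res <- signed_rank_test(values[, a], values[, b],
                            zero_method = zero_method)
    md <- stats::median(values[, a] - values[, b])
    data.frame(condition_a = labs[a], condition_b = labs[b],
               statistic = res$statistic, p_raw = res$p.value,
               direction = if (md > 0) ">" else if (md < 0) "<" else "=",
               degenerate = res$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = method)
  out[, c("condition_a", "condition_b", "statistic", "p_raw",
          "p_adjusted", "direction", "degenerate")]
}

#' Compare actual network energies with paired null energies
#'
#' Paired Wilcoxon signed-rank test of actual vs surrogate energies
#' across subjects, reporting the direction of the median difference.
#' Brain-like (coherently organised) networks are expected to sit below
#' their random-topology nulls.
#'
#' @param actual,null Paired numeric vectors of equal length.
#' @param zero_method Passed to [signed_rank_test()].
#' @return List with `statistic`, `p.value`, `direction` (one of
#'   `"actual < null"`, `"actual > null"`, `"equal"`), `degenerate`.
#' @export
actual_vs_null_test <- function(actual, null, zero_method = "wilcox") {
  if (length(actual) != length(null))
    stop("actual and null must be paired vectors of equal length")
  res <- signed_rank_test(actual, null, zero_method = zero_method)
  md <- stats::median(actual - null)
  list(statistic = res$statistic, p.value = res$p.value,
       direction = if (md < 0) "actual < null"
                   else if (md > 0) "actual > null" else "equal",
       degenerate = res$degenerate)
}

#' Intraclass correlation, two-way mixed, consistency, average measures
#'
#' ICC(3,k) with k = 2 fixed raters (here: two parcellation atlases
#' rating the same subjects), from the two-way ANOVA mean squares:
#' \deqn{ICC(3,k) = (MS_R - MS_E) / MS_R,}
#' with an F-based confidence interval (Shrout & Fleiss). Consistency
#' ICC ignores affine rescaling between raters.
#'
#' @param ratings_a,ratings_b Numeric vectors of the same subjects rated
#'   by the two raters; length >= 5.
#' @param conf_level Confidence level for the interval.
#' @return List of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `model`, `n`, `k`.
#' @export
icc_consistency <- function(ratings_a, ratings_b, conf_level = 0.95) {
  a <- as.numeric(ratings_a); b <- as.numeric(ratings_b)
  if (length(a) != length(b)) stop("rating vectors must have equal length")
  n <- length(a)
  if (n < 5L) stop("need at least 5 subjects")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite ratings")
  y <- cbind(a, b)
  k <- 2L
  grand <- mean(y)
  row_m <- rowMeans(y); col_m <- colMeans(y)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((y - outer(row_m, rep(1, k)) -
                 outer(rep(1, n), col_m) + grand)^2)
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps * max(1, abs(grand)))
    stop("zero between-subject variance: ICC undefined")
  icc <- (msr - mse) / msr
  alpha <- 1 - conf_level
  fobs <- msr / mse
  df1 <- n - 1L; df2 <- (n - 1L) * (k - 1L)
  fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
  fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
  structure(list(icc = icc, ci_low = 1 - 1 / fl, ci_high = 1 - 1 / fu,
                 model = "two-way mixed, consistency, average of 2 raters",
                 n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(3,k) = %.3f  [%.3f, %.3f]  (%s, n = %d)\n",
              x$icc, x$ci_low, x$ci_high, x$model, x$n))
  invisible(x)
}
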