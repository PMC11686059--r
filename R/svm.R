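# RBF-kernel support vector machines (classification and regression)
# on top of the SMO dual solver in src/smo.cpp. Scope is deliberately
# narrow: dense small-sample problems with a Gaussian kernel, which is
# all the prediction pipeline needs.

#' Gaussian (RBF) kernel matrix
#'
#' \eqn{K(x, z) = \exp(-\|x - z\|^2 / (2\sigma^2))} with bandwidth
#' (length scale) `sigma`.
#'
#' @param x,z Numeric matrices (rows = samples). `z = x` gives the Gram
#'   matrix.
#' @param sigma Positive bandwidth.
#' @return `nrow(x)` x `nrow(z)` kernel matrix.
#' @export
rbf_kernel <- function(x, z = x, sigma) {
  x <- as.matrix(x); z <- as.matrix(z)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  d2 <- outer(rowSums(x^2), rowSums(z^2), "+") - 2 * tcrossprod(x, z)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Median-distance bandwidth heuristic
#'
#' The median of the pairwise Euclidean distances between samples; the
#' standard way of fixing the RBF length scale once so that only the
#' regularisation parameter C needs tuning.
#'
#' @param x Numeric matrix, rows = samples.
#' @return Positive scalar bandwidth (1 if all samples coincide).
#' @export
median_heuristic_sigma <- function(x) {
  x <- as.matrix(x)
  d <- stats::dist(x)
  d <- d[d > 0]
  if (length(d) == 0L) return(1)
  stats::median(d)
}

#' Fit an RBF-kernel support vector machine
#'
#' C-classification (any number of classes via one-vs-one voting) or
#' epsilon-insensitive regression, trained by sequential minimal
#' optimisation. Features are used as given; callers are responsible for
#' scaling (the cross-validation drivers z-score per training fold).
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Class labels (factor/character) for classification, numeric
#'   target for regression.
#' @param type `"C-classification"` or `"eps-regression"`.
#' @param C Regularisation parameter (> 0).
#' @param sigma RBF bandwidth; default [median_heuristic_sigma()] of `x`.
#' @param epsilon Half-width of the insensitive tube (regression only),
#'   on the scale of `y`.
#' @param tol SMO stopping tolerance.
#' @return An object of class `rbf_svm`.
#' @export
rbf_svm <- function(x, y, type = c("C-classification", "eps-regression"),
                    C = 1, sigma = NULL, epsilon = 0.01, tol = 1e-3) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (!is.finite(C) || C <= 0) stop("C must be positive")
  if (is.null(sigma)) sigma <- median_heuristic_sigma(x)
  K <- rbf_kernel(x, sigma = sigma)

  if (type == "C-classification") {
    y <- factor(y)
    lev <- levels(y)
    if (length(lev) < 2L) stop("need at least 2 classes")
    pairs <- utils::combn(lev, 2L, simplify = FALSE)
    machines <- lapply(pairs, function(pr) {
      idx <- which(y %in% pr)
      yy <- ifelse(y[idx] == pr[1L], 1L, -1L)
      fit <- smo_binary(K[idx, idx, drop = FALSE], yy, C, tol)
      list(classes = pr, idx = idx, coef = fit$coef, rho = fit$rho)
    })
    out <- list(type = type, x = x, sigma = sigma, C = C, levels = lev,
                machines = machines)
  } else {
    y <- as.numeric(y)
    if (any(!is.finite(y))) stop("regression target must be finite")
    fit <- smo_svr(K, y, C, epsilon, tol)
    out <- list(type = type, x = x, sigma = sigma, C = C,
                epsilon = epsilon, coef = fit$coef, rho = fit$rho)
  }
  class(out) <- "rbf_svm"
  out
}

# binary C-SVC dual: p = -1, Q = yy' * K
smo_binary <- function(K, yy, C, tol) {
  l <- length(yy)
  Q <- K * tcrossprod(yy)
  sol <- smo_solve_cpp(Q, rep(-1, l), as.integer(yy), rep(C, l), tol)
  list(coef = sol$alpha * yy, rho = sol$rho)
}

# eps-SVR via the doubled formulation: variables (a, a*), y = (+1, -1)
smo_svr <- function(K, z, C, epsilon, tol) {
  l <- length(z)
  yy <- c(rep(1L, l), rep(-1L, l))
  Q <- rbind(cbind(K, -K), cbind(-K, K))
  p <- c(epsilon - z, epsilon + z)
  sol <- smo_solve_cpp(Q, p, yy, rep(C, 2L * l), tol)
  a <- sol$alpha
  list(coef = a[seq_len(l)] - a[l + seq_len(l)], rho = sol$rho)
}

#' Predict from an RBF SVM
#'
#' @param object An [rbf_svm()] fit.
#' @param newdata Numeric feature matrix.
#' @param decision Also return the per-pair decision values
#'   (classification only).
#' @param ... Unused.
#' @return Factor of predicted classes, or numeric predictions for
#'   regression. With `decision = TRUE`, a list with elements `class`
#'   and `decision`.
#' @export
predict.rbf_svm <- function(object, newdata, decision = FALSE, ...) {
  newdata <- as.matrix(newdata)
  if (object$type == "eps-regression") {
    K <- rbf_kernel(newdata, object$x, sigma = object$sigma)
    return(drop(K %*% object$coef) - object$rho)
  }
  lev <- object$levels
  votes <- matrix(0L, nrow(newdata), length(lev), dimnames = list(NULL, lev))
  dsum <- matrix(0, nrow(newdata), length(lev), dimnames = list(NULL, lev))
  decvals <- list()
  for (mch in object$machines) {
    K <- rbf_kernel(newdata, object$x[mch$idx, , drop = FALSE],
                    sigma = object$sigma)
    f <- drop(K %*% mch$coef) - mch$rho
    pos <- mch$classes[1L]; neg <- mch$classes[2L]
    votes[, pos] <- votes[, pos] + (f >= 0)
    votes[, neg] <- votes[, neg] + (f < 0)
    dsum[, pos] <- dsum[, pos] + f
    dsum[, neg] <- dsum[, neg] - f
    decvals[[paste(mch$classes, collapse = "/")]] <- f
  }
  # majority vote; ties broken by summed decision values
  pick <- vapply(seq_len(nrow(newdata)), function(i) {
    v <- votes[i, ]
    top <- which(v == max(v))
    if (length(top) > 1L) top <- top[which.max(dsum[i, top])]
    lev[top]
  }, character(1))
  cls <- factor(pick, levels = lev)
  if (decision) list(class = cls, decision = decvals) else cls
}
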