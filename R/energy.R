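#' Real (signed) cube root
#'
#' `sign(x) * abs(x)^(1/3)`: the real cube root, multiplicative over the
#' reals so that `signed_cbrt(a*b*c) == signed_cbrt(a)*signed_cbrt(b)*
#' signed_cbrt(c)`. A naive `x^(1/3)` is NaN for negative `x` in R and
#' must not be used on signed weights.
#'
#' @param x Numeric vector; all elements must be finite.
#' @return Numeric vector of real cube roots.
#' @examples
#' signed_cbrt(0.125)  # 0.5
#' signed_cbrt(-1)     # -1
#' @export
signed_cbrt <- function(x) {
  if (!is.numeric(x)) stop("x must be numeric")
  if (any(!is.finite(x))) stop("signed_cbrt requires finite input")
  sign(x) * abs(x)^(1 / 3)
}

#' Structural-balance energy of a signed network
#'
#' The energy of a signed weighted network with weights \eqn{S_{ij}} is
#' \deqn{U = -\frac{1}{\binom{N}{3}} \sum_{\langle i,j,k \rangle}
#'   \sqrt[3]{S_{ij} S_{ik} S_{jk}},}
#' the negative mean, over all \eqn{\binom{N}{3}} region triples, of the
#' cube-rooted triangle weight product. Balanced triangles (positive
#' product) lower the energy; imbalanced triangles (negative product)
#' raise it. \eqn{U} is bounded in \eqn{[-1, 1]} for weights in
#' \eqn{[-1, 1]}: \eqn{-1} for a complete all-+1 network, \eqn{+1} for a
#' complete all--1 network.
#'
#' Implementation: with \eqn{T} the element-wise signed cube root of the
#' weight matrix (zero diagonal), \eqn{\mathrm{tr}(T^3)} counts each
#' unordered triangle 6 times, so
#' \eqn{U = -\mathrm{tr}(T^3) / (N(N-1)(N-2))}. This is
#' \eqn{O(N^3)} via two dense matrix products and agrees with explicit
#' triangle enumeration ([brute_force_energy()]) to 1e-10.
#'
#' @param m A [connectivity_matrix()] or square numeric matrix (validated
#'   on the fly).
#' @param ... Passed to [connectivity_matrix()] when `m` is a bare matrix.
#' @return Scalar energy \eqn{U}.
#' @seealso [brute_force_energy()], [triangle_census()],
#'   [subnetwork_energy()]
#' @export
network_energy <- function(m, ...) {
  m <- connectivity_matrix(m, ...)
  tmat <- signed_cbrt(m$weights)
  n <- m$n
  -sum(diag(tmat %*% tmat %*% tmat)) / (n * (n - 1) * (n - 2))
}

#' Energy by explicit triangle enumeration
#'
#' Reference implementation of [network_energy()]: loops over all
#' \eqn{\binom{N}{3}} unordered region triples and averages the
#' cube-rooted triangle products. Used as the enumeration oracle for the
#' trace-based computation; practical up to a few hundred regions
#' (N = 229 is about 1.97 million triangles).
#'
#' @inheritParams network_energy
#' @return Scalar energy \eqn{U}.
#' @export
brute_force_energy <- function(m, ...) {
  m <- connectivity_matrix(m, ...)
  brute_force_energy_cpp(signed_cbrt(m$weights))
}

#' Census of balanced and imbalanced triangles
#'
#' Classifies every region triple by the sign of its weight product
#' \eqn{S_{ij} S_{ik} S_{jk}}: positive = balanced (stabilising),
#' negative = imbalanced (destabilising). Triangles containing an
#' exactly-zero edge have zero product and are counted as neither.
#' Intensities are sums of cube-rooted product magnitudes, so that
#' \deqn{-(I_{bal} - I_{imb}) / \binom{N}{3} = U.}
#'
#' @inheritParams network_energy
#' @return A list of class `triangle_census` with elements `n_balanced`,
#'   `n_imbalanced`, `intensity_balanced`, `intensity_imbalanced`,
#'   `n_triangles` (= \eqn{\binom{N}{3}}).
#' @export
triangle_census <- function(m, ...) {
  m <- connectivity_matrix(m, ...)
  res <- triangle_census_cpp(signed_cbrt(m$weights))
  res$n_triangles <- choose(m$n, 3)
  class(res) <- "triangle_census"
  res
}

#' @export
print.triangle_census <- function(x, ...) {
  cat(sprintf(
    "<triangle_census> %d balanced (intensity %.4g), %d imbalanced (intensity %.4g) of %d triples\n",
    x$n_balanced, x$intensity_balanced, x$n_imbalanced,
    x$intensity_imbalanced, x$n_triangles))
  invisible(x)
}

#' Energy of a canonical sub-network
#'
#' Extracts the principal submatrix of the regions belonging to `scope`
#' and returns its [network_energy()]; normalisation uses the
#' sub-network's own region count.
#'
#' @param m A [connectivity_matrix()].
#' @param p A [parcellation()] covering the matrix regions.
#' @param scope Canonical network label, or [whole_brain()].
#' @return Scalar energy of the sub-network.
#' @export
subnetwork_energy <- function(m, p, scope) {
  m <- connectivity_matrix(m)
  ids <- scope_regions(p, scope)
  keep <- m$region_ids %in% ids
  if (sum(keep) < 3L)
    stop(sprintf("scope '%s' maps to %d regions of this matrix; need >= 3",
                 scope, sum(keep)))
  sub <- connectivity_matrix(m$weights[keep, keep, drop = FALSE],
                             region_ids = m$region_ids[keep],
                             subject_id = m$subject_id, condition = m$condition)
  network_energy(sub)
}

#' Rest-to-task energy change
#'
#' \eqn{\Delta U = U_{task} - U_{rest}}: the energy the network receives
#' in the transition from rest to task. For a conservative process this
#' endpoint difference is independent of the trajectory taken between
#' the two states.
#'
#' @param task_u Energy in the task condition.
#' @param rest_u Energy at rest.
#' @return `task_u - rest_u`.
#' @export
energy_delta <- function(task_u, rest_u) {
  if (any(!is.finite(task_u)) || any(!is.finite(rest_u)))
    stop("energy_delta requires finite energies")
  task_u - rest_u
}

#' Long-format energy table for a cohort
#'
#' Computes one energy per (subject, condition, scope) for the whole
#' brain and every canonical network, and optionally the rest-to-task
#' change \eqn{\Delta U} relative to the same subject's rest scan.
#'
#' @param cohort Nested list `cohort[[subject]][[condition]]` of
#'   [connectivity_matrix()] objects (as returned by [read_matrix_dir()]
#'   or [generate_cohort()]`$matrices`).
#' @param p A [parcellation()].
#' @param scopes Character vector of scopes; default whole brain plus
#'   every network label present in `p`.
#' @param delta Fill `dU` for non-rest conditions (requires each subject
#'   to have a `"rest"` entry).
#' @return `data.frame` with columns `subject_id`, `condition`, `scope`,
#'   `U`, and `dU` when `delta = TRUE`.
#' @export
energy_table <- function(cohort, p, scopes = NULL, delta = TRUE) {
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$matrices
  if (is.null(scopes))
    scopes <- c(whole_brain(), sort(unique(p$network_label)))
  if (delta) {
    missing_rest <- names(cohort)[!vapply(cohort, function(s)
      "rest" %in% names(s), logical(1))]
    if (length(missing_rest) > 0L)
      stop("dU requested but no rest condition for subject(s): ",
           paste(missing_rest, collapse = ", "))
  }
  rows <- list()
  for (sid in names(cohort)) {
    for (cond in names(cohort[[sid]])) {
      m <- cohort[[sid]][[cond]]
      u <- vapply(scopes, function(sc) subnetwork_energy(m, p, sc), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, condition = cond, scope = scopes, U = u,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (delta) {
    rest <- out[out$condition == "rest", c("subject_id", "scope", "U")]
    names(rest)[3] <- "U_rest"
    out <- merge(out, rest, by = c("subject_id", "scope"), sort = FALSE)
    out$dU <- ifelse(out$condition == "rest", NA_real_,
                     energy_delta(out$U, out$U_rest))
    out$U_rest <- NULL
  }
  out <- out[order(out$subject_id, match(out$condition, ne_conditions()),
                   match(out$scope, c(whole_brain(), sort(unique(p$network_label))))), ]
  rownames(out) <- NULL
  out[, c("subject_id", "condition", "scope", "U",
          if (delta) "dU" else NULL)]
}
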