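# Comparator global network measures used as competing features next to
# network energy. Signed edges are handled by the dominant conventions
# of weighted brain-network toolkits: absolute values for clustering and
# efficiency, the positive-weight subgraph for modularity -- the signed
# information is exactly what the energy statistic contributes.

#' Global weighted clustering coefficient
#'
#' Mean over nodes of the geometric-mean (triangle-intensity) weighted
#' clustering coefficient of Onnela et al., computed on \eqn{|w|}
#' rescaled to \eqn{[0, 1]} by the global maximum:
#' \deqn{c_i = \frac{1}{k_i (k_i - 1)} \sum_{j,k}
#'   (\hat w_{ij} \hat w_{jk} \hat w_{ki})^{1/3},}
#' with \eqn{k_i} the number of nonzero edges at node \eqn{i}. Nodes
#' with \eqn{k_i < 2} contribute 0. A complete unit-weight graph scores
#' 1; a star (no triangles) scores 0.
#'
#' @param m A [connectivity_matrix()] (or square matrix).
#' @return Scalar in \eqn{[0, 1]}; 0 for an all-zero matrix.
#' @export
global_clustering <- function(m) {
  m <- connectivity_matrix(m, allow_out_of_range = TRUE)
  w <- abs(m$weights)
  mx <- max(w)
  if (mx == 0) return(0)
  wh <- (w / mx)^(1 / 3)
  tri <- diag(wh %*% wh %*% wh)           # 2 * sum of cube-rooted triangle intensities at i
  k <- rowSums(w > 0)
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  mean(ci)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of \eqn{1/d(i, j)}, where \eqn{d} is the
#' weighted shortest-path length on edge lengths \eqn{1/|w|} (zero-weight
#' edges absent). Disconnected pairs contribute 0. A complete
#' unit-weight graph scores 1.
#'
#' @param m A [connectivity_matrix()] (or square matrix; N >= 2 via the
#'   container's N >= 3 requirement).
#' @return Scalar in \eqn{[0, \infty)}.
#' @export
global_efficiency <- function(m) {
  m <- connectivity_matrix(m, allow_out_of_range = TRUE)
  w <- abs(m$weights)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0L) return(0)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (m$n * (m$n - 1))
}

#' Global modularity
#'
#' Newman modularity Q of the best partition found by seeded Louvain
#' optimisation on the positive-weight subgraph. Negative edges are
#' excluded (the usual convention; their structure is what the energy
#' statistic captures).
#'
#' @param m A [connectivity_matrix()] (or square matrix).
#' @param seed Integer seed for the stochastic optimiser; fixed seeds
#'   give reproducible partitions.
#' @return Scalar Q in \eqn{[-1, 1]}; 0 when no positive edges exist.
#' @export
global_modularity <- function(m, seed = 1L) {
  m <- connectivity_matrix(m, allow_out_of_range = TRUE)
  w <- m$weights
  w[w < 0] <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0L) return(0)
  rng <- local_rng(seed)
  comm <- rng(function()
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight))
  igraph::modularity(g, igraph::membership(comm),
                     weights = igraph::E(g)$weight)
}

#' Long-format table of global graph measures for a cohort
#'
#' Mirrors [energy_table()]: one row per (subject, condition, scope)
#' with the three comparator measures.
#'
#' @param cohort Nested list `cohort[[subject]][[condition]]` of
#'   [connectivity_matrix()] objects, or a [generate_cohort()] result.
#' @param p A [parcellation()].
#' @param scopes Scopes to evaluate; default whole brain plus every
#'   network label in `p`.
#' @param seed Seed for the modularity optimiser.
#' @return `data.frame` with columns `subject_id`, `condition`, `scope`,
#'   `gcc`, `ge`, `gm`.
#' @export
measures_table <- function(cohort, p, scopes = NULL, seed = 1L) {
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$matrices
  if (is.null(scopes))
    scopes <- c(whole_brain(), sort(unique(p$network_label)))
  rows <- list()
  for (sid in names(cohort)) {
    for (cond in names(cohort[[sid]])) {
      m <- cohort[[sid]][[cond]]
      for (sc in scopes) {
        ids <- scope_regions(p, sc)
        keep <- m$region_ids %in% ids
        sub <- connectivity_matrix(m$weights[keep, keep, drop = FALSE],
                                   region_ids = m$region_ids[keep])
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, condition = cond, scope = sc,
          gcc = global_clustering(sub), ge = global_efficiency(sub),
          gm = global_modularity(sub, seed = seed),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
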