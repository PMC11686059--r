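# Independent pure-R oracles, deliberately naive: explicit loops, no
# reuse of the package's computation paths.

# random valid symmetric signed matrix with zero diagonal
rand_sym_matrix <- function(n, seed) {
  set.seed(seed)
  w <- matrix(stats::runif(n * n, -1, 1), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

scbrt <- function(x) sign(x) * abs(x)^(1 / 3)

# triple-loop energy oracle (independent of src/energy.cpp)
oracle_energy <- function(w) {
  n <- nrow(w)
  acc <- 0
  for (i in 1:(n - 2))
    for (j in (i + 1):(n - 1))
      for (k in (j + 1):n)
        acc <- acc + scbrt(w[i, j] * w[i, k] * w[j, k])
  -acc / choose(n, 3)
}

# triangle census oracle
oracle_census <- function(w) {
  n <- nrow(w)
  nb <- ni <- 0L; ib <- ii <- 0
  for (i in 1:(n - 2))
    for (j in (i + 1):(n - 1))
      for (k in (j + 1):n) {
        pr <- w[i, j] * w[i, k] * w[j, k]
        if (pr > 0) { nb <- nb + 1L; ib <- ib + scbrt(pr) }
        else if (pr < 0) { ni <- ni + 1L; ii <- ii - scbrt(pr) }
      }
  list(n_balanced = nb, n_imbalanced = ni,
       intensity_balanced = ib, intensity_imbalanced = ii)
}

# weighted clustering oracle: per-node triple loop (Onnela geometric mean)
oracle_clustering <- function(w) {
  w <- abs(w); diag(w) <- 0
  mx <- max(w)
  if (mx == 0) return(0)
  wh <- w / mx
  n <- nrow(w)
  ci <- numeric(n)
  for (i in 1:n) {
    nbrs <- which(w[i, ] > 0)
    k <- length(nbrs)
    if (k < 2) next
    s <- 0
    for (j in nbrs) for (l in nbrs)
      if (j != l) s <- s + (wh[i, j] * wh[j, l] * wh[l, i])^(1 / 3)
    ci[i] <- s / (k * (k - 1))
  }
  mean(ci)
}

# all-pairs shortest paths (Floyd-Warshall) efficiency oracle
oracle_efficiency <- function(w) {
  w <- abs(w); diag(w) <- 0
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# all set partitions of 1..n (Bell-number enumeration, small n only)
all_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1L)) {
    for (b in seq_along(p)) {
      q <- p; q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# exhaustive-maximum Newman modularity on the positive subgraph
oracle_max_modularity <- function(w) {
  w[w < 0] <- 0; diag(w) <- 0
  tw <- sum(w) / 2
  deg <- rowSums(w)
  qval <- function(memb) {
    s <- 0
    for (c in unique(memb)) {
      idx <- memb == c
      s <- s + sum(w[idx, idx]) / (2 * tw) - (sum(deg[idx]) / (2 * tw))^2
    }
    s
  }
  best <- -Inf
  for (p in all_partitions(nrow(w))) {
    memb <- integer(nrow(w))
    for (b in seq_along(p)) memb[p[[b]]] <- b
    best <- max(best, qval(memb))
  }
  best
}

# exact two-sided signed-rank p by enumeration of all sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wdist <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(wdist <= w_obs), mean(wdist >= w_obs)))
}
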