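# Independent oracles and small generators used across the suite.
# Everything here is deliberately naive (loops, literal enumeration) and
# shares no code with the package internals it checks.

# Eq.-style single-observation probability, plain arithmetic
oracle_p_obs <- function(d, delta, alpha, beta) {
  if (is.na(d)) return(1)
  if (delta == 0) { if (d == 0) 1 - alpha else alpha }
  else            { if (d == 0) beta else 1 - beta }
}

# per-site per-clone likelihood by direct double loop over cells
oracle_site_clone_probs <- function(D, tr, alpha, beta) {
  A <- oracle_ancestry(tr)
  m <- ncol(D); N <- tr$N
  P <- matrix(NA_real_, m, N - 1L)
  for (l in seq_len(m)) {
    for (c in 2:N) {
      pr <- 1
      for (k in seq_len(nrow(D))) {
        delta <- as.integer(A[c, tr$assignment[rownames(D)[k]]])
        pr <- pr * oracle_p_obs(D[k, l], delta, alpha, beta)
      }
      P[l, c - 1L] <- pr
    }
  }
  P
}

# marginal likelihood via per-site averaging (factorised form)
oracle_marginal_loglik <- function(D, tr, alpha, beta) {
  P <- oracle_site_clone_probs(D, tr, alpha, beta)
  sum(log(rowMeans(P)))
}

# marginal likelihood via literal summation over every full theta
# assignment (the unfactorised definition); exponential in m
oracle_marginal_loglik_full_sum <- function(D, tr, alpha, beta) {
  P <- oracle_site_clone_probs(D, tr, alpha, beta)
  m <- nrow(P); C <- ncol(P)
  grid <- as.matrix(expand.grid(rep(list(seq_len(C)), m)))
  probs <- exp(rowSums(matrix(log(P[cbind(rep(seq_len(m), each = nrow(grid)),
                                          as.vector(grid))]),
                              nrow(grid), m)))
  log(sum(probs)) - m * log(C)
}

# ancestry by repeatedly following parent pointers
oracle_ancestry <- function(tr) {
  N <- tr$N
  A <- matrix(FALSE, N, N)
  for (c in seq_len(N)) {
    cur <- c
    repeat {
      A[cur, c] <- TRUE
      cur <- tr$parent[cur]
      if (is.na(cur)) break
    }
  }
  A
}

# all-pairs shortest paths on the undirected clone graph by BFS
oracle_clone_distances <- function(tr) {
  N <- tr$N
  adj <- vector("list", N)
  for (c in seq_len(N)[-1L]) {
    p <- tr$parent[c]
    adj[[c]] <- c(adj[[c]], p); adj[[p]] <- c(adj[[p]], c)
  }
  D <- matrix(NA_integer_, N, N)
  for (s in seq_len(N)) {
    dist <- rep(NA_integer_, N); dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L; queue <- c(queue, w)
      }
    }
    D[s, ] <- dist
  }
  D
}

# all rooted trees on N labelled clones (root = 1) as parent vectors
enumerate_parent_vectors <- function(N) {
  if (N == 1L) return(list(NA_integer_))
  choices <- rep(list(seq_len(N)), N - 1L)
  grid <- as.matrix(expand.grid(choices))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    pv <- c(NA_integer_, as.integer(grid[i, ]))
    if (any(pv[-1L] == seq_len(N)[-1L])) next  # self-parenting
    ok <- TRUE
    for (c in seq_len(N)[-1L]) {            # must reach the root
      cur <- c; steps <- 0L
      while (cur != 1L) {
        cur <- pv[cur]; steps <- steps + 1L
        if (steps > N) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) out[[length(out) + 1L]] <- pv
  }
  out
}

# random valid clonal tree over given cells (independent of the simulator)
random_tree <- function(n_clones, cells, p_unobserved = 0) {
  N <- n_clones + 1L
  parent <- rep(NA_integer_, N)
  if (N >= 2L) parent[2L] <- 1L
  for (c in seq_len(N)[-(1:2)])
    parent[c] <- if (c == 3L) 2L else sample(2:(c - 1L), 1L)
  # assign every cell to a uniformly chosen non-root clone, but make sure
  # clones needed for validity exist; unobserved clones arise naturally
  asg <- 1L + sample.int(N - 1L, length(cells), replace = TRUE)
  names(asg) <- cells
  clonal_tree(parent, asg)
}

random_genotypes <- function(n, m, p_na = 0.15,
                             cells = paste0("c", seq_len(n))) {
  x <- matrix(sample(0:1, n * m, replace = TRUE), n, m,
              dimnames = list(cells, paste0("s", seq_len(m))))
  x[sample.int(n * m, round(p_na * n * m))] <- NA_integer_
  suppressWarnings(genotype_matrix(x))
}
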