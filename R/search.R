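#' Search configuration
#'
#' Tuning knobs of the three-step inference.
#'
#' @param epsilon Bayes factor threshold (> 1). A latent clone is added
#'   only if it improves the marginal likelihood by more than a factor
#'   `epsilon`; a cell merge is kept only while the likelihood stays
#'   within a factor `1/epsilon` of the best clustering seen. Default 10
#'   ("strong evidence" on Jeffreys's scale).
#' @param max_stall accepted moves without improving the best score before
#'   the climb is abandoned and the search backtracks
#' @param backtrack_pool number of best previously seen, not yet expanded
#'   solutions the search may return to after stalling
#' @param max_iter hard cap on the number of scored trees
#' @param seed integer seed recorded with results (the search itself is
#'   deterministic; the seed governs simulation-based callers)
#' @return object of class `search_config`
#' @export
search_config <- function(epsilon = 10, max_stall = 5, backtrack_pool = 10,
                          max_iter = 2e5, seed = 1L) {
  if (epsilon <= 1) stop("epsilon must exceed 1")
  if (max_stall < 1 || backtrack_pool < 1 || max_iter < 1)
    stop("all search counts must be >= 1")
  structure(list(epsilon = epsilon, max_stall = as.integer(max_stall),
                 backtrack_pool = as.integer(backtrack_pool),
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "search_config")
}

# --- scorer -----------------------------------------------------------------
# Closure over (D, E). Caches the per-entry evidence W = L1 - L0 once; a
# tree is scored with one (N x n) . (n x m) product. Neighborhoods are
# scored incrementally: a prune-and-regraft of subtree v only rescales the
# likelihood terms of the clones on the old and new ancestor paths, so the
# per-site sum over clones is updated with two vector operations per
# neighbor. Exact from-scratch scoring is used as fallback whenever the
# incremental update is not finite.
make_scorer <- function(D, E) {
  tab <- obs_loglik_tables(D, E)
  m <- ncol(D)
  cells <- rownames(D)
  lognm1 <- function(N) m * log(N - 1)

  score_state <- function(tr) {
    # assumes tr$cells in the same order as rownames(D)
    A <- ancestry(tr)
    Dlt <- A[, tr$assignment, drop = FALSE]
    storage.mode(Dlt) <- "double"
    Smat <- Dlt %*% tab$W                       # N x m, row 1 is "normal"
    Smat <- Smat + rep(1, tr$N) %o% tab$base
    Smat[1L, ] <- -Inf                          # the root is never an origin
    Moff <- Smat[2L, ]
    if (tr$N > 2L)
      for (r in 3L:tr$N) Moff <- pmax(Moff, Smat[r, ])
    Moff[!is.finite(Moff)] <- 0
    Eexp <- exp(Smat - rep(1, tr$N) %o% Moff)
    Z <- colSums(Eexp[-1L, , drop = FALSE])
    loglik <- sum(Moff + log(Z)) - lognm1(tr$N)
    list(tr = tr, A = A, Smat = Smat, Moff = Moff, Eexp = Eexp, Z = Z,
         loglik = loglik)
  }

  score_tree <- function(tr) score_state(tr)$loglik

  # Per-node reattachment precomputation on a state: moving the subtree
  # of v rescales the terms of the clones on the old and new ancestor
  # paths only, so every target is scored with two O(m) vector updates.
  reattach_setup <- function(st, v) {
    tr <- st$tr
    N <- tr$N
    wv <- (st$A[v, tr$assignment, drop = FALSE] %*% tab$W)[1L, ]
    em <- exp(-wv)
    p <- tr$parent[v]
    ancp <- ancestors_of(tr$parent, p)
    Ev <- st$Eexp
    if (length(ancp))
      Ev[ancp, ] <- Ev[ancp, , drop = FALSE] * (rep(1, length(ancp)) %o% em)
    Zbase <- st$Z -
      (if (length(ancp)) colSums(st$Eexp[ancp, , drop = FALSE]) else 0) +
      (if (length(ancp)) colSums(Ev[ancp, , drop = FALSE]) else 0)
    # path sums cum[x, ] = sum of Ev rows on root..x (root excluded);
    # c is on the path to x iff x lies in the subtree of c
    cum <- crossprod(st$A[-1L, , drop = FALSE], Ev[-1L, , drop = FALSE])
    list(Zbase = Zbase, cum = cum, epm1 = exp(wv) - 1, em = em, ancp = ancp)
  }

  # scores for all moves (v, target, type) given the expanded state of
  # the current tree; all targets of one node are scored as one matrix
  # operation, with exact from-scratch scoring as the non-finite fallback
  score_moves <- function(st, moves) {
    if (!nrow(moves)) return(numeric(0))
    tr <- st$tr
    N <- tr$N
    out <- numeric(nrow(moves))
    batch <- function(su, Moffsum, targets, extra = NULL) {
      k <- length(targets)
      Zmat <- su$cum[targets, , drop = FALSE] * rep(su$epm1, each = k) +
        rep(su$Zbase, each = k)
      if (!is.null(extra)) Zmat <- Zmat + extra
      Moffsum + rowSums(log(Zmat)) - lognm1(N)
    }
    for (v in unique(moves[, 1L])) {
      rows1 <- which(moves[, 1L] == v & moves[, 3L] == 1L)
      if (length(rows1)) {
        su <- reattach_setup(st, v)
        out[rows1] <- batch(su, sum(st$Moff), moves[rows1, 2L])
      }
      rows23 <- which(moves[, 1L] == v & moves[, 3L] != 1L)
      if (length(rows23)) {
        # splice moves are scored on the hoisted state, where v is a leaf
        kid <- which(!is.na(tr$parent) & tr$parent == v)
        stH <- if (length(kid)) {
          hp <- tr$parent
          hp[kid] <- tr$parent[v]
          score_state(new_tree(hp, tr$assignment, tr$cells))
        } else st
        su <- reattach_setup(stH, v)
        MoffsumH <- sum(stH$Moff)
        r2 <- rows23[moves[rows23, 3L] == 2L]
        if (length(r2))
          out[r2] <- batch(su, MoffsumH, moves[r2, 2L])
        r3 <- rows23[moves[rows23, 3L] == 3L]
        if (length(r3)) {
          WSH <- stH$A[, stH$tr$assignment, drop = FALSE] %*% tab$W
          hp <- stH$tr$parent
          ys <- moves[r3, 2L]
          k <- length(ys)
          # subtree weight of y without v's own cells when v sat below y
          WY <- exp(WSH[ys, , drop = FALSE])
          sel <- ys %in% su$ancp
          if (any(sel))
            WY[sel, ] <- WY[sel, , drop = FALSE] * rep(su$em, each = sum(sel))
          extra <- (WY - 1) * rep(stH$Eexp[v, ], each = k)
          out[r3] <- batch(su, MoffsumH, hp[ys], extra = extra)
        }
      }
    }
    bad <- which(!is.finite(out))
    for (b in bad)
      out[b] <- score_tree(apply_move(tr, moves[b, 1L], moves[b, 2L],
                                      moves[b, 3L]))
    out
  }

  list(score_state = score_state, score_tree = score_tree,
       score_moves = score_moves, m = m, cells = cells)
}

# --- step 1: initial cell-tree search ---------------------------------------

# Greedy sequential-insertion seed tree: cells are added in order of
# increasing mutation count (ancestral cells carry fewer mutations under
# the no-loss assumption), each attached to whichever existing node
# maximises the marginal log-likelihood of the partial data. Gives the
# hill climb a second, independently constructed basin besides the star.
insertion_tree <- function(D, E) {
  d <- unclass(D)
  n <- nrow(d); m <- ncol(d)
  tab <- obs_loglik_tables(D, E)
  L0 <- tab$L0
  ord <- order(rowSums(d == 1L, na.rm = TRUE), rownames(d))
  parent <- NA_integer_            # over clones 1..i+1, clone j+1 = ord[j]
  score_partial <- function(parent_vec, idx) {
    nn <- length(parent_vec)
    tr <- list(parent = parent_vec, N = nn)
    A <- ancestry_parent(parent_vec)
    Dlt <- A[-1L, -1L, drop = FALSE]   # cell j in clone j+1
    storage.mode(Dlt) <- "double"
    Smat <- Dlt %*% tab$W[idx, , drop = FALSE] +
      rep(1, nn - 1L) %o% colSums(L0[idx, , drop = FALSE])
    M <- apply(Smat, 2L, max)
    M[!is.finite(M)] <- 0
    sum(M + log(colSums(exp(Smat - rep(1, nn - 1L) %o% M)))) -
      m * log(nn - 1L)
  }
  parent <- c(NA_integer_, 1L)
  for (i in seq_len(n)[-1L]) {
    idx <- ord[seq_len(i)]
    best_p <- 1L; best_ll <- -Inf
    for (p in seq_len(i)) {        # existing clones 1..i
      cand <- c(parent, p)
      ll <- score_partial(cand, idx)
      if (ll > best_ll + 1e-9) { best_ll <- ll; best_p <- p }
    }
    parent <- c(parent, best_p)
  }
  # re-express with clone numbering aligned to rownames(D)
  tgt <- c(1L, match(rownames(d)[ord], rownames(d)) + 1L)
  new_parent <- rep(NA_integer_, n + 1L)
  new_parent[tgt[-1L]] <- tgt[parent[-1L]]
  asg <- seq_len(n) + 1L
  names(asg) <- rownames(d)
  clonal_tree(new_parent, asg)
}

# ancestry from a bare parent vector (no cells attached)
ancestry_parent <- function(parent) {
  N <- length(parent)
  A <- diag(TRUE, N)
  for (c in rev(topo_order(parent))) {
    p <- parent[c]
    if (!is.na(p)) A[p, ] <- A[p, ] | A[c, ]
  }
  A
}

#' Initial search over cell lineage trees
#'
#' Heuristic hill climbing in the space of trees where every cell is its
#' own clone, seeded by the star tree and by a greedy sequential-insertion
#' tree. Climbs are steepest-ascent over the prune-and-regraft
#' neighborhood; to escape local optima the search keeps the
#' `backtrack_pool` best solutions seen together with their scored,
#' not-yet-expanded neighbors and restarts climbs from the best of those
#' neighbors. `max_stall` bounds non-improving moves within a climb, and
#' the search ends when the pool is exhausted, `backtrack_pool`
#' consecutive restarts fail to improve the incumbent, or `max_iter`
#' trees have been scored. Deterministic: ties break on the lowest move
#' index.
#'
#' @param D a [genotype_matrix()]
#' @param E an [error_model()]
#' @param cfg a [search_config()]
#' @return object of class `inference_result`: list with elements `tree`,
#'   `loglik`, `alpha`, `beta`, `trace`, `n_scored`
#' @export
initial_search <- function(D, E, cfg = search_config()) {
  sc <- make_scorer(D, E)
  star <- star_tree(rownames(D))
  star_ll <- sc$score_tree(star)
  seeds <- list(star)
  n_seed_cost <- 1L
  if (length(rownames(D)) >= 2L) {
    seeds[[2L]] <- insertion_tree(D, E)   # greedy multi-start seed
    n_seed_cost <- n_seed_cost + length(rownames(D))^2
  }
  out <- pooled_search(sc, seeds, cfg)
  trace <- list(list(stage = "star", loglik = star_ll),
                list(stage = "initial_search", loglik = out$loglik))
  structure(list(tree = out$tree, loglik = out$loglik,
                 alpha = E$alpha, beta = E$beta,
                 trace = trace, n_scored = out$n_scored + n_seed_cost,
                 hit_max_iter = out$hit_max_iter),
            class = "inference_result")
}

# Backtracking steepest-ascent search from one or more seed trees.
# The pool keeps the backtrack_pool highest-scoring expanded solutions
# together with their scored, not yet expanded neighbors. A climb is
# abandoned at a local optimum, or after max_stall consecutive accepted
# moves that fail to improve the incumbent; the search then backtracks
# to the best unexpanded neighbor of any pooled solution. It terminates
# when the pool is exhausted or max_iter trees have been scored.
# Deterministic: ties break on the lowest move index.
pooled_search <- function(sc, seeds, cfg,
                          fail_limit = cfg$backtrack_pool) {
  st <- sc$score_state(seeds[[1L]])
  best_tr <- st$tr; best_ll <- st$loglik
  assignment <- st$tr$assignment
  n_scored <- length(seeds)
  fail_climbs <- 0L
  climb_base <- best_ll
  expanded <- new.env(hash = TRUE, parent = emptyenv())
  pool <- list()      # expanded solutions: parent, score, cand (moves+scores)
  queue <- list()     # unclimbed seed trees, visited before backtracking
  for (s in seeds[-1L]) {
    ll <- sc$score_tree(s)
    queue[[length(queue) + 1L]] <- list(parent = s$parent, score = ll)
    if (ll > best_ll + 1e-9) { best_ll <- ll; best_tr <- s }
  }
  stall <- 0L

  repeat {
    assign(tree_key(st$tr), TRUE, envir = expanded)
    moves <- neighbor_moves(st$tr)
    lls <- sc$score_moves(st, moves)
    n_scored <- n_scored + length(lls)
    # record this solution and its scored neighborhood in the pool
    pool[[length(pool) + 1L]] <- list(parent = st$tr$parent,
                                      score = st$loglik,
                                      moves = moves, cand_ll = lls)
    if (length(pool) > cfg$backtrack_pool) {
      sc_ <- vapply(pool, `[[`, 0, "score")
      pool[[which.min(sc_)]] <- NULL
    }
    # steepest ascent: best not-yet-expanded neighbor strictly above current
    cand <- NA
    if (length(lls)) {
      ord <- order(-lls)
      for (i in ord) {
        if (lls[i] <= st$loglik + 1e-9) break
        pv <- move_parent(st$tr$parent, moves[i, 1L], moves[i, 2L],
                          moves[i, 3L])
        if (!exists(paste(pv[-1L], collapse = ","), envir = expanded)) {
          cand <- i; break
        }
      }
    }
    if (!is.na(cand) && n_scored < cfg$max_iter && stall < cfg$max_stall) {
      st <- sc$score_state(apply_move(st$tr, moves[cand, 1L],
                                      moves[cand, 2L], moves[cand, 3L]))
      if (st$loglik > best_ll + 1e-9) {
        best_ll <- st$loglik; best_tr <- st$tr; stall <- 0L
      } else stall <- stall + 1L
      next
    }
    # local optimum, stalled climb or iteration cap: this climb is over
    stall <- 0L
    if (best_ll <= climb_base + 1e-9) fail_climbs <- fail_climbs + 1L
    climb_base <- best_ll
    if (n_scored >= cfg$max_iter) break
    # un-climbed seeds take priority over backtracking
    if (length(queue)) {
      entry <- queue[[1L]]; queue[[1L]] <- NULL
      st <- sc$score_state(new_tree(entry$parent, assignment))
      next
    }
    if (fail_climbs >= fail_limit) break
    # backtrack: best unexpanded neighbor of any pooled solution
    nxt <- NULL; nxt_ll <- -Inf
    for (j in seq_along(pool)) {
      entry <- pool[[j]]
      keep <- rep(TRUE, length(entry$cand_ll))
      for (i in order(-entry$cand_ll)) {
        if (entry$cand_ll[i] <= nxt_ll + 1e-9) break
        pv <- move_parent(entry$parent, entry$moves[i, 1L],
                          entry$moves[i, 2L], entry$moves[i, 3L])
        if (exists(paste(pv[-1L], collapse = ","), envir = expanded)) {
          keep[i] <- FALSE
        } else {
          nxt <- pv; nxt_ll <- entry$cand_ll[i]
          break
        }
      }
      if (!all(keep)) {   # drop dead candidates so later scans shrink
        pool[[j]]$moves <- entry$moves[keep, , drop = FALSE]
        pool[[j]]$cand_ll <- entry$cand_ll[keep]
      }
    }
    if (is.null(nxt)) break
    st <- sc$score_state(new_tree(nxt, assignment))
    if (st$loglik > best_ll + 1e-9) { best_ll <- st$loglik; best_tr <- st$tr }
  }
  list(tree = best_tr, loglik = best_ll, n_scored = n_scored,
       hit_max_iter = n_scored >= cfg$max_iter)
}

#' @export
print.inference_result <- function(x, ...) {
  cat("Clonal tree inference result\n")
  cat(sprintf("  log-likelihood: %.4f  (alpha = %g, beta = %g)\n",
              x$loglik, x$alpha, x$beta))
  print(x$tree)
  invisible(x)
}

# --- step 2: unobserved clones ----------------------------------------------

#' Test for unobserved clones
#'
#' Iteratively inserts a latent (cell-free) clone at each branch point of
#' the current tree, uses all the insertion trees as start trees of one
#' new backtracking search over the enlarged model, and accepts its
#' result if and only if the marginal log-likelihood exceeds the current
#' one by more than `log(epsilon)` (a Bayes factor test; the
#' `1/(N-1)^m` prior term penalises the extra clone automatically).
#' Accepted expansions repeat until the test fails.
#'
#' @param res an `inference_result` (from [initial_search()])
#' @inheritParams initial_search
#' @return an updated `inference_result`
#' @export
add_unobserved_clones <- function(res, D, E, cfg = search_config()) {
  sc <- make_scorer(D, E)
  cur <- res$tree; cur_ll <- res$loglik
  log_eps <- log(cfg$epsilon)
  repeat {
    bps <- branch_points(cur)
    if (!length(bps)) break
    # the insertion trees of all branch points seed one new search over
    # the enlarged model: all nodes may move, so subsets of a branch
    # point's children can migrate back while the latent clone finds its
    # place
    seeds <- lapply(bps, function(b) insert_unobserved(cur, b))
    out <- pooled_search(sc, seeds, cfg)
    if (out$loglik - cur_ll > log_eps) {
      cur <- out$tree; cur_ll <- out$loglik
    } else break
  }
  res$tree <- cur; res$loglik <- cur_ll
  res$trace[[length(res$trace) + 1L]] <-
    list(stage = "add_unobserved_clones", loglik = cur_ll)
  res
}

# --- step 3: clustering cells into clones -----------------------------------

#' Cluster cells into clones
#'
#' Greedily merges clones into their parents (never into the root) while
#' the marginal log-likelihood stays above the best clustering solution
#' seen so far minus `log(epsilon)`. Merge rounds are interleaved with
#' steepest-ascent prune-and-regraft moves at the clone level, so cells
#' that were slightly misplaced in the cell tree can regroup as clones
#' coalesce; the refinement only ever accepts strict improvements, so the
#' Bayes-factor tolerance applies to merges alone. Afterwards, latent
#' clones left with fewer than two children are spliced out.
#'
#' @param res an `inference_result`
#' @inheritParams initial_search
#' @return an updated `inference_result` holding the final clonal lineage
#'   tree
#' @export
cluster_cells <- function(res, D, E, cfg = search_config()) {
  sc <- make_scorer(D, E)
  cur <- res$tree; cur_ll <- res$loglik
  log_eps <- log(cfg$epsilon)
  best_so_far <- cur_ll
  repeat {
    progress <- FALSE
    # merge rounds: best merge first, tolerated while within log(eps) of
    # the best clustering solution seen so far
    repeat {
      merged <- merge_candidates(cur)
      if (!length(merged)) break
      lls <- vapply(merged, sc$score_tree, 0)
      j <- which.max(lls)
      if (lls[j] > best_so_far - log_eps) {
        cur <- merged[[j]]; cur_ll <- lls[j]
        best_so_far <- max(best_so_far, cur_ll)
        progress <- TRUE
      } else break
    }
    # clone-level refinement: strict steepest ascent over prune-and-regraft
    st <- sc$score_state(cur)
    repeat {
      moves <- neighbor_moves(st$tr)
      if (!nrow(moves)) break
      lls <- sc$score_moves(st, moves)
      j <- which.max(lls)
      if (lls[j] <= st$loglik + 1e-9) break
      st2 <- sc$score_state(apply_move(st$tr, moves[j, 1L], moves[j, 2L],
                                       moves[j, 3L]))
      if (st2$loglik <= st$loglik + 1e-9) break  # exact score is authoritative
      st <- st2
      progress <- TRUE
    }
    if (st$loglik > cur_ll + 1e-9) {
      cur <- st$tr; cur_ll <- st$loglik
      best_so_far <- max(best_so_far, cur_ll)
    }
    if (!progress) break
  }
  cur <- prune_linear_unobserved(cur)
  cur_ll <- sc$score_tree(cur)
  res$tree <- cur; res$loglik <- cur_ll
  res$trace[[length(res$trace) + 1L]] <-
    list(stage = "cluster_cells", loglik = cur_ll)
  res
}

# candidate clusterings one merge away: each non-root clone merged into
# its parent (when the parent is not the root) and into each of its
# siblings (equivalent to a regraft followed by a parent merge, offered
# as one step so greedy clustering can reach it)
merge_candidates <- function(tr) {
  kids <- children_list(tr$parent)
  out <- list()
  for (ch in seq_len(tr$N)[-1L]) {
    p <- tr$parent[ch]
    if (p != 1L)
      out[[length(out) + 1L]] <- merge_edge(tr, ch, p)
    for (s in kids[[p]]) {
      if (s == ch) next
      out[[length(out) + 1L]] <- merge_edge(apply_move(tr, ch, s), ch, s)
    }
  }
  out
}

# --- driver -----------------------------------------------------------------

#' Infer a clonal lineage tree
#'
#' Full three-step inference: initial cell-tree search, Bayes-factor
#' testing for unobserved clones, and clustering of cells into clones.
#' When `E` is `NULL` the error rates are first estimated by grid maximum
#' likelihood ([estimate_parameters()]) and the best grid cell's result is
#' returned.
#'
#' @param D a [genotype_matrix()]
#' @param E an [error_model()], or `NULL` to estimate the rates
#' @param cfg a [search_config()]
#' @param grid a [parameter_grid()] used when `E` is `NULL`
#' @return an `inference_result`; `trace` records the three stages
#' @export
infer <- function(D, E = NULL, cfg = search_config(),
                  grid = parameter_grid()) {
  if (is.null(E)) {
    est <- estimate_parameters(D, grid, cfg)
    res <- est$result
    res$trace[[length(res$trace) + 1L]] <-
      list(stage = "estimate_parameters", loglik = res$loglik)
    return(res)
  }
  res <- initial_search(D, E, cfg)
  res <- add_unobserved_clones(res, D, E, cfg)
  res <- cluster_cells(res, D, E, cfg)
  res
}
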