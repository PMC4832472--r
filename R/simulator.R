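#' Simulation configuration
#'
#' Knobs of the two-step data simulator. Defaults are the study's
#' reference scenario: ten tumor clones (none unobserved), 20 cells, 200
#' variant sites, false positive rate 0.2, false negative rate 0.1 and
#' 20\% missing values.
#'
#' @param n_clones number of tumor clones (the root normal is extra)
#' @param n_unobserved how many of them carry no sampled cells; must
#'   leave at least one cell per observed clone
#' @param n_cells number of sampled cells
#' @param n_sites number of somatic variant sites
#' @param alpha false positive rate applied to truly unmutated entries
#' @param beta false negative rate applied to truly mutated entries
#' @param p_missing fraction of entries set to `NA`
#' @param seed integer seed, or `NULL` to use the current RNG state
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(n_clones = 10, n_unobserved = 0,
                              n_cells = 20, n_sites = 200,
                              alpha = 0.2, beta = 0.1,
                              p_missing = 0.2, seed = NULL) {
  if (n_unobserved >= n_clones)
    stop("n_unobserved must be smaller than n_clones")
  if (n_cells < n_clones - n_unobserved)
    stop("need at least one cell per observed clone")
  if (alpha < 0 || alpha >= 1 || beta < 0 || beta >= 1 ||
      p_missing < 0 || p_missing >= 1)
    stop("alpha, beta and p_missing must lie in [0, 1)")
  structure(list(n_clones = as.integer(n_clones),
                 n_unobserved = as.integer(n_unobserved),
                 n_cells = as.integer(n_cells),
                 n_sites = as.integer(n_sites),
                 alpha = alpha, beta = beta, p_missing = p_missing,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a random clonal lineage tree
#'
#' Clone 1 is the root and parent of clone 2; every further clone attaches
#' to a uniformly chosen existing non-root clone. When unobserved clones
#' are requested, trees are re-simulated until at least `n_unobserved`
#' clones have two or more children, and that many branch clones are then
#' chosen uniformly to be unobserved. One cell is assigned to every
#' observed clone; the remaining cells join clones iteratively with
#' probability proportional to current clone size (a Chinese-restaurant
#' style rich-get-richer scheme producing clones of uneven size).
#'
#' @param cfg a [simulation_config()]
#' @return a `clonal_tree` with `n_clones + 1` clones and `n_cells` cells
#' @export
simulate_tree <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  simulate_tree_impl(cfg)
}

simulate_tree_impl <- function(cfg) {
  N <- cfg$n_clones + 1L
  attempts <- 0L
  repeat {
    parent <- rep(NA_integer_, N)
    if (N >= 2L) parent[2L] <- 1L
    for (c in seq_len(N)[-(1:2)])
      parent[c] <- if (c == 3L) 2L else
        sample(2:(c - 1L), 1L)
    nkid <- tabulate(parent[-1L], nbins = N)
    branch_nodes <- which(nkid >= 2L)
    if (cfg$n_unobserved == 0L || length(branch_nodes) >= cfg$n_unobserved)
      break
    attempts <- attempts + 1L
    if (attempts > 1e5)
      stop("could not simulate a tree with ", cfg$n_unobserved,
           " branch clones; configuration looks infeasible")
  }
  unobserved <- if (cfg$n_unobserved > 0L)
    branch_nodes[sample.int(length(branch_nodes), cfg$n_unobserved)]
  else integer(0)
  observed <- setdiff(seq_len(N)[-1L], unobserved)
  # one cell per observed clone, then proportional-to-size assignment
  asg <- observed
  for (k in seq_len(cfg$n_cells - length(observed))) {
    sizes <- tabulate(asg, nbins = N)[observed]
    asg <- c(asg, observed[sample.int(length(observed), 1L, prob = sizes)])
  }
  names(asg) <- paste0("cell", seq_along(asg))
  clonal_tree(parent, asg)
}

#' Simulate noisy genotype observations from a tree
#'
#' Each site's origin clone is drawn uniformly from the non-root clones
#' (latent clones included); the true genotype of a cell is 1 iff the
#' origin is the cell's clone or one of its ancestors (infinite sites, no
#' loss). Noise is applied to the true matrix in three steps on disjoint
#' entry sets: (1) a fraction `p_missing` of entries becomes `NA`, (2) a
#' fraction `alpha` of unmutated non-missing entries flips to 1, (3) a
#' fraction `beta` of mutated non-missing entries flips to 0. Fractions
#' are realised as exact counts (`round`) so noise levels are
#' reproducible even for small matrices. Any site left without a single
#' observed mutation afterwards receives one false positive at a random
#' cell, and the cell order of the output matrix is randomised.
#'
#' @param tr a `clonal_tree` (e.g. from [simulate_tree()])
#' @param cfg a [simulation_config()]; the seed field is ignored here (the
#'   caller controls the RNG), use [simulate_dataset()] for seeded
#'   end-to-end simulation
#' @return list with `genotypes` (a [genotype_matrix()], rows in
#'   randomised cell order) and `truth` (list: `tree`, `theta`,
#'   `true_genotypes`)
#' @export
simulate_genotypes <- function(tr, cfg) {
  n <- length(tr$cells); m <- cfg$n_sites
  N <- tr$N
  theta <- sample(2:N, m, replace = TRUE)
  A <- ancestry(tr)
  # true genotype: origin clone is ancestor-or-self of the cell's clone
  G_true <- t(A[theta, tr$assignment, drop = FALSE]) * 1L
  dimnames(G_true) <- list(tr$cells, paste0("site", seq_len(m)))
  G <- G_true
  storage.mode(G) <- "integer"
  # (1) missing values
  n_na <- round(cfg$p_missing * n * m)
  na_idx <- sample.int(n * m, n_na)
  G[na_idx] <- NA_integer_
  # (2) false positives among truly unmutated, non-missing entries
  zero_idx <- which(!is.na(G) & G_true == 0L)
  n_fp <- round(cfg$alpha * length(zero_idx))
  if (n_fp > 0L) G[sample(zero_idx, n_fp)] <- 1L
  # (3) false negatives among truly mutated, non-missing entries
  one_idx <- which(!is.na(G) & G_true == 1L)
  n_fn <- round(cfg$beta * length(one_idx))
  if (n_fn > 0L) G[sample(one_idx, n_fn)] <- 0L
  # rescue: every site must report at least one mutation
  dead <- which(colSums(G == 1L, na.rm = TRUE) == 0L)
  for (l in dead) G[sample.int(n, 1L), l] <- 1L
  # randomise cell order (identifiers travel with the rows)
  G <- G[sample.int(n), , drop = FALSE]
  list(genotypes = genotype_matrix(G),
       truth = list(tree = tr, theta = theta, true_genotypes = G_true))
}

#' Simulate a complete dataset
#'
#' Seeds the RNG from `cfg$seed` (when set), simulates a tree and then a
#' noisy genotype matrix from it.
#'
#' @param cfg a [simulation_config()]
#' @return as [simulate_genotypes()]
#' @export
simulate_dataset <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tr <- simulate_tree_impl(cfg)
  simulate_genotypes(tr, cfg)
}
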