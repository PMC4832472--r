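test_that("search configuration validates its thresholds", {
  expect_error(search_config(epsilon = 1), "exceed 1")
  expect_error(search_config(max_stall = 0), ">= 1")
  expect_s3_class(search_config(), "search_config")
})

test_that("incremental neighborhood scores agree with from-scratch scoring", {
  set.seed(123)
  for (i in 1:15) {
    n <- sample(3:7, 1)
    cfg <- simulation_config(n_clones = sample(2:4, 1), n_cells = n,
                             n_sites = 15, alpha = 0.1, beta = 0.1,
                             p_missing = 0.15, seed = 9000 + i)
    sim <- simulate_dataset(cfg)
    D <- sim$genotypes
    E <- error_model(runif(1, 0.02, 0.3), runif(1, 0.02, 0.3))
    sc <- cellnem:::make_scorer(D, E)
    tr <- random_tree(sample(2:4, 1), rownames(D))
    st <- sc$score_state(tr)
    moves <- cellnem:::neighbor_moves(tr)
    fast <- sc$score_moves(st, moves)
    slow <- vapply(seq_len(nrow(moves)), function(j)
      marginal_loglik(D, cellnem:::apply_move(tr, moves[j, 1], moves[j, 2],
                                              moves[j, 3]), E),
      0)
    expect_equal(fast, slow, tolerance = 1e-9)
  }
})

test_that("two-cell inputs are solved by enumeration of all three trees", {
  D <- genotype_matrix(matrix(c(1L, 1L, 0L, 1L), 2, 2,
                              dimnames = list(c("a", "b"), c("s1", "s2"))))
  E <- error_model(0.05, 0.05)
  res <- initial_search(D, E, search_config())
  lls <- vapply(enumerate_parent_vectors(3L), function(pv)
    marginal_loglik(D, clonal_tree(pv, res$tree$assignment), E), 0)
  expect_equal(res$loglik, max(lls), tolerance = 1e-9)
  # b carries a superset of a's mutations: a should be ancestral to b
  expect_equal(res$tree$parent, c(NA, 1L, 2L))
})

test_that("the initial search never returns below the star tree", {
  set.seed(31)
  for (i in 1:5) {
    cfg <- simulation_config(n_clones = 3, n_cells = 6, n_sites = 20,
                             alpha = 0.2, beta = 0.2, p_missing = 0.3,
                             seed = 600 + i)
    sim <- simulate_dataset(cfg)
    E <- error_model(0.2, 0.2)
    res <- initial_search(sim$genotypes, E, search_config())
    star_ll <- marginal_loglik(sim$genotypes,
                               star_tree(rownames(sim$genotypes)), E)
    expect_gte(res$loglik, star_ll - 1e-9)
    # cell trees only: no latent clones, every cell its own clone
    expect_equal(res$tree$N, nrow(sim$genotypes) + 1L)
    expect_true(all(observed_clones(res$tree)[-1L]))
  }
})

test_that("noise-free four-cell chains are recovered exactly", {
  # deterministic chain truth: c1 -> c2 -> c3 -> c4 below the root
  pv <- c(NA, 1L, 2L, 3L, 4L)
  asg <- stats::setNames(2:5, paste0("c", 1:4))
  truth <- clonal_tree(pv, asg)
  set.seed(44)
  theta <- sample(2:5, 24, replace = TRUE)
  A <- ancestry(truth)
  G <- t(A[theta, asg]) * 1L
  rownames(G) <- names(asg); colnames(G) <- paste0("s", seq_along(theta))
  D <- genotype_matrix(G)
  E <- error_model(1e-9, 1e-9)
  res <- initial_search(D, E, search_config())
  best <- max(vapply(enumerate_parent_vectors(5L), function(p)
    marginal_loglik(D, clonal_tree(p, asg), E), 0))
  expect_equal(res$loglik, best, tolerance = 1e-9)
  expect_equal(res$tree$parent, pv)
})

test_that("latent clone testing recovers a simulated unobserved branch clone", {
  # three observed clones below one latent branch clone, two cells each
  E <- error_model(0.01, 0.01)
  cfg_s <- search_config()
  exact <- 0L
  for (s in 1:10) {
    cfg <- simulation_config(n_clones = 4, n_unobserved = 1, n_cells = 6,
                             n_sites = 100, alpha = 0.01, beta = 0.01,
                             p_missing = 0.1, seed = s)
    sim <- simulate_dataset(cfg)
    res1 <- initial_search(sim$genotypes, E, cfg_s)
    res2 <- add_unobserved_clones(res1, sim$genotypes, E, cfg_s)
    res3 <- cluster_cells(res2, sim$genotypes, E, cfg_s)
    if (shortest_path_distance(res3$tree, sim$truth$tree) == 0) {
      exact <- exact + 1L
      # the accepted expansion carried a decisive Bayes factor and the
      # final tree retains a cell-free branch clone
      expect_gt(res2$loglik - res1$loglik, log(cfg_s$epsilon))
      expect_true(any(!observed_clones(res3$tree)[-1L]))
    }
  }
  expect_gte(exact, 6L)
})

test_that("a chain has no branch points so latent testing is a no-op", {
  D <- genotype_matrix(matrix(c(1L, 1L, 0L, 1L), 2, 2,
                              dimnames = list(c("a", "b"), c("s1", "s2"))))
  E <- error_model(0.05, 0.05)
  res <- initial_search(D, E, search_config())
  expect_equal(length(branch_points(res$tree)), 0L)
  res2 <- add_unobserved_clones(res, D, E, search_config())
  expect_identical(res2$tree$parent, res$tree$parent)
})

test_that("an extreme Bayes factor threshold blocks latent clone acceptance", {
  cfg <- simulation_config(n_clones = 4, n_unobserved = 1, n_cells = 6,
                           n_sites = 100, alpha = 0.01, beta = 0.01,
                           p_missing = 0.1, seed = 3)
  sim <- simulate_dataset(cfg)
  E <- error_model(0.01, 0.01)
  res1 <- initial_search(sim$genotypes, E, search_config())
  res2 <- add_unobserved_clones(res1, sim$genotypes, E,
                                search_config(epsilon = 1e300))
  expect_identical(res2$tree$parent, res1$tree$parent)
})

test_that("cells with identical genotypes are clustered, disjoint ones are not", {
  E <- error_model(0.01, 0.01)
  # duplicate rows: should merge into one clone
  G <- rbind(a = c(1L, 1L, 0L, 0L, 0L, 0L),
             b = c(1L, 1L, 0L, 0L, 0L, 0L),
             c = c(1L, 1L, 1L, 1L, 1L, 1L))
  colnames(G) <- paste0("s", 1:6)
  D <- genotype_matrix(G)
  res <- infer(D, E, search_config())
  expect_equal(unname(res$tree$assignment["a"]),
               unname(res$tree$assignment["b"]))
  # disjoint mutation sets: every merge is expensive, no clustering
  G2 <- rbind(a = c(1L, 1L, 1L, 0L, 0L, 0L),
              b = c(0L, 0L, 0L, 1L, 1L, 1L))
  colnames(G2) <- paste0("s", 1:6)
  res2 <- infer(genotype_matrix(G2), error_model(0.01, 0.01),
                search_config())
  expect_false(res2$tree$assignment["a"] == res2$tree$assignment["b"])
})

test_that("clustering tolerance is honoured at the threshold limit", {
  set.seed(52)
  cfg <- simulation_config(n_clones = 3, n_cells = 8, n_sites = 60,
                           alpha = 0.05, beta = 0.05, p_missing = 0.1,
                           seed = 52)
  sim <- simulate_dataset(cfg)
  E <- error_model(0.05, 0.05)
  res1 <- initial_search(sim$genotypes, E, search_config())
  res2 <- add_unobserved_clones(res1, sim$genotypes, E, search_config())
  # with epsilon ~ 1 only likelihood-neutral or improving merges happen
  cfg_tiny <- search_config(epsilon = 1 + 1e-9)
  res3 <- cluster_cells(res2, sim$genotypes, E, cfg_tiny)
  expect_gte(res3$loglik, res2$loglik - 1e-6)
})

test_that("the full pipeline is deterministic and cache-consistent", {
  cfg <- simulation_config(n_clones = 4, n_cells = 8, n_sites = 50,
                           alpha = 0.1, beta = 0.1, p_missing = 0.2,
                           seed = 13)
  sim <- simulate_dataset(cfg)
  E <- error_model(0.1, 0.1)
  r1 <- infer(sim$genotypes, E, search_config())
  r2 <- infer(sim$genotypes, E, search_config())
  expect_identical(r1$tree$parent, r2$tree$parent)
  expect_identical(r1$loglik, r2$loglik)
  # reported loglik equals a from-scratch rescoring of the final tree
  expect_equal(r1$loglik, marginal_loglik(sim$genotypes, r1$tree, E),
               tolerance = 1e-9)
  # trace covers the three stages in order
  stages <- vapply(r1$trace, `[[`, "", "stage")
  expect_true(all(c("initial_search", "add_unobserved_clones",
                    "cluster_cells") %in% stages))
})

test_that("single-cell input yields the trivial chain", {
  D <- genotype_matrix(matrix(c(1L, 0L), 1, 2,
                              dimnames = list("only", c("s1", "s2"))))
  res <- infer(D, error_model(0.1, 0.1), search_config())
  expect_equal(res$tree$parent, c(NA, 1L))
  expect_equal(res$tree$N, 2L)
})

test_that("accepted likelihoods never decrease across pipeline stages beyond tolerance", {
  set.seed(61)
  for (i in 1:3) {
    cfg <- simulation_config(n_clones = 4, n_cells = 8, n_sites = 60,
                             alpha = 0.15, beta = 0.1, p_missing = 0.2,
                             seed = 700 + i)
    sim <- simulate_dataset(cfg)
    E <- error_model(0.15, 0.1)
    sc <- search_config()
    res1 <- initial_search(sim$genotypes, E, sc)
    res2 <- add_unobserved_clones(res1, sim$genotypes, E, sc)
    res3 <- cluster_cells(res2, sim$genotypes, E, sc)
    expect_gte(res2$loglik, res1$loglik - 1e-9)        # expansion only if better
    expect_gte(res3$loglik, res2$loglik - log(sc$epsilon) - 1e-6)
  }
})
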