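test_that("single-observation log-probabilities follow the error model", {
  E <- error_model(0.2, 0.1)
  expect_equal(single_obs_loglik(NA, 0, E), 0)
  expect_equal(single_obs_loglik(NA, 1, E), 0)
  expect_equal(single_obs_loglik(1, 0, E), log(0.2))
  expect_equal(single_obs_loglik(0, 1, E), log(0.1))
  expect_equal(single_obs_loglik(0, 0, E), log(0.8))
  expect_equal(single_obs_loglik(1, 1, E), log(0.9))
  expect_error(error_model(1, 0.1), "\\[0, 1\\)")
  expect_error(error_model(-0.1, 0.1), "\\[0, 1\\)")
  # exact-zero rates are legal and give -Inf for the impossible event
  expect_identical(single_obs_loglik(1, 0, error_model(0, 0.1)), -Inf)
})

test_that("per-site per-clone terms match the brute-force double loop", {
  set.seed(21)
  for (i in 1:30) {
    tr <- random_tree(sample(2:5, 1), paste0("c", 1:5))
    D <- random_genotypes(5, 8)
    E <- error_model(runif(1, 0.01, 0.4), runif(1, 0.01, 0.4))
    S <- site_clone_loglik(D, tr, E)
    expect_equal(unname(unclass(S)),
                 log(oracle_site_clone_probs(D, tr, E$alpha, E$beta)),
                 tolerance = 1e-12)
    expect_true(all(S <= 1e-12))
  }
})

test_that("an all-missing matrix scores zero everywhere", {
  D <- suppressWarnings(genotype_matrix(
    matrix(NA_integer_, 3, 4, dimnames = list(paste0("c", 1:3), NULL))))
  tr <- star_tree(paste0("c", 1:3))
  E <- error_model(0.1, 0.2)
  expect_true(all(site_clone_loglik(D, tr, E) == 0))
  # per site: logsumexp over N-1 flat terms cancels the prior exactly
  expect_equal(marginal_loglik(D, tr, E), 0)
})

test_that("tiny closed-form cases come out exactly", {
  # one cell, one site, chain 1->2
  tr <- star_tree("c1")
  E <- error_model(0.2, 0.1)
  D1 <- genotype_matrix(matrix(1L, 1, 1, dimnames = list("c1", "s1")))
  expect_equal(marginal_loglik(D1, tr, E), log(0.9))
  Dna <- suppressWarnings(genotype_matrix(
    matrix(NA_integer_, 1, 1, dimnames = list("c1", "s1"))))
  expect_equal(marginal_loglik(Dna, tr, E), 0)
  expect_equal(site_clone_loglik(D1, tr, E)[1, 1], log(0.9),
               ignore_attr = TRUE)
})

test_that("marginal likelihood equals the factorised brute force on random instances", {
  set.seed(99)
  for (i in 1:50) {
    tr <- random_tree(sample(2:6, 1), paste0("c", seq_len(sample(2:5, 1))))
    D <- random_genotypes(length(tr$cells), sample(3:10, 1))
    E <- error_model(runif(1, 0, 0.45), runif(1, 0, 0.45))
    expect_equal(marginal_loglik(D, tr, E),
                 oracle_marginal_loglik(D, tr, E$alpha, E$beta),
                 tolerance = 1e-10)
  }
})

test_that("known-placement likelihood matches and rejects root placements", {
  set.seed(3)
  tr <- random_tree(4, paste0("c", 1:4))
  D <- random_genotypes(4, 6)
  E <- error_model(0.15, 0.1)
  theta <- sample(2:tr$N, 6, replace = TRUE)
  S <- site_clone_loglik(D, tr, E)
  expect_equal(known_theta_loglik(D, tr, theta, E),
               sum(S[cbind(1:6, theta - 1L)]))
  expect_error(known_theta_loglik(D, tr, c(1L, theta[-1]), E), "non-root")
  # marginal is the log-mean-exp of the known-theta scores over all theta
  per_site <- exp(S)
  expect_equal(marginal_loglik(D, tr, E), sum(log(rowMeans(per_site))),
               tolerance = 1e-12)
})

test_that("noise-free data generated from a tree scores probability one", {
  set.seed(8)
  cfg <- simulation_config(n_clones = 4, n_cells = 6, n_sites = 12,
                           alpha = 0, beta = 0, p_missing = 0, seed = 8)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth$tree
  D <- genotype_matrix(unclass(sim$genotypes)[tr$cells, , drop = FALSE])
  expect_equal(known_theta_loglik(D, tr, sim$truth$theta,
                                  error_model(0, 0)), 0)
})

test_that("a single mismatch costs exactly the error-model log odds", {
  tr <- clonal_tree(c(NA, 1L, 2L), c(a = 2L, b = 3L))
  E <- error_model(0.2, 0.1)
  # truth: site originates in clone 2, both cells mutated
  D_match <- genotype_matrix(matrix(c(1L, 1L), 2, 1,
                                    dimnames = list(c("a", "b"), "s")))
  D_fn <- genotype_matrix(matrix(c(1L, 0L), 2, 1,
                                 dimnames = list(c("a", "b"), "s")))
  diff_fn <- known_theta_loglik(D_match, tr, 2L, E) -
    known_theta_loglik(D_fn, tr, 2L, E)
  expect_equal(diff_fn, log((1 - E$beta) / E$beta))
})

test_that("marginal likelihood is invariant under cell and site permutations", {
  set.seed(17)
  tr <- random_tree(4, paste0("c", 1:5))
  D <- random_genotypes(5, 7)
  E <- error_model(0.1, 0.3)
  base <- marginal_loglik(D, tr, E)
  for (r in 1:5) {
    pc <- sample(nrow(D)); ps <- sample(ncol(D))
    D2 <- genotype_matrix(unclass(D)[pc, ps])
    expect_equal(marginal_loglik(D2, tr, E), base, tolerance = 1e-12)
  }
})

test_that("noise-free truth is a global optimum over all enumerable trees", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 3
    cfg <- simulation_config(n_clones = n, n_cells = n, n_sites = 20,
                             alpha = 0, beta = 0, p_missing = 0,
                             seed = 500 + rep)
    sim <- simulate_dataset(cfg)
    truth <- sim$truth$tree
    D <- genotype_matrix(unclass(sim$genotypes)[truth$cells, , drop = FALSE])
    E <- error_model(1e-9, 1e-9)
    ll_truth <- marginal_loglik(D, truth, E)
    for (pv in enumerate_parent_vectors(n + 1L)) {
      cand <- clonal_tree(pv, truth$assignment)
      expect_lte(marginal_loglik(D, cand, E), ll_truth + 1e-9)
    }
  }
})

test_that("a latent clone extending a single-clone chain leaves the score unchanged", {
  # N-1 = 1: inserting a latent clone above the only clone duplicates its
  # pattern and exactly cancels against the prior normalisation
  D <- genotype_matrix(matrix(c(1L, 0L, 1L, NA), 2, 2,
                              dimnames = list(c("a", "b"), c("s1", "s2"))))
  tr <- clonal_tree(c(NA, 1L), c(a = 2L, b = 2L))
  ext <- clonal_tree(c(NA, 3L, 1L), c(a = 2L, b = 2L))  # 1 -> u(3) -> 2
  E <- error_model(0.2, 0.1)
  expect_equal(marginal_loglik(D, ext, E), marginal_loglik(D, tr, E),
               tolerance = 1e-12)
})

test_that("log-sum-exp scoring stays finite at scale", {
  set.seed(77)
  cfg <- simulation_config(n_clones = 12, n_cells = 30, n_sites = 10000,
                           alpha = 1e-6, beta = 1e-6, p_missing = 0.1,
                           seed = 77)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth$tree
  D <- genotype_matrix(unclass(sim$genotypes)[tr$cells, , drop = FALSE])
  ll <- marginal_loglik(D, tr, error_model(1e-6, 1e-6))
  expect_true(is.finite(ll))
})
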