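#' Error-rate parameter grid
#'
#' Grid of candidate (false positive, false negative) rate combinations
#' for maximum-likelihood estimation. The default grid is deliberately
#' coarse (the likelihood surface around the optimum is flat enough that
#' tree inference is robust to rate errors of this size): 0.01 and then
#' 0.05 steps up to 0.45, on both axes.
#'
#' @param alphas increasing false positive rates in `[0, 1)`
#' @param betas increasing false negative rates in `[0, 1)`
#' @return object of class `parameter_grid`
#' @export
parameter_grid <- function(alphas = c(0.01, seq(0.05, 0.45, by = 0.05)),
                           betas = c(0.01, seq(0.05, 0.45, by = 0.05))) {
  for (v in list(alphas, betas)) {
    if (!length(v) || anyDuplicated(v) || is.unsorted(v) ||
        any(v < 0) || any(v >= 1))
      stop("grid values must be distinct, increasing and in [0, 1)")
  }
  structure(list(alphas = alphas, betas = betas), class = "parameter_grid")
}

#' Grid maximum-likelihood estimation of error rates
#'
#' Runs the full three-step tree inference for every `(alpha, beta)` grid
#' combination and selects the pair whose final tree has the highest
#' marginal log-likelihood. Because trees at all grid cells are scored
#' against the same data over the same model space, raw log-likelihoods
#' are directly comparable.
#'
#' @param D a [genotype_matrix()]
#' @param grid a [parameter_grid()]
#' @param cfg a [search_config()]; the same configuration (and seed) is
#'   used for every grid cell so cells are comparable
#' @param verbose print progress per grid cell
#' @return list with elements `error_model` (the selected rates), `result`
#'   (the `inference_result` at the optimum) and `surface` (matrix of
#'   final log-likelihoods, alphas in rows, betas in columns)
#' @export
estimate_parameters <- function(D, grid = parameter_grid(),
                                cfg = search_config(), verbose = FALSE) {
  surface <- matrix(NA_real_, length(grid$alphas), length(grid$betas),
                    dimnames = list(alpha = grid$alphas, beta = grid$betas))
  best <- NULL; best_ll <- -Inf; best_E <- NULL
  for (j in seq_along(grid$betas)) {
    for (i in seq_along(grid$alphas)) {
      E <- error_model(grid$alphas[i], grid$betas[j])
      res <- initial_search(D, E, cfg)
      res <- add_unobserved_clones(res, D, E, cfg)
      res <- cluster_cells(res, D, E, cfg)
      surface[i, j] <- res$loglik
      if (res$loglik > best_ll) {
        best_ll <- res$loglik; best <- res; best_E <- E
      }
      if (verbose)
        message(sprintf("alpha=%.2f beta=%.2f loglik=%.2f",
                        E$alpha, E$beta, res$loglik))
    }
  }
  list(error_model = best_E, result = best, surface = surface)
}
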