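#' Genotyping error model
#'
#' Global per-entry error rates of the binarized genotype matrix: `alpha`
#' is the false positive rate (a truly unmutated site called mutated),
#' `beta` the false negative rate (a true mutation called unmutated,
#' dominated by allele dropout). The two are independent parameters; they
#' are conceptually distinct from the sequencing FDR and ADO rate, which
#' apply before site selection, consensus filtering and binarization.
#'
#' @param alpha false positive rate in `[0, 1)`
#' @param beta false negative rate in `[0, 1)`
#' @return object of class `error_model`
#' @export
error_model <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      alpha < 0 || alpha >= 1 || beta < 0 || beta >= 1)
    stop("alpha and beta must lie in [0, 1)")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("Error model: FPR alpha = %g, FNR beta = %g\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Log-probability of a single genotype observation
#'
#' The observation model: an observed call `d` given the predicted
#' genotype `delta` has probability `1 - alpha` (0|0), `alpha` (1|0),
#' `beta` (0|1), `1 - beta` (1|1); a missing call corresponds to the event
#' `{0, 1}` and has probability 1 regardless of `delta`.
#'
#' @param d observed call: 0, 1 or `NA`
#' @param delta predicted genotype: 0 or 1
#' @param E an [error_model()]
#' @return log-probability (`log(0) = -Inf` is legal when a rate is 0)
#' @export
single_obs_loglik <- function(d, delta, E) {
  if (is.na(d)) return(0)
  if (!d %in% c(0, 1) || !delta %in% c(0, 1)) stop("d and delta must be 0/1")
  if (delta == 0) {
    if (d == 0) log1p(-E$alpha) else log(E$alpha)
  } else {
    if (d == 0) log(E$beta) else log1p(-E$beta)
  }
}

# per-entry log-probability tables under both predicted genotypes:
# L0[k,l] = log P(d_kl | delta = 0), L1[k,l] = log P(d_kl | delta = 1);
# NA entries contribute 0 to both. W = L1 - L0 is the per-entry evidence
# for the mutation being present. Exact-zero rates are legal: log(0) is
# clamped at the smallest representable log-probability so that matrix
# products stay NaN-free; the affected terms still underflow to
# probability zero under exp().
obs_loglik_tables <- function(D, E) {
  d <- unclass(D)
  floor_log <- log(.Machine$double.xmin)
  safe_log <- function(x) max(log(x), floor_log)
  L0 <- matrix(0, nrow(d), ncol(d))
  L1 <- matrix(0, nrow(d), ncol(d))
  is0 <- !is.na(d) & d == 0L
  is1 <- !is.na(d) & d == 1L
  L0[is0] <- log1p(-E$alpha); L0[is1] <- safe_log(E$alpha)
  L1[is0] <- safe_log(E$beta); L1[is1] <- log1p(-E$beta)
  list(L0 = L0, L1 = L1, W = L1 - L0, base = colSums(L0))
}

# delta matrix over non-root clones x cells: Dlt[c-1, k] = 1 iff the clone
# of cell k lies in the subtree of clone c (mutation arising in c is
# inherited by all descendants, never lost)
delta_matrix <- function(tr, A = ancestry(tr)) {
  Dlt <- A[-1L, tr$assignment, drop = FALSE]
  storage.mode(Dlt) <- "double"
  Dlt
}

#' Per-site per-clone log-likelihood terms
#'
#' `S[l, c]` is the summed log-probability of column `l` of the data under
#' the hypothesis that site `l`'s mutation originated in clone `c`,
#' i.e. `sum_k log P(d_kl | delta_kl)` with `delta_kl = 1` iff cell `k`'s
#' clone descends from (or is) `c`. Columns cover the non-root clones
#' `2..N`.
#'
#' @param D a [genotype_matrix()]
#' @param tr a `clonal_tree` over the same cells
#' @param E an [error_model()]
#' @return an `m x (N - 1)` matrix; sites in rows, clones `2..N` in columns
#' @export
site_clone_loglik <- function(D, tr, E) {
  check_cells_match(D, tr)
  tab <- obs_loglik_tables(D, E)
  Dlt <- delta_matrix(tr)[, match(rownames(D), tr$cells), drop = FALSE]
  S <- t(Dlt %*% tab$W + rep(1, tr$N - 1L) %o% tab$base)
  dimnames(S) <- list(colnames(D), paste0("clone", seq_len(tr$N)[-1L]))
  S
}

check_cells_match <- function(D, tr) {
  if (!setequal(rownames(D), tr$cells) ||
      nrow(D) != length(tr$cells))
    stop("cells of the genotype matrix and the tree do not match")
  invisible(TRUE)
}

# numerically safe log(sum(exp())) over rows of a matrix
row_logsumexp <- function(S) {
  M <- apply(S, 1L, max)
  M[!is.finite(M)] <- 0        # all -Inf row: result -Inf, avoid NaN
  M + log(rowSums(exp(S - M)))
}

#' Marginal log-likelihood of a clonal lineage tree
#'
#' The mutation origin of each site is a nuisance parameter with a uniform
#' prior over the `N - 1` non-root clones (no mutations arise in the
#' normal); sites are independent, so the marginal likelihood factorises
#' per site:
#' `log P(D | T) = sum_l logsumexp_c S[l, c] - m * log(N - 1)`.
#' Computed entirely in log space.
#'
#' @inheritParams site_clone_loglik
#' @return scalar log-likelihood
#' @export
marginal_loglik <- function(D, tr, E) {
  if (tr$N < 2L) stop("a tree with cells has at least 2 clones")
  S <- site_clone_loglik(D, tr, E)
  sum(row_logsumexp(S)) - ncol(D) * log(tr$N - 1)
}

#' Log-likelihood for known mutation placements
#'
#' The complete-data likelihood given the origin clone of every site.
#'
#' @inheritParams site_clone_loglik
#' @param theta integer vector of length `m`: origin clone per site, each
#'   in `2..N` (the normal can never be an origin)
#' @return scalar log-likelihood
#' @export
known_theta_loglik <- function(D, tr, theta, E) {
  theta <- as.integer(theta)
  if (length(theta) != ncol(D))
    stop("theta must give one origin clone per site")
  if (any(theta < 2L | theta > tr$N))
    stop("theta values must be non-root clones in 2..N")
  S <- site_clone_loglik(D, tr, E)
  sum(S[cbind(seq_len(ncol(D)), theta - 1L)])
}
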