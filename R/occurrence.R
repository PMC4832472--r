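#' Posterior mutation placements
#'
#' For every variant site, the posterior probability that its mutation
#' originated in each non-root clone, under the uniform origin prior:
#' the per-site likelihood terms are renormalised across clones in log
#' space. Latent (unobserved) clones are legal origins and get columns
#' like any other non-root clone.
#'
#' @param D a [genotype_matrix()]
#' @param tr a `clonal_tree` over the same cells
#' @param E an [error_model()]
#' @return an `m x (N - 1)` matrix of class `occurrence_posterior`; rows
#'   are sites and sum to 1, columns are clones `2..N`
#' @export
posterior_theta <- function(D, tr, E) {
  S <- site_clone_loglik(D, tr, E)
  P <- exp(S - row_logsumexp(S))
  class(P) <- c("occurrence_posterior", class(P))
  P
}

#' Expected branch lengths
#'
#' The expected number of mutations separating each clone from its
#' parent: the column sums of the occurrence posterior. Summed over all
#' edges this equals `m` (every mutation occurs exactly once in
#' expectation).
#'
#' @param P an [posterior_theta()] matrix
#' @param tr the `clonal_tree` the posterior was computed on
#' @return numeric vector of length `N`; entry `c` is the length of the
#'   edge `(pa(c), c)`, entry 1 (the root) is `NA`
#' @export
branch_lengths <- function(P, tr) {
  if (ncol(P) != tr$N - 1L)
    stop("posterior has ", ncol(P), " clone columns but the tree has ",
         tr$N - 1L, " non-root clones")
  L <- c(NA_real_, colSums(P))
  names(L) <- paste0("clone", seq_len(tr$N))
  L
}

#' Maximum a posteriori mutation placement
#'
#' The highest-posterior origin clone per site; ties go to the lowest
#' clone index and are flagged in the `tie` attribute.
#'
#' @param P an [posterior_theta()] matrix
#' @return integer vector of clone indices (values in `2..N`), one per
#'   site, with attribute `tie`, a logical vector marking exact ties
#' @export
map_theta <- function(P) {
  idx <- apply(P, 1L, which.max)
  tie <- apply(P, 1L, function(x) sum(x >= max(x) - 1e-12) > 1L)
  out <- as.integer(idx) + 1L
  names(out) <- rownames(P)
  attr(out, "tie") <- tie
  out
}

#' Write the occurrence posterior as TSV
#' @param P an [posterior_theta()] matrix
#' @param path output file
#' @export
write_posterior <- function(P, path) {
  df <- data.frame(site = rownames(P), unclass(P), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
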