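#' Pairwise cell shortest-path distances within a tree
#'
#' Distances between all cells placed on a clonal tree, plus one extra
#' cell (index 0) anchored in the root so the root's position influences
#' the measure. Two cells in the same clone have distance 0; otherwise
#' their distance is the number of tree edges separating their clones,
#' direction ignored.
#'
#' @param tr a `clonal_tree`
#' @return a symmetric integer matrix over cells `0, <cells...>` with zero
#'   diagonal
#' @export
cell_pair_distances <- function(tr) {
  depth <- clone_depths(tr)
  A <- ancestry(tr)
  N <- tr$N
  # clone-to-clone edge distances via deepest common ancestor
  cd <- matrix(0L, N, N)
  for (c1 in seq_len(N)) for (c2 in seq_len(N)) {
    if (c2 <= c1) next
    anc_common <- which(A[, c1] & A[, c2])  # ancestors-or-self of both
    l <- anc_common[which.max(depth[anc_common])]
    cd[c1, c2] <- cd[c2, c1] <- depth[c1] + depth[c2] - 2L * depth[l]
  }
  placement <- c(1L, tr$assignment)   # extra cell 0 lives in the root
  D <- cd[placement, placement]
  ids <- c("0", tr$cells)
  dimnames(D) <- list(ids, ids)
  D
}

#' Pairwise cell shortest-path distance between two trees
#'
#' Sum of absolute differences of all unordered cell-pair distances
#' (including the root-anchored cell 0) between two trees on the same
#' cells. This is a metric on clonal trees. With `normalized = TRUE` the
#' sum is divided by the number of pairs actually summed,
#' `(n + 1) * n / 2` for `n` cells.
#'
#' @param tr1,tr2 `clonal_tree` objects over identical cell sets
#' @param normalized divide by the number of cell pairs
#' @return a non-negative number
#' @export
shortest_path_distance <- function(tr1, tr2, normalized = FALSE) {
  if (!setequal(tr1$cells, tr2$cells))
    stop("trees must be built on the same cells")
  D1 <- cell_pair_distances(tr1)
  D2 <- cell_pair_distances(tr2)
  D2 <- D2[rownames(D1), rownames(D1)]
  d <- sum(abs(D1 - D2)[upper.tri(D1)])
  if (normalized) {
    n <- length(tr1$cells)
    d <- d / ((n + 1) * n / 2)
  }
  d
}

#' V-measure of a clustering against a reference
#'
#' Entropy-based external cluster evaluation: the harmonic mean of
#' homogeneity (each predicted cluster contains only members of one true
#' class) and completeness (all members of a true class end up in one
#' predicted cluster). Both components are 1 by convention when the
#' corresponding entropy is zero. Invariant under relabelling of either
#' partition; 1 iff the partitions coincide.
#'
#' @param predicted named vector: cluster label per cell
#' @param truth named vector over the same cells: true class per cell
#' @return list-free scalar in `[0, 1]`, with attributes `homogeneity`
#'   and `completeness`
#' @export
v_measure <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("partitions must cover the same cells")
  if (!is.null(names(predicted)) && !is.null(names(truth))) {
    if (!setequal(names(predicted), names(truth)))
      stop("partitions must cover the same cells")
    truth <- truth[names(predicted)]
  }
  tab <- table(truth, predicted)
  n <- sum(tab)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  H_C <- ent(rowSums(tab) / n)
  H_K <- ent(colSums(tab) / n)
  # conditional entropies from the joint
  p_joint <- tab / n
  H_C_given_K <- -sum(p_joint[p_joint > 0] *
                        log((p_joint / rep(colSums(p_joint),
                                           each = nrow(p_joint)))[p_joint > 0]))
  H_K_given_C <- -sum(p_joint[p_joint > 0] *
                        log((p_joint / rowSums(p_joint))[p_joint > 0]))
  h <- if (H_C == 0) 1 else 1 - H_C_given_K / H_C
  c_ <- if (H_K == 0) 1 else 1 - H_K_given_C / H_K
  v <- if (h + c_ == 0) 0 else 2 * h * c_ / (h + c_)
  structure(v, homogeneity = h, completeness = c_)
}

#' Mutation order accuracy
#'
#' Agreement of the inferred mutation placements with the ground truth,
#' averaged over two components computed on mutation pairs whose true
#' origins lie in different clones: (i) the fraction of truly
#' ancestor-ordered pairs whose order is reproduced (origin of `a` a
#' strict ancestor of origin of `b`), and (ii) the fraction of truly
#' mutually exclusive pairs (origins on separate branches) reproduced as
#' mutually exclusive. Returns `NaN` (with attribute `undefined = TRUE`)
#' when the ground truth has no mutually exclusive mutation pair, i.e.
#' when the true tree is linear.
#'
#' @param tr1 inferred `clonal_tree`
#' @param theta1 integer vector: inferred origin clone per site in `tr1`
#' @param tr2 ground-truth `clonal_tree`
#' @param theta2 integer vector: true origin clone per site in `tr2`
#' @return scalar in `[0, 1]` or `NaN`; attributes `order_component`,
#'   `exclusivity_component`
#' @export
mutation_order_accuracy <- function(tr1, theta1, tr2, theta2) {
  m <- length(theta2)
  if (length(theta1) != m)
    stop("both trees must place the same mutation sites")
  if (anyNA(theta1) || anyNA(theta2)) stop("missing mutation placements")
  A1 <- ancestry(tr1); A2 <- ancestry(tr2)
  # strict ancestry between origins: up[a, b] = origin(a) strict anc of origin(b)
  up1 <- A1[theta1, theta1, drop = FALSE] &
    outer(theta1, theta1, `!=`)
  up2 <- A2[theta2, theta2, drop = FALSE] &
    outer(theta2, theta2, `!=`)
  diff2 <- outer(theta2, theta2, `!=`)
  excl2 <- diff2 & !up2 & !t(up2)
  diff1 <- outer(theta1, theta1, `!=`)
  excl1 <- diff1 & !up1 & !t(up1)
  off <- upper.tri(diff2) | lower.tri(diff2)
  ord_pairs <- up2 & off          # ordered pairs, true a-above-b
  exc_pairs <- excl2 & upper.tri(excl2)   # unordered exclusive pairs
  comp_order <- if (any(ord_pairs)) mean(up1[ord_pairs]) else NA_real_
  comp_excl <- if (any(exc_pairs)) mean(excl1[exc_pairs]) else NA_real_
  if (is.na(comp_excl)) {
    out <- NaN
    attr(out, "undefined") <- TRUE
  } else {
    out <- mean(c(comp_order, comp_excl), na.rm = TRUE)
    attr(out, "undefined") <- FALSE
  }
  attr(out, "order_component") <- comp_order
  attr(out, "exclusivity_component") <- comp_excl
  out
}
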