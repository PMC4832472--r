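#' Clonal lineage trees
#'
#' A clonal lineage tree is a rooted directed tree over clones. Clone 1 is
#' the unmutated normal and never holds cells; every other clone holds zero
#' or more sequenced cells. A clone with no cells (other than the root) is
#' an unobserved clone. The tree is stored as a parent vector plus a
#' cell-to-clone assignment.
#'
#' @param parent integer vector of length `N`; `parent[1]` must be `NA`
#'   (the root), `parent[c]` for `c >= 2` is the parent clone of `c`.
#' @param assignment named integer vector mapping each cell to its clone
#'   (values in `2..N`); names are the cell identifiers.
#' @return An object of class `clonal_tree` with elements `parent`,
#'   `assignment`, `cells` and `N`.
#' @examples
#' tr <- clonal_tree(c(NA, 1L, 2L), c(a = 2L, b = 3L))
#' n_clones(tr)
#' @export
clonal_tree <- function(parent, assignment) {
  parent <- as.integer(parent)
  N <- length(parent)
  if (N < 1L || !is.na(parent[1L]))
    stop("parent[1] must be NA: clone 1 is the root")
  if (N >= 2L) {
    p <- parent[-1L]
    if (anyNA(p) || any(p < 1L) || any(p > N))
      stop("parent entries for clones 2..N must be clone indices")
  }
  cells <- names(assignment)
  assignment <- as.integer(assignment)
  names(assignment) <- cells
  if (length(assignment) > 0L) {
    if (is.null(cells) || anyDuplicated(cells))
      stop("cells must carry unique identifiers")
    if (anyNA(assignment) || any(assignment < 2L) || any(assignment > N))
      stop("cells must be assigned to non-root clones in 2..N")
    if (N < 2L) stop("N >= 2 required when cells are present")
  }
  tr <- structure(
    list(parent = parent, assignment = assignment,
         cells = if (is.null(cells)) character(0) else cells, N = N),
    class = "clonal_tree")
  validate_tree_structure(tr)
  tr
}

validate_tree_structure <- function(tr) {
  # every non-root clone must reach the root by following parents (acyclic,
  # connected); depth-bounded walk catches cycles
  N <- tr$N
  for (c in seq_len(N)[-1L]) {
    cur <- c
    steps <- 0L
    while (cur != 1L) {
      cur <- tr$parent[cur]
      steps <- steps + 1L
      if (steps > N) stop("parent map contains a cycle at clone ", c)
    }
  }
  invisible(tr)
}

#' @export
print.clonal_tree <- function(x, ...) {
  obs <- clone_sizes(x)
  cat("Clonal lineage tree: ", x$N, " clones (",
      sum(obs[-1L] > 0L), " observed), ",
      length(x$cells), " cells\n", sep = "")
  cat("  parent:", paste(ifelse(is.na(x$parent), ".", x$parent),
                         collapse = " "), "\n")
  if (length(x$cells) > 0L && length(x$cells) <= 25L)
    cat("  cells: ",
        paste0(x$cells, "->", x$assignment, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of clones in a tree
#' @param tr a `clonal_tree`
#' @return integer count of clones including the root
#' @export
n_clones <- function(tr) tr$N

#' Cells per clone
#' @param tr a `clonal_tree`
#' @return integer vector of length `N` counting cells in each clone
#' @export
clone_sizes <- function(tr) {
  tabulate(tr$assignment, nbins = tr$N)
}

#' Observed-clone flags
#'
#' The root is always unobserved (it is the normal); any other clone is
#' observed iff it contains at least one cell.
#' @param tr a `clonal_tree`
#' @return logical vector of length `N`
#' @export
observed_clones <- function(tr) {
  obs <- clone_sizes(tr) > 0L
  obs[1L] <- FALSE
  obs
}

children_list <- function(parent) {
  N <- length(parent)
  kids <- vector("list", N)
  for (c in seq_len(N)[-1L]) {
    p <- parent[c]
    kids[[p]] <- c(kids[[p]], c)
  }
  kids
}

#' Star tree over a set of cells
#'
#' The default start state of the search: every cell is its own clone and
#' all clones attach directly to the normal root.
#'
#' @param cells character vector of cell identifiers (length `n >= 1`)
#' @return a `clonal_tree` with `N = n + 1`
#' @export
star_tree <- function(cells) {
  cells <- as.character(cells)
  n <- length(cells)
  if (n < 1L) stop("at least one cell is required")
  if (anyDuplicated(cells)) stop("cell identifiers must be unique")
  parent <- c(NA_integer_, rep(1L, n))
  assignment <- seq_len(n) + 1L
  names(assignment) <- cells
  clonal_tree(parent, assignment)
}

#' Ancestry matrix of a tree
#'
#' `A[c, c']` is `TRUE` iff `c' == c` or `c'` is a descendant of `c`; row
#' `c` therefore marks the subtree rooted at `c`. Under the infinite sites
#' assumption a mutation arising in clone `c` is present exactly in the
#' clones of row `c`.
#'
#' @param tr a `clonal_tree`
#' @return an `N x N` logical matrix
#' @export
ancestry <- function(tr) {
  N <- tr$N
  parent <- tr$parent
  A <- diag(TRUE, N)
  # accumulate subtree indicators bottom-up in reverse topological order
  ord <- topo_order(parent)
  for (c in rev(ord)) {
    p <- parent[c]
    if (!is.na(p)) A[p, ] <- A[p, ] | A[c, ]
  }
  A
}

topo_order <- function(parent) {
  # root first, each node after its parent
  N <- length(parent)
  kids <- children_list(parent)
  ord <- integer(N)
  ord[1L] <- 1L
  i <- 1L; filled <- 1L
  while (i <= filled) {
    for (k in kids[[ord[i]]]) {
      filled <- filled + 1L
      ord[filled] <- k
    }
    i <- i + 1L
  }
  ord
}

clone_depths <- function(tr) {
  N <- tr$N
  d <- integer(N)
  for (c in topo_order(tr$parent)[-1L]) d[c] <- d[tr$parent[c]] + 1L
  d
}

ancestors_of <- function(parent, c, include_self = TRUE) {
  # path from c up to (and excluding) the root
  path <- integer(0)
  cur <- if (include_self) c else parent[c]
  while (!is.na(cur) && cur != 1L) {
    path <- c(path, cur)
    cur <- parent[cur]
  }
  path
}

#' Neighborhood of a tree under prune-regraft and node relocation
#'
#' The union of two symmetric move classes: (a) detaching one non-root
#' clone together with its subtree and reattaching it to any clone
#' outside that subtree; (b) splicing out one non-root clone with at most
#' one child (its child, if any, is re-parented to its parent) and
#' re-inserting it elsewhere, either as a new leaf or subdividing an
#' existing edge. Class (b) lets single clones slide along and between
#' branches, which pure subtree moves cannot do in one step. The original
#' tree is excluded and no duplicates are produced; the union is
#' symmetric (`T2` is a neighbor of `T1` iff `T1` is one of `T2`) and
#' connects the whole labelled tree space.
#'
#' @param tr a `clonal_tree`
#' @return list of `clonal_tree` objects
#' @export
tree_neighbors <- function(tr) {
  moves <- neighbor_moves(tr)
  lapply(seq_len(nrow(moves)), function(i)
    apply_move(tr, moves[i, 1L], moves[i, 2L], moves[i, 3L]))
}

# Moves as a matrix with columns (v, target, type), deterministic order.
# type 1: subtree of v re-attached as child of target.
# type 2: v (<= 1 child) spliced out and re-attached as a leaf child of
#         target (only for v with exactly one child; for leaves this
#         coincides with type 1).
# type 3: v (<= 1 child) spliced out and inserted into the edge above
#         target (v becomes target's parent).
neighbor_moves <- function(tr, nodes = NULL) {
  N <- tr$N
  A <- ancestry(tr)
  parent <- tr$parent
  kids <- children_list(parent)
  nkids <- vapply(kids, length, 1L)
  if (is.null(nodes)) nodes <- seq_len(N)[-1L]
  out <- vector("list", 3L * length(nodes))
  k <- 0L
  for (v in nodes) {
    p <- parent[v]
    # type 1: subtree prune-and-regraft
    targets <- which(!A[v, ])
    targets <- targets[targets != p]
    if (length(targets)) {
      k <- k + 1L; out[[k]] <- cbind(v, targets, 1L)
    }
    if (nkids[v] > 1L) next
    c_v <- if (nkids[v] == 1L) kids[[v]] else 0L
    # parent map of the spliced tree (v removed, child hoisted)
    hp <- parent
    if (c_v > 0L) hp[c_v] <- p
    if (c_v > 0L) {
      # type 2: leaf re-attachment of a spliced one-child clone; q = p
      # duplicates the plain subtree move of the child, leaves duplicate
      # type 1 entirely, and q = a childless c duplicates the type-3
      # insertion of c into the edge above v
      t2 <- setdiff(seq_len(N),
                    c(v, p, if (nkids[c_v] == 0L) c_v else integer(0)))
      if (length(t2)) { k <- k + 1L; out[[k]] <- cbind(v, t2, 2L) }
    }
    # type 3: insert v into the edge above y (y != v); skip y == c_v with
    # unchanged parent (rebuilds the original tree) and y whose hoisted
    # parent is v's own parent when v is a leaf attached there already
    ys <- setdiff(seq_len(N)[-1L], v)
    keep <- logical(length(ys))
    for (i in seq_along(ys)) {
      y <- ys[i]
      x <- hp[y]
      if (y == c_v && x == p) next        # original tree
      if (c_v == 0L && x == p) next       # duplicates type 1 of y under v
      keep[i] <- TRUE
    }
    if (any(keep)) { k <- k + 1L; out[[k]] <- cbind(v, ys[keep], 3L) }
  }
  res <- do.call(rbind, c(out[seq_len(k)], list(matrix(integer(0), ncol = 3L))))
  colnames(res) <- c("v", "target", "type")
  res
}

# fast construction for internally generated, known-valid parent vectors
new_tree <- function(parent, assignment, cells = names(assignment)) {
  structure(list(parent = parent, assignment = assignment,
                 cells = cells, N = length(parent)),
            class = "clonal_tree")
}

move_parent <- function(parent, v, q, type = 1L) {
  if (type == 1L) {
    parent[v] <- q
  } else {
    kid <- which(!is.na(parent) & parent == v)
    if (length(kid)) parent[kid] <- parent[v]
    if (type == 2L) {
      parent[v] <- q
    } else {
      parent[v] <- parent[q]
      parent[q] <- v
    }
  }
  parent
}

apply_move <- function(tr, v, q, type = 1L) {
  # moves preserve validity by construction: type 1 only targets nodes
  # outside the moved subtree, types 2/3 re-parent the hoisted child first
  new_tree(move_parent(tr$parent, v, q, type), tr$assignment, tr$cells)
}

#' Insert an unobserved clone at a branch point
#'
#' Creates a new cell-free clone `u` as a child of branch point `b` and
#' re-parents all current children of `b` to `u`. Subsequent local search
#' (moves of `u`) optimises the latent clone's position; subsets of
#' children need not be enumerated up front.
#'
#' @param tr a `clonal_tree`
#' @param b a clone with at least two children
#' @return a `clonal_tree` with `N + 1` clones; the new clone has index
#'   `N + 1` and carries no cells
#' @export
insert_unobserved <- function(tr, b) {
  kids <- children_list(tr$parent)[[b]]
  if (length(kids) < 2L)
    stop("clone ", b, " is not a branch point (fewer than 2 children)")
  u <- tr$N + 1L
  parent <- c(tr$parent, b)
  parent[kids] <- u
  clonal_tree(parent, tr$assignment)
}

#' Branch points of a tree
#' @param tr a `clonal_tree`
#' @return integer vector of clones with >= 2 children
#' @export
branch_points <- function(tr) {
  kids <- children_list(tr$parent)
  which(vapply(kids, length, 1L) >= 2L)
}

#' Merge a clone into its parent
#'
#' The cells of `child` are reassigned to `parent`, the children of
#' `child` are re-parented to `parent`, and `child` is removed. Merging
#' into the root is forbidden: the normal never holds cells. Surviving
#' clones are relabelled densely `1..N-1` with the root fixed at 1; the
#' old-to-new map is attached as attribute `label_map`.
#'
#' @param tr a `clonal_tree`
#' @param child clone to remove
#' @param parent its parent (checked)
#' @return a `clonal_tree` with `N - 1` clones
#' @export
merge_edge <- function(tr, child, parent) {
  if (is.na(tr$parent[child]) || tr$parent[child] != parent)
    stop("clones ", child, " and ", parent, " are not a child-parent pair")
  if (parent == 1L)
    stop("cells may not be merged into the root (normal) clone")
  pv <- tr$parent
  pv[pv == child] <- parent         # re-parent child's children
  asg <- tr$assignment
  asg[asg == child] <- parent       # move cells
  keep <- setdiff(seq_len(tr$N), child)
  map <- integer(tr$N)
  map[keep] <- seq_along(keep)
  new_parent <- map[pv[keep]]
  new_parent[1L] <- NA_integer_
  new_asg <- map[asg]
  names(new_asg) <- names(asg)
  out <- clonal_tree(new_parent, new_asg)
  attr(out, "label_map") <- map
  out
}

#' Splice out linear unobserved clones
#'
#' Unobserved non-root clones with fewer than two children cannot be
#' identified from genotype data (they create no extra mutation pattern);
#' this removes every such clone, re-parenting its children to its parent.
#' Idempotent. Surviving clones are relabelled densely; the old-to-new map
#' is attached as attribute `label_map`.
#'
#' @param tr a `clonal_tree`
#' @return a `clonal_tree`
#' @export
prune_linear_unobserved <- function(tr) {
  repeat {
    obs <- observed_clones(tr)
    kids <- children_list(tr$parent)
    deg <- vapply(kids, length, 1L)
    drop <- which(!obs & deg < 2L & seq_len(tr$N) != 1L)
    if (!length(drop)) break
    v <- drop[1L]
    pv <- tr$parent
    pv[pv == v] <- pv[v]
    keep <- setdiff(seq_len(tr$N), v)
    map <- integer(tr$N)
    map[keep] <- seq_along(keep)
    new_parent <- map[pv[keep]]
    new_parent[1L] <- NA_integer_
    new_asg <- map[tr$assignment]
    names(new_asg) <- names(tr$assignment)
    prev_map <- attr(tr, "label_map")
    tr <- clonal_tree(new_parent, new_asg)
    attr(tr, "label_map") <- if (is.null(prev_map)) map else
      ifelse(prev_map == 0L, 0L, map[pmax(prev_map, 1L)])
  }
  tr
}

# canonical key for visited-set hashing during search
tree_key <- function(tr) paste(tr$parent[-1L], collapse = ",")

#' Write a tree as an edge list
#'
#' Three-column TSV: `parent`, `child`, `cells` (comma-separated cell ids
#' of the child clone; empty for unobserved clones). An optional fourth
#' column carries branch lengths when supplied.
#'
#' @param tr a `clonal_tree`
#' @param path output file
#' @param lengths optional numeric vector of length `N` with expected
#'   mutation counts per clone (entry 1, the root, is ignored)
#' @export
write_tree <- function(tr, path, lengths = NULL) {
  cl <- seq_len(tr$N)[-1L]
  cellcol <- vapply(cl, function(c)
    paste(tr$cells[tr$assignment == c], collapse = ","), "")
  df <- data.frame(parent = tr$parent[cl], child = cl, cells = cellcol,
                   stringsAsFactors = FALSE)
  if (!is.null(lengths)) df$length <- lengths[cl]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tree from an edge list written by [write_tree()]
#' @param path input file
#' @return a `clonal_tree`
#' @export
read_tree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("parent", "child", "cells") %in% names(df)))
    stop("edge list must have columns parent, child, cells")
  pa <- as.integer(df$parent); ch <- as.integer(df$child)
  N <- max(ch, pa, 1L)
  parent <- rep(NA_integer_, N)
  parent[ch] <- pa
  asg <- integer(0); nm <- character(0)
  for (i in seq_along(ch)) {
    if (nzchar(df$cells[i])) {
      ids <- strsplit(df$cells[i], ",", fixed = TRUE)[[1]]
      asg <- c(asg, rep(ch[i], length(ids)))
      nm <- c(nm, ids)
    }
  }
  names(asg) <- nm
  clonal_tree(parent, asg)
}

#' Newick export of a clonal tree
#'
#' Clone labels are `clone<i>` with member cells appended in brackets;
#' branch lengths (expected mutation counts, 2 decimals) are attached when
#' supplied.
#'
#' @param tr a `clonal_tree`
#' @param lengths optional numeric vector of per-clone expected mutation
#'   counts
#' @return a single Newick string, semicolon-terminated
#' @export
tree_newick <- function(tr, lengths = NULL) {
  kids <- children_list(tr$parent)
  lab <- function(c) {
    cells <- tr$cells[tr$assignment == c]
    paste0("clone", c,
           if (length(cells)) paste0("[", paste(cells, collapse = "-"), "]") else "")
  }
  rec <- function(c) {
    ks <- kids[[c]]
    core <- if (length(ks))
      paste0("(", paste(vapply(ks, rec, ""), collapse = ","), ")", lab(c))
    else lab(c)
    if (!is.null(lengths) && c != 1L)
      core <- paste0(core, ":", formatC(lengths[c], digits = 2L, format = "f"))
    core
  }
  paste0(rec(1L), ";")
}

#' DOT (graphviz) export of a clonal tree
#' @param tr a `clonal_tree`
#' @param lengths optional per-clone expected mutation counts used as edge
#'   labels
#' @return character vector of DOT lines
#' @export
tree_dot <- function(tr, lengths = NULL) {
  lines <- c("digraph clonal_tree {", "  node [shape=circle];")
  for (c in seq_len(tr$N)) {
    cells <- tr$cells[tr$assignment == c]
    label <- if (c == 1L) "normal" else paste0("clone", c)
    if (length(cells)) label <- paste0(label, "\\n", paste(cells, collapse = " "))
    style <- if (c != 1L && !length(cells)) ", style=dashed" else ""
    lines <- c(lines, sprintf("  n%d [label=\"%s\"%s];", c, label, style))
  }
  for (c in seq_len(tr$N)[-1L]) {
    el <- if (is.null(lengths)) "" else
      sprintf(" [label=\"%.2f\"]", lengths[c])
    lines <- c(lines, sprintf("  n%d -> n%d%s;", tr$parent[c], c, el))
  }
  c(lines, "}")
}
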