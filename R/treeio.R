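#' Validate a rooted, branch-length-bearing phylogeny
#'
#' Checks the invariants every tree used by the package must satisfy: at least
#' two tips, unique non-empty tip labels, a single root, and finite,
#' non-negative branch lengths on every edge. Zero-length branches are allowed
#' (posterior draws can contain them); negative or missing lengths are not.
#'
#' @param tree an [ape::phylo] object.
#' @return `tree`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  labs <- trimws(gsub("^'|'$|^\"|\"$", "", tree$tip.label))
  if (any(!nzchar(labs))) stop("empty tip label")
  if (length(labs) < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(labs)) {
    stop("duplicate tip label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; branch lengths are mandatory")
  }
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    stop("missing or non-finite branch length(s); no silent zero-fill")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length(s)")
  tree$tip.label <- labs
  invisible(tree)
}

#' Coerce to a tree sample
#'
#' A `tree_sample` is an ordered list of rooted `phylo` trees sharing one tip
#' set, e.g. draws from a posterior distribution of dated phylogenies.
#'
#' @param x a `phylo`, `multiPhylo`, or list of `phylo` objects.
#' @return an object of class `tree_sample` (a list of validated `phylo`).
#' @export
as_tree_sample <- function(x) {
  if (inherits(x, "tree_sample")) return(x)
  if (inherits(x, "phylo")) x <- list(x)
  if (inherits(x, "multiPhylo")) x <- unclass(x)
  if (!is.list(x) || length(x) < 1L) stop("need at least one tree")
  x <- lapply(x, function(tr) {
    validate_phylogeny(tr)
    tr$tip.label <- trimws(gsub("^'|'$|^\"|\"$", "", tr$tip.label))
    tr
  })
  ref <- sort(x[[1L]]$tip.label)
  for (i in seq_along(x)) {
    tips <- sort(x[[i]]$tip.label)
    if (!identical(tips, ref)) {
      extra <- setdiff(tips, ref)
      miss <- setdiff(ref, tips)
      stop("tree ", i, " has a different tip set; only in tree ", i, ": {",
           paste(extra, collapse = ", "), "}; missing from tree ", i, ": {",
           paste(miss, collapse = ", "), "}")
    }
  }
  structure(x, class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("tree_sample:", length(x), "tree(s),",
      length(x[[1L]]$tip.label), "shared tips\n")
  invisible(x)
}

#' @export
`[.tree_sample` <- function(x, i) {
  structure(unclass(x)[i], class = "tree_sample")
}

#' Read one or more Newick trees
#'
#' Reads a Newick file (a single `;`-terminated tree or a multi-tree file, one
#' tree per line) into a [as_tree_sample()] object, in file order. Branch
#' lengths are mandatory on every edge; duplicate tip labels within a tree and
#' inconsistent tip sets across trees are rejected. Quoted labels and
#' surrounding whitespace are tolerated (quotes/whitespace trimmed).
#'
#' @param file path to a Newick file.
#' @param text Newick string(s) given directly instead of a file.
#' @return a `tree_sample`.
#' @export
read_newick <- function(file = NULL, text = NULL) {
  trees <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(trees)) stop("malformed Newick: no tree could be parsed")
  as_tree_sample(trees)
}

#' Write a tree sample to a Newick file (one tree per line)
#'
#' @param trees a `tree_sample`, `phylo`, or `multiPhylo`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_newick <- function(trees, file) {
  trees <- as_tree_sample(trees)
  ape::write.tree(structure(unclass(trees), class = "multiPhylo"), file = file)
  invisible(file)
}

#' Prune a phylogeny to a taxon set
#'
#' Drops all tips outside `taxa`, merging the resulting unbranched internal
#' nodes with branch lengths summed, so that all pairwise patristic distances
#' among retained tips are unchanged.
#'
#' @param tree a `phylo`.
#' @param taxa character vector of tip labels to keep (at least 2).
#' @return the pruned `phylo`.
#' @export
prune_to <- function(tree, taxa) {
  validate_phylogeny(tree)
  taxa <- unique(as.character(taxa))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) {
    stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(taxa) < 2L) stop("need at least 2 taxa to keep")
  ape::keep.tip(tree, taxa)
}

#' Pairwise patristic distance matrix
#'
#' Sum of branch lengths on the path between each pair of tips, in the tree's
#' branch-length units (Ma for dated trees). Rows/columns follow
#' `tree$tip.label` order.
#'
#' @param tree a `phylo`.
#' @return a symmetric numeric matrix with zero diagonal and tip labels as
#'   dimnames.
#' @export
cophenetic_dist <- function(tree) {
  validate_phylogeny(tree)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

# Edge index leading into each node (0 for the root), and per-tip root-path
# edge sets, as a tips x edges logical incidence matrix. The incidence matrix
# is the workhorse behind PD and PhyloSor.
tip_edge_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent_edge <- integer(nnode)
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  parent_node <- integer(nnode)
  parent_node[tree$edge[, 2L]] <- tree$edge[, 1L]
  inc <- matrix(FALSE, ntip, nrow(tree$edge),
                dimnames = list(tree$tip.label, NULL))
  for (tip in seq_len(ntip)) {
    node <- tip
    while (parent_edge[node] != 0L) {
      inc[tip, parent_edge[node]] <- TRUE
      node <- parent_node[node]
    }
  }
  inc
}

#' Total branch length of the minimal subtree spanning a taxon set
#'
#' With `include_root = FALSE` (the convention used for Faith's PD here),
#' returns the summed branch lengths of the minimal spanning subtree of `taxa`
#' rooted at their most recent common ancestor; no edge above the MRCA is
#' counted. With `include_root = TRUE` the path from that MRCA up to the tree
#' root is counted as well.
#'
#' A single taxon with `include_root = FALSE` has no defined subtree length:
#' the result is `NA` (never silently 0), and propagates as missing.
#'
#' @param tree a `phylo`.
#' @param taxa character vector of tip labels (non-empty).
#' @param include_root count the MRCA-to-root path? Default `FALSE`.
#' @return branch length in tree units, or `NA_real_` when undefined.
#' @export
subtree_length <- function(tree, taxa, include_root = FALSE) {
  validate_phylogeny(tree)
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("empty taxon set")
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) {
    stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(taxa) == 1L && !include_root) return(NA_real_)
  inc <- tip_edge_incidence(tree)[taxa, , drop = FALSE]
  len <- tree$edge.length
  on_union <- colSums(inc) > 0L
  if (include_root) return(sum(len[on_union]))
  on_all <- colSums(inc) == length(taxa)  # edges above the MRCA of `taxa`
  sum(len[on_union]) - sum(len[on_all])
}
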