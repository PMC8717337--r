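#' Sorensen dissimilarity between two communities
#'
#' With `a` shared taxa, `b` unique to A and `c` unique to B:
#' `(b + c) / (2a + b + c)` — the proportion of taxa not shared, the complement
#' of the classical Sorensen similarity on presence-absence data.
#'
#' @param a,b binary occurrence vectors over the same taxa.
#' @return dissimilarity in `[0, 1]`; `NA` if both communities are empty.
#' @export
sorensen <- function(a, b) {
  if (length(a) != length(b)) stop("occurrence vectors differ in length")
  shared <- sum(a == 1 & b == 1)
  only_a <- sum(a == 1 & b == 0)
  only_b <- sum(a == 0 & b == 1)
  tot <- 2 * shared + only_a + only_b
  if (tot == 0) return(NA_real_)
  (only_a + only_b) / tot
}

#' Pairwise Sorensen dissimilarity matrix
#'
#' @param community binary site x species matrix.
#' @return a `beta_matrix`: symmetric matrix in `[0,1]` with attributes
#'   `metric = "sorensen"`, `aggregation = "single"`.
#' @export
sorensen_matrix <- function(community) {
  validate_community(community)
  M <- community * 1
  shared <- M %*% t(M)
  S <- rowSums(M)
  tot <- outer(S, S, "+")            # 2a + b + c
  d <- (tot - 2 * shared) / tot
  d[tot == 0] <- NA_real_
  diag(d)[S > 0] <- 0
  structure(d, metric = "sorensen", aggregation = "single",
            class = c("beta_matrix", "matrix"))
}

# Site x edge structures for one tree: weighted union/"all-paths" crossprods.
# u[s,e]: edge e lies on the root path of >= 1 present tip of site s.
# a[s,e]: edge e lies on the root path of ALL present tips of site s (these are
# exactly the edges above the MRCA of the site's taxa).
.phylosor_engine <- function(community, tree) {
  comm <- community[, tree$tip.label, drop = FALSE] * 1
  inc <- tip_edge_incidence(tree) * 1
  len <- tree$edge.length
  cnt <- comm %*% inc
  S <- rowSums(comm)
  U <- (cnt > 0) * 1
  A <- (cnt == S & S > 0) * 1
  shared_root <- U %*% (len * t(U))   # sum of edge lengths on both unions
  above_pair <- A %*% (len * t(A))    # edge lengths above the pooled-pair MRCA
  bl_root <- diag(shared_root)        # per-site branch length to tree root
  list(shared_root = shared_root, above_pair = above_pair,
       bl_root = bl_root, S = S)
}

#' PhyloSor phylogenetic dissimilarity matrix for one tree
#'
#' For each site pair, branch lengths are measured on the minimal subtrees
#' connecting each site's taxa to the most recent common ancestor of the
#' pooled pair (so the shared-branch decomposition
#' `BL_shared = BL_A + BL_B - BL_union` is exact and non-negative).
#' Dissimilarity = `1 - BL_shared / (0.5 * (BL_A + BL_B))`, the proportion of
#' branch length not shared. Single-taxon sites are permitted under this
#' rooted convention; a pair of identical single-taxon sites has dissimilarity
#' 0 by continuity. Sites with no taxa give `NA`.
#'
#' @param community binary site x species matrix; taxa must be tree tips.
#' @param tree a `phylo`.
#' @return a `beta_matrix` with attribute `metric = "phylosor"`.
#' @export
phylosor_matrix <- function(community, tree) {
  validate_community(community)
  validate_phylogeny(tree)
  unknown <- setdiff(colnames(community), tree$tip.label)
  if (length(unknown)) stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  eng <- .phylosor_engine(community, tree)
  shared <- eng$shared_root - eng$above_pair
  bl_a <- outer(eng$bl_root, rep(1, length(eng$bl_root))) - eng$above_pair
  bl_b <- t(bl_a)
  denom <- 0.5 * (bl_a + bl_b)
  d <- 1 - shared / denom
  d[denom == 0] <- 0                      # identical single-taxon pairs
  empty <- eng$S == 0
  d[empty, ] <- NA_real_
  d[, empty] <- NA_real_
  diag(d)[!empty] <- 0
  dimnames(d) <- list(rownames(community), rownames(community))
  structure(d, metric = "phylosor", aggregation = "single",
            class = c("beta_matrix", "matrix"))
}

#' PhyloSor dissimilarity between two taxon sets
#'
#' @param tree a `phylo`.
#' @param taxa_a,taxa_b character vectors of present taxa (each non-empty).
#' @return dissimilarity in `[0, 1]`.
#' @export
phylosor <- function(tree, taxa_a, taxa_b) {
  validate_phylogeny(tree)
  if (length(taxa_a) == 0L || length(taxa_b) == 0L) {
    stop("each site needs at least one taxon")
  }
  tips <- tree$tip.label
  m <- matrix(0, 2L, length(tips), dimnames = list(c("A", "B"), tips))
  m["A", as.character(taxa_a)] <- 1
  m["B", as.character(taxa_b)] <- 1
  unname(phylosor_matrix(m, tree)[1L, 2L])
}

#' Beta dissimilarities with cross-tree aggregation
#'
#' Sorensen is tree-independent and computed once; PhyloSor is computed on
#' every tree of the sample and summarized elementwise across trees (default:
#' the median, mirroring the cross-tree aggregation used for the alpha SES
#' metrics).
#'
#' @param community binary site x species matrix.
#' @param trees a `tree_sample` (ignored for `metric = "sorensen"`).
#' @param metric `"phylosor"` (default) or `"sorensen"`.
#' @param summary `"median"` (default) or `"mean"`.
#' @return a `beta_matrix`; for phylosor, attribute `aggregation` records the
#'   summary used and `n_trees` the number of trees.
#' @export
beta_over_trees <- function(community, trees, metric = c("phylosor", "sorensen"),
                            summary = c("median", "mean")) {
  metric <- match.arg(metric)
  summary <- match.arg(summary)
  if (metric == "sorensen") return(sorensen_matrix(community))
  trees <- as_tree_sample(trees)
  mats <- lapply(unclass(trees), function(tr) phylosor_matrix(community, tr))
  arr <- array(unlist(mats), dim = c(dim(mats[[1L]]), length(mats)))
  fun <- if (summary == "median") median else mean
  d <- apply(arr, c(1L, 2L), fun)
  dimnames(d) <- dimnames(mats[[1L]])
  structure(d, metric = "phylosor",
            aggregation = paste0("cross-tree ", summary),
            n_trees = length(trees),
            class = c("beta_matrix", "matrix"))
}

#' Long-format view of a beta matrix
#'
#' @param beta a `beta_matrix`.
#' @return data.frame with columns `site_i`, `site_j`, `value`, one row per
#'   unordered pair.
#' @export
beta_long <- function(beta) {
  ids <- rownames(beta)
  ij <- which(upper.tri(beta), arr.ind = TRUE)
  data.frame(site_i = ids[ij[, 1L]], site_j = ids[ij[, 2L]],
             value = beta[ij], stringsAsFactors = FALSE)
}
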