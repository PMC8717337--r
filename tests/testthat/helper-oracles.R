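# Brute-force oracles, independent of the package's incidence-matrix and
# crossprod implementations: everything here works by explicit path/pair
# enumeration on the ape edge table.

# edge indices on the path from the root to a tip, by walking parent pointers
.oracle_root_path <- function(tree, node) {
  edges <- integer(0)
  repeat {
    row <- which(tree$edge[, 2L] == node)
    if (!length(row)) break
    edges <- c(edges, row)
    node <- tree$edge[row, 1L]
  }
  edges
}

oracle_dist <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  pa <- .oracle_root_path(tree, ia)
  pb <- .oracle_root_path(tree, ib)
  # symmetric difference of the two root paths
  sum(tree$edge.length[setdiff(pa, pb)]) + sum(tree$edge.length[setdiff(pb, pa)])
}

oracle_pd <- function(tree, taxa, include_root = FALSE) {
  if (length(taxa) < 2L && !include_root) return(NA_real_)
  paths <- lapply(match(taxa, tree$tip.label), .oracle_root_path, tree = tree)
  union_edges <- Reduce(union, paths)
  if (include_root) return(sum(tree$edge.length[union_edges]))
  common <- Reduce(intersect, paths)  # edges above the MRCA
  sum(tree$edge.length[setdiff(union_edges, common)])
}

oracle_pairs <- function(tree, taxa) {
  pr <- utils::combn(taxa, 2L)
  vapply(seq_len(ncol(pr)), function(k) oracle_dist(tree, pr[1L, k], pr[2L, k]),
         numeric(1L))
}

oracle_mpd <- function(tree, taxa) mean(oracle_pairs(tree, taxa))

oracle_mntd <- function(tree, taxa) {
  mean(vapply(taxa, function(ti) {
    min(vapply(setdiff(taxa, ti), function(tj) oracle_dist(tree, ti, tj),
               numeric(1L)))
  }, numeric(1L)))
}

oracle_vpd <- function(tree, taxa) {
  dd <- oracle_pairs(tree, taxa)
  mean((dd - mean(dd))^2)
}

# PhyloSor by explicit edge-set arithmetic relative to the pooled-pair MRCA:
# BL_X = edges on tip-to-root paths of X minus edges shared by every pooled
# tip (i.e. above the pooled MRCA); shared = intersection of the two sets.
oracle_phylosor <- function(tree, taxa_a, taxa_b) {
  pa <- lapply(match(taxa_a, tree$tip.label), .oracle_root_path, tree = tree)
  pb <- lapply(match(taxa_b, tree$tip.label), .oracle_root_path, tree = tree)
  above <- Reduce(intersect, c(pa, pb))
  ea <- setdiff(Reduce(union, pa), above)
  eb <- setdiff(Reduce(union, pb), above)
  bl_a <- sum(tree$edge.length[ea])
  bl_b <- sum(tree$edge.length[eb])
  shared <- sum(tree$edge.length[intersect(ea, eb)])
  if (bl_a + bl_b == 0) return(0)
  1 - shared / (0.5 * (bl_a + bl_b))
}
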