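#' Species richness of a community
#'
#' @param x binary occurrence vector, or a binary site x species matrix (then
#'   one value per site).
#' @return integer count(s) of present species.
#' @export
richness <- function(x) {
  if (is.matrix(x)) return(as.integer(rowSums(x)))
  as.integer(sum(x))
}

#' Faith's phylogenetic diversity (root-excluded)
#'
#' Total branch length of the minimal subtree connecting the present taxa,
#' rooted at their most recent common ancestor (no edge above the MRCA is
#' counted). Undefined (`NA`) for fewer than two taxa.
#'
#' @param tree a `phylo`.
#' @param taxa character vector of present taxa.
#' @return PD in branch-length units, or `NA`.
#' @export
faith_pd <- function(tree, taxa) {
  if (length(taxa) < 2L) return(NA_real_)
  subtree_length(tree, taxa, include_root = FALSE)
}

.pair_dists <- function(dist, taxa) {
  taxa <- as.character(taxa)
  unknown <- setdiff(taxa, rownames(dist))
  if (length(unknown)) stop("taxa not in distance matrix: ",
                            paste(unknown, collapse = ", "))
  d <- dist[taxa, taxa, drop = FALSE]
  d[upper.tri(d)]
}

#' Mean pairwise phylogenetic distance (MPD)
#'
#' Average patristic distance over all unordered pairs of present taxa.
#'
#' @param dist patristic distance matrix (labels as dimnames).
#' @param taxa present taxa.
#' @return MPD, or `NA` for fewer than two taxa.
#' @export
mpd <- function(dist, taxa) {
  if (length(taxa) < 2L) return(NA_real_)
  mean(.pair_dists(dist, taxa))
}

#' Mean nearest taxon distance (MNTD)
#'
#' Average, over present taxa, of each taxon's distance to its closest
#' co-occurring relative.
#'
#' @inheritParams mpd
#' @return MNTD, or `NA` for fewer than two taxa.
#' @export
mntd <- function(dist, taxa) {
  taxa <- as.character(taxa)
  if (length(taxa) < 2L) return(NA_real_)
  unknown <- setdiff(taxa, rownames(dist))
  if (length(unknown)) stop("taxa not in distance matrix: ",
                            paste(unknown, collapse = ", "))
  d <- dist[taxa, taxa, drop = FALSE]
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

#' Variance of pairwise distances (VPD)
#'
#' Population variance of the multiset of the S(S-1)/2 pairwise patristic
#' distances among present taxa (denominator = number of pairs, not pairs - 1),
#' i.e. the average squared deviation from MPD. High values indicate a
#' community mixing very close and very distant relatives. VPD is reported on
#' the observed scale and is never standardized.
#'
#' @inheritParams mpd
#' @return VPD in squared branch-length units, or `NA` for fewer than two taxa.
#' @export
vpd <- function(dist, taxa) {
  if (length(taxa) < 2L) return(NA_real_)
  dd <- .pair_dists(dist, taxa)
  mean((dd - mean(dd))^2)
}

# Vectorized per-site metrics used by the SES machinery: comm is a binary
# sites x species matrix whose columns align with the tree tip order.
alpha_matrix_metrics <- function(comm, dist = NULL, inc = NULL, edge_len = NULL,
                                 metrics = c("PD", "MPD", "MNTD")) {
  S <- rowSums(comm)
  out <- list(S = as.integer(S))
  storage.mode(comm) <- "integer"
  if ("PD" %in% metrics) {
    cnt <- comm %*% (inc * 1)           # sites x edges path counts
    on_union <- (cnt > 0) %*% edge_len
    on_all <- (cnt == S & S > 0) %*% edge_len
    pd <- as.numeric(on_union - on_all)
    pd[S < 2] <- NA_real_
    out$PD <- pd
  }
  if ("MPD" %in% metrics) out$MPD <- as.numeric(cpp_mpd(dist, comm))
  if ("MNTD" %in% metrics) out$MNTD <- as.numeric(cpp_mntd(dist, comm))
  if ("VPD" %in% metrics) {
    M <- comm * 1
    npair <- S * (S - 1) / 2
    s1 <- rowSums((M %*% dist) * M) / 2
    s2 <- rowSums((M %*% dist^2) * M) / 2
    mpd_ <- ifelse(npair > 0, s1 / npair, NA_real_)
    v <- ifelse(npair > 0, s2 / npair - mpd_^2, NA_real_)
    out$VPD <- pmax(v, 0)  # clamp tiny negative fp residue
  }
  out
}

#' Per-site alpha metrics for one phylogeny
#'
#' Computes S, root-excluded Faith's PD, MPD, MNTD and VPD for every site of a
#' community matrix against one tree. The cophenetic matrix is computed once
#' and reused. Sites with fewer than two species get `NA` for all phylogenetic
#' metrics.
#'
#' @param community binary site x species matrix; taxa must be tree tips.
#' @param tree a `phylo`.
#' @return a data.frame with columns `site`, `S`, `PD`, `MPD`, `MNTD`, `VPD`.
#' @export
compute_alpha <- function(community, tree) {
  validate_community(community)
  validate_phylogeny(tree)
  unknown <- setdiff(colnames(community), tree$tip.label)
  if (length(unknown)) stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  if (ncol(community) < 2L) {
    return(data.frame(site = rownames(community),
                      S = as.integer(rowSums(community)),
                      PD = NA_real_, MPD = NA_real_, MNTD = NA_real_,
                      VPD = NA_real_, row.names = NULL, stringsAsFactors = FALSE))
  }
  tr <- if (length(tree$tip.label) > ncol(community)) {
    prune_to(tree, colnames(community))
  } else tree
  comm <- community[, tr$tip.label, drop = FALSE]
  dist <- cophenetic_dist(tr)
  inc <- tip_edge_incidence(tr)
  vals <- alpha_matrix_metrics(comm, dist = dist, inc = inc,
                               edge_len = tr$edge.length,
                               metrics = c("PD", "MPD", "MNTD", "VPD"))
  data.frame(site = rownames(community), S = vals$S, PD = vals$PD,
             MPD = vals$MPD, MNTD = vals$MNTD, VPD = vals$VPD,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-site alpha metrics summarized across a tree sample
#'
#' Runs [compute_alpha()] on every tree of a posterior-like sample and
#' summarizes each phylogenetic metric across trees (default: median), the
#' aggregation used for tree-uncertainty-aware gradient analyses. S is
#' tree-independent.
#'
#' @param community binary site x species matrix.
#' @param trees a `tree_sample`.
#' @param summary `"median"` (default) or `"mean"`.
#' @return a data.frame like [compute_alpha()]'s.
#' @export
alpha_over_trees <- function(community, trees, summary = c("median", "mean")) {
  summary <- match.arg(summary)
  trees <- as_tree_sample(trees)
  fun <- if (summary == "median") median else mean
  per_tree <- lapply(unclass(trees), function(tr) compute_alpha(community, tr))
  out <- per_tree[[1L]]
  for (mcol in c("PD", "MPD", "MNTD", "VPD")) {
    vals <- vapply(per_tree, function(df) df[[mcol]], numeric(nrow(out)))
    vals <- matrix(vals, nrow = nrow(out))
    out[[mcol]] <- apply(vals, 1L, function(v) {
      if (all(is.na(v))) NA_real_ else fun(v, na.rm = TRUE)
    })
  }
  out
}
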