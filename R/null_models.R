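#' Null-model configuration
#'
#' Bundles the knobs of the randomization machinery. Swap effort counts
#' *successful* checkerboard swaps (default 1000 per null matrix) with a cap
#' on attempts (default 100 x number of matrix cells) so mixing is comparable
#' across matrix shapes and a swap-free matrix still terminates.
#'
#' @param model `"independent_swap"` (community null) or `"tip_shuffle"`
#'   (phylogeny null).
#' @param n_null_per_tree null replicates per tree (999 for the alpha SES
#'   metrics at study scale; 10 for SES.PhyloSor).
#' @param swap_successes successful swaps per null matrix.
#' @param swap_attempts_factor attempt cap = factor x rows x cols.
#' @param seed master RNG seed (integer) or `NULL`.
#' @param summary cross-tree aggregation, `"median"` or `"mean"`.
#' @param share_nulls reuse one null-matrix set across trees (speed-up with
#'   changed semantics: the paper-faithful default regenerates nulls per tree).
#' @return a list of class `null_config`.
#' @export
null_config <- function(model = c("independent_swap", "tip_shuffle"),
                        n_null_per_tree = 999L, swap_successes = 1000L,
                        swap_attempts_factor = 100L, seed = NULL,
                        summary = c("median", "mean"), share_nulls = FALSE) {
  model <- match.arg(model)
  summary <- match.arg(summary)
  stopifnot(n_null_per_tree >= 1L, swap_successes >= 1L,
            swap_attempts_factor >= 1L)
  structure(list(model = model, n_null_per_tree = as.integer(n_null_per_tree),
                 swap_successes = as.integer(swap_successes),
                 swap_attempts_factor = as.integer(swap_attempts_factor),
                 seed = seed, summary = summary,
                 share_nulls = isTRUE(share_nulls)),
            class = "null_config")
}

# Derive one reproducible sub-seed per stream from a master seed, so results
# do not depend on evaluation order.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}

#' Independent-swap randomization of a community matrix
#'
#' Repeatedly draws a random 2x2 submatrix and, iff it is a checkerboard
#' (`[[1,0],[0,1]]` or its complement), flips it. Every draw preserves all
#' site richness values (row sums) and species occupancy counts (column
#' sums). If the attempt cap is reached with zero successful swaps (e.g. a
#' perfectly nested matrix with no checkerboard), the matrix is returned
#' unchanged with a warning.
#'
#' @param community binary site x species matrix.
#' @param n_successes successful swaps to perform (default 1000).
#' @param max_attempts attempt cap (default 100 x cells).
#' @return the randomized matrix, with attributes `swaps` and `attempts`.
#' @export
independent_swap <- function(community, n_successes = 1000L,
                             max_attempts = 100L * length(community)) {
  validate_community(community)
  m <- community
  storage.mode(m) <- "integer"
  out <- cpp_independent_swap(m, as.integer(n_successes),
                              as.integer(min(max_attempts, .Machine$integer.max)))
  if (attr(out, "swaps") == 0L) {
    warning("no checkerboard found within the attempt cap; matrix returned unchanged")
  }
  dimnames(out) <- dimnames(community)
  storage.mode(out) <- "double"
  out
}

#' Tip-shuffle randomization of a phylogeny
#'
#' Keeps topology and branch lengths fixed and assigns the tip labels a
#' uniformly random permutation, destroying any association between the
#' phylogeny and species identity while preserving the tree shape (and hence
#' the multiset of cophenetic distances).
#'
#' @param tree a `phylo`.
#' @return the relabelled `phylo`.
#' @export
tip_shuffle <- function(tree) {
  validate_phylogeny(tree)
  tree$tip.label <- sample(tree$tip.label)
  tree
}

#' Alpha-metric standardized effect sizes over a tree sample
#'
#' For each tree: observed PD / MPD / MNTD per site; `n_null` independent-swap
#' null matrices, the metric recomputed on each; per-site SES =
#' (observed - null mean) / null sd. The per-site result reported is the
#' cross-tree summary (default median) of the per-tree SES values; the raw
#' per-tree values are kept alongside. Cells where the null sd is 0 or the
#' observed value is missing are `NA`.
#'
#' @param community binary site x species matrix; the null-model species pool
#'   is exactly the matrix's taxa (all observed species of the focal lineage).
#' @param trees a `tree_sample`.
#' @param metrics subset of `c("PD", "MPD", "MNTD")`.
#' @param config a [null_config()] with `model = "independent_swap"`.
#' @return an object of class `ses_alpha`: list with `summary` (data.frame:
#'   site, metric, observed, null_mean, null_sd, ses, quantile, n_trees,
#'   n_null — observed/null_mean/null_sd/ses/quantile are cross-tree
#'   summaries), `per_tree_ses` (site x metric x tree array), and `effort`
#'   (null-generation counters).
#' @export
ses_alpha <- function(community, trees, metrics = c("PD", "MPD", "MNTD"),
                      config = null_config()) {
  validate_community(community)
  trees <- as_tree_sample(trees)
  metrics <- match.arg(metrics, c("PD", "MPD", "MNTD"), several.ok = TRUE)
  if (config$model != "independent_swap") {
    stop("alpha SES uses the independent_swap null model")
  }
  n_tree <- length(trees)
  n_null <- config$n_null_per_tree
  sites <- rownames(community)
  n_site <- length(sites)
  max_att <- config$swap_attempts_factor * length(community)

  seeds <- derive_seeds(config$seed, n_tree + 1L)
  m_int <- community
  storage.mode(m_int) <- "integer"

  # optional speed-up: one null set reused across trees
  shared_nulls <- NULL
  if (config$share_nulls) {
    if (!is.null(seeds[[n_tree + 1L]])) set.seed(seeds[[n_tree + 1L]])
    shared_nulls <- lapply(seq_len(n_null), function(i) {
      cpp_independent_swap(m_int, config$swap_successes, max_att)
    })
  }

  obs_arr <- array(NA_real_, dim = c(n_site, length(metrics), n_tree),
                   dimnames = list(sites, metrics, NULL))
  ses_arr <- obs_arr
  mean_arr <- obs_arr
  sd_arr <- obs_arr
  rank_arr <- obs_arr
  total_nulls <- 0L

  for (t in seq_len(n_tree)) {
    if (!is.null(seeds[[t]])) set.seed(seeds[[t]])
    tr <- trees[[t]]
    comm <- community[, tr$tip.label, drop = FALSE]
    dist <- cophenetic_dist(tr)
    inc <- tip_edge_incidence(tr)
    obs <- alpha_matrix_metrics(comm, dist, inc, tr$edge.length, metrics)
    nulls <- array(NA_real_, dim = c(n_site, length(metrics), n_null))
    for (k in seq_len(n_null)) {
      nm <- if (config$share_nulls) shared_nulls[[k]] else
        cpp_independent_swap(m_int, config$swap_successes, max_att)
      nm <- nm[, tr$tip.label, drop = FALSE]
      nv <- alpha_matrix_metrics(nm, dist, inc, tr$edge.length, metrics)
      for (j in seq_along(metrics)) nulls[, j, k] <- nv[[metrics[j]]]
    }
    total_nulls <- total_nulls + n_null
    for (j in seq_along(metrics)) {
      o <- obs[[metrics[j]]]
      nm_j <- nulls[, j, , drop = FALSE]
      mu <- apply(nm_j, 1L, mean, na.rm = TRUE)
      sg <- apply(nm_j, 1L, sd, na.rm = TRUE)
      ses <- (o - mu) / sg
      ses[!is.finite(ses)] <- NA_real_
      rk <- vapply(seq_len(n_site), function(s) {
        v <- nm_j[s, 1L, ]
        if (is.na(o[s]) || all(is.na(v))) return(NA_real_)
        mean(v <= o[s], na.rm = TRUE)
      }, numeric(1L))
      obs_arr[, j, t] <- o
      mean_arr[, j, t] <- mu
      sd_arr[, j, t] <- sg
      ses_arr[, j, t] <- ses
      rank_arr[, j, t] <- rk
    }
  }

  fun <- if (config$summary == "median") median else mean
  agg <- function(a) apply(a, c(1L, 2L), function(v) {
    if (all(is.na(v))) NA_real_ else fun(v, na.rm = TRUE)
  })
  summ <- expand.grid(site = sites, metric = metrics,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  summ$observed <- as.vector(agg(obs_arr))
  summ$null_mean <- as.vector(agg(mean_arr))
  summ$null_sd <- as.vector(agg(sd_arr))
  summ$ses <- as.vector(agg(ses_arr))
  summ$quantile <- as.vector(agg(rank_arr))
  summ$n_trees <- n_tree
  summ$n_null <- n_null
  structure(list(summary = summ, per_tree_ses = ses_arr,
                 per_tree_observed = obs_arr,
                 effort = list(n_trees = n_tree, n_null_per_tree = n_null,
                               null_matrices_total = total_nulls,
                               swap_successes = config$swap_successes,
                               share_nulls = config$share_nulls,
                               summary = config$summary, seed = config$seed)),
            class = "ses_alpha")
}

#' @export
print.ses_alpha <- function(x, ...) {
  cat("ses_alpha:", x$effort$n_trees, "tree(s) x", x$effort$n_null_per_tree,
      "independent-swap nulls; cross-tree", x$effort$summary, "\n")
  print(utils::head(x$summary, 10L))
  invisible(x)
}

# Stratum tag for a site pair: "within:F" or "between:F1-F2" (alphabetical).
pair_stratum <- function(f1, f2) {
  f1 <- as.character(f1); f2 <- as.character(f2)
  ifelse(f1 == f2, paste0("within:", f1),
         paste0("between:", pmin(f1, f2), "-", pmax(f1, f2)))
}

#' SES.PhyloSor: standardized phylogenetic beta diversity
#'
#' Observed value per site pair = cross-tree summary (default median) of the
#' PhyloSor dissimilarity. Null distribution per pair = PhyloSor recomputed
#' with the community fixed and each tree's tips shuffled `n_null_per_tree`
#' times, pooled across trees (study scale: 100 trees x 10 shuffles = 1000
#' pooled null values). SES = (observed - null mean) / null sd. When an
#' environment table is supplied, each pair is tagged within-/between-
#' formation for stratified summaries.
#'
#' @param community binary site x species matrix.
#' @param trees a `tree_sample`.
#' @param env optional environment data.frame with `site` and `formation`.
#' @param config a [null_config()] with `model = "tip_shuffle"` (default here:
#'   10 shuffles per tree).
#' @return an object of class `ses_beta`: list with `pairs` (data.frame:
#'   site_i, site_j, stratum, observed, null_mean, null_sd, ses, n_null),
#'   `null_values` (pair x pooled-null matrix) and `effort`.
#' @export
ses_phylosor <- function(community, trees, env = NULL,
                         config = null_config(model = "tip_shuffle",
                                              n_null_per_tree = 10L)) {
  validate_community(community)
  trees <- as_tree_sample(trees)
  if (config$model != "tip_shuffle") {
    stop("SES.PhyloSor uses the tip_shuffle null model")
  }
  n_tree <- length(trees)
  n_shuf <- config$n_null_per_tree
  sites <- rownames(community)
  ut <- which(upper.tri(diag(length(sites))), arr.ind = TRUE)
  n_pair <- nrow(ut)

  seeds <- derive_seeds(config$seed, n_tree)
  obs_per_tree <- matrix(NA_real_, n_pair, n_tree)
  null_vals <- matrix(NA_real_, n_pair, n_tree * n_shuf)
  for (t in seq_len(n_tree)) {
    if (!is.null(seeds[[t]])) set.seed(seeds[[t]])
    tr <- trees[[t]]
    obs_per_tree[, t] <- phylosor_matrix(community, tr)[ut]
    for (k in seq_len(n_shuf)) {
      null_vals[, (t - 1L) * n_shuf + k] <-
        phylosor_matrix(community, tip_shuffle(tr))[ut]
    }
  }
  fun <- if (config$summary == "median") median else mean
  observed <- apply(obs_per_tree, 1L, function(v) {
    if (all(is.na(v))) NA_real_ else fun(v, na.rm = TRUE)
  })
  mu <- rowMeans(null_vals, na.rm = TRUE)
  sg <- apply(null_vals, 1L, sd, na.rm = TRUE)
  ses <- (observed - mu) / sg
  ses[!is.finite(ses)] <- NA_real_

  stratum <- NA_character_
  if (!is.null(env)) {
    f <- env$formation[match(sites, env$site)]
    stratum <- pair_stratum(f[ut[, 1L]], f[ut[, 2L]])
  }
  pairs <- data.frame(site_i = sites[ut[, 1L]], site_j = sites[ut[, 2L]],
                      stratum = stratum, observed = observed, null_mean = mu,
                      null_sd = sg, ses = ses, n_null = ncol(null_vals),
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, null_values = null_vals,
                 effort = list(n_trees = n_tree, n_shuffle_per_tree = n_shuf,
                               pooled_null_per_pair = n_tree * n_shuf,
                               summary = config$summary, seed = config$seed)),
            class = "ses_beta")
}

#' @export
print.ses_beta <- function(x, ...) {
  cat("ses_beta:", x$effort$n_trees, "tree(s) x", x$effort$n_shuffle_per_tree,
      "tip shuffles =", x$effort$pooled_null_per_pair,
      "pooled nulls per pair\n")
  print(utils::head(x$pairs, 10L))
  invisible(x)
}

#' Five-number summaries of SES.PhyloSor by formation stratum
#'
#' Summarizes pairwise SES values for each within-formation stratum and each
#' between-formation stratum (6 strata for 3 formations), for boxplot-style
#' comparison of phylogenetic turnover within vs. across geological surfaces.
#' Strata with no finite values are omitted with a message.
#'
#' @param ses_beta a `ses_beta` (pairs must carry stratum tags) or its `pairs`
#'   data.frame.
#' @return data.frame: stratum, type (within/between), n_pairs, min, q1,
#'   median, q3, max.
#' @export
summarize_ses_by_stratum <- function(ses_beta) {
  pairs <- if (inherits(ses_beta, "ses_beta")) ses_beta$pairs else ses_beta
  if (all(is.na(pairs$stratum))) stop("no stratum tags; supply env to ses_phylosor()")
  out <- lapply(split(pairs, pairs$stratum), function(df) {
    v <- df$ses[is.finite(df$ses)]
    if (!length(v)) return(NULL)
    fn <- fivenum(v)
    data.frame(stratum = df$stratum[1L],
               type = sub(":.*$", "", df$stratum[1L]),
               n_pairs = length(v), min = fn[1L], q1 = fn[2L],
               median = fn[3L], q3 = fn[4L], max = fn[5L],
               stringsAsFactors = FALSE)
  })
  dropped <- names(out)[vapply(out, is.null, logical(1L))]
  if (length(dropped)) message("stratum with no finite SES omitted: ",
                               paste(dropped, collapse = ", "))
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  rownames(out) <- NULL
  out
}
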