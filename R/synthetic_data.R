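# Study-design constants for the emulated sampling design: three geological
# strata with printed base-cation means and ranges (cmol(+)/kg) and site
# counts 9 / 12 / 19.
.stratum_calibration <- list(
  Solimoes = list(n = 9L, mean = 7.59, lo = 2.56, hi = 13.89),
  Ica = list(n = 12L, mean = 0.16, lo = 0.11, hi = 0.26),
  Terrace = list(n = 19L, mean = 0.37, lo = 0.18, hi = 0.60)
)

#' Simulate a pure-birth (Yule) phylogeny with a fixed crown age
#'
#' Birth-only tree with `n_tips` tips, rescaled so the crown depth equals
#' `crown_age` exactly (ultrametric). Tip labels are `sp001`, `sp002`, ...
#'
#' @param n_tips number of tips (>= 2).
#' @param crown_age crown depth in Ma.
#' @return a `phylo`.
#' @export
simulate_tree <- function(n_tips, crown_age = 100) {
  stopifnot(n_tips >= 2L, crown_age > 0)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (crown_age / depth)
  tr$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  validate_phylogeny(tr)
  tr
}

# moment-matched log-normal for one stratum: the printed range is treated as
# a central 95% interval (fixes sdlog); meanlog then matches the printed
# arithmetic mean exactly in expectation.
.stratum_lognormal <- function(calib) {
  sdlog <- log(calib$hi / calib$lo) / (2 * stats::qnorm(0.975))
  meanlog <- log(calib$mean) - sdlog^2 / 2
  c(meanlog = meanlog, sdlog = sdlog)
}

#' Simulate the site environment table
#'
#' Draws per-stratum base-cation concentrations from log-normal distributions
#' calibrated so each stratum's arithmetic mean matches the study design
#' (Solimoes 7.59, Ica 0.16, Terrace 0.37 cmol(+)/kg) and the bulk of draws
#' fall inside the design ranges. Default site counts are 9 / 12 / 19.
#' Covariates phosphorus, aluminum and pH are generated as noisy monotone
#' functions of the cation concentration (for exercising ordination arrows;
#' they carry no independent signal).
#'
#' @param n_sites named integer vector `c(solimoes=, ica=, terrace=)` (any
#'   count may be 0).
#' @return environment data.frame: site, base_cation, formation, phosphorus,
#'   aluminum, pH.
#' @export
simulate_environment <- function(n_sites = c(solimoes = 9L, ica = 12L,
                                             terrace = 19L)) {
  names(n_sites) <- tolower(names(n_sites))
  counts <- c(Solimoes = as.integer(n_sites[["solimoes"]]),
              Ica = as.integer(n_sites[["ica"]]),
              Terrace = as.integer(n_sites[["terrace"]]))
  stopifnot(all(counts >= 0L), sum(counts) > 0L)
  bc <- numeric(0)
  form <- character(0)
  for (f in names(counts)) {
    if (counts[[f]] == 0L) next
    par <- .stratum_lognormal(.stratum_calibration[[f]])
    bc <- c(bc, rlnorm(counts[[f]], par[["meanlog"]], par[["sdlog"]]))
    form <- c(form, rep(f, counts[[f]]))
  }
  n <- length(bc)
  data.frame(
    site = sprintf("T%02d", seq_len(n)),
    base_cation = bc,
    formation = factor(form, levels = .formation_levels),
    phosphorus = 50 * bc^0.6 * rlnorm(n, 0, 0.3),
    aluminum = 2.5 * bc^-0.25 * rlnorm(n, 0, 0.2),
    pH = pmax(3.2, 4.3 + 0.8 * log10(bc) + stats::rnorm(n, 0, 0.15)),
    stringsAsFactors = FALSE
  )
}

#' Evolve edaphic niches along a phylogeny
#'
#' Realizes per-species edaphic niche parameters: an optimum `mu` on the
#' log10 base-cation axis, a tolerance `tau` and a maximum occupancy `p_max`.
#' Two generators:
#' * `"brownian"`: `mu` evolves by Brownian motion from `root_value`
#'   (phylogenetically conserved niches, no directional bias);
#' * `"biased_two_state"`: a binary poor/rich substrate-preference state
#'   evolves by an asymmetric Markov process (rates `q_pr` poor-to-rich and
#'   `q_rp` rich-to-poor, per unit crown depth), and `mu` is drawn from the
#'   state-conditional normal at each tip. With `q_pr >> q_rp` rich-adapted
#'   species arise all over the tree while poor-soil specialists stay
#'   concentrated in the few lineages that never left the poor state.
#'
#' @param tree a `phylo`.
#' @param generator `"brownian"` or `"biased_two_state"`.
#' @param root_value Brownian root optimum.
#' @param sigma Brownian rate per sqrt(Ma); default scales so the expected
#'   tip standard deviation is 0.8 gradient units.
#' @param tau niche tolerance (single value or per species).
#' @param p_max maximum occupancy probability.
#' @param q_pr,q_rp state transition rates per unit crown depth.
#' @param root_state `"poor"` or `"rich"`.
#' @param mu_poor,mu_rich `c(mean, sd)` of the state-conditional optimum.
#' @return data.frame of class `niche_model`: species, mu, tau, p_max, state.
#' @export
simulate_niche <- function(tree,
                           generator = c("brownian", "biased_two_state"),
                           root_value = 0, sigma = NULL,
                           tau = 0.5, p_max = 0.8,
                           q_pr = 3, q_rp = 0.3, root_state = "poor",
                           mu_poor = c(-0.65, 0.2), mu_rich = c(0.85, 0.2)) {
  generator <- match.arg(generator)
  validate_phylogeny(tree)
  depth <- max(ape::node.depth.edgelength(tree))
  n <- length(tree$tip.label)
  stopifnot(all(tau > 0), all(p_max > 0 & p_max <= 1))
  if (generator == "brownian") {
    if (is.null(sigma)) sigma <- 0.8 / sqrt(depth)
    mu <- ape::rTraitCont(tree, model = "BM", sigma = sigma,
                          root.value = root_value)
    mu <- mu[tree$tip.label]
    state <- rep(NA_character_, n)
  } else {
    # rTraitDisc: rates[i, j] = rate of change from state i to state j;
    # state 1 = poor, state 2 = rich
    rates <- matrix(c(0, q_rp / depth, q_pr / depth, 0), 2L, 2L)
    st <- ape::rTraitDisc(tree, model = rates, states = c("poor", "rich"),
                          root.value = if (root_state == "poor") 1L else 2L)
    state <- as.character(st[tree$tip.label])
    mu <- ifelse(state == "poor",
                 stats::rnorm(n, mu_poor[1L], mu_poor[2L]),
                 stats::rnorm(n, mu_rich[1L], mu_rich[2L]))
  }
  out <- data.frame(species = tree$tip.label, mu = as.numeric(mu),
                    tau = rep_len(tau, n), p_max = rep_len(p_max, n),
                    state = state, stringsAsFactors = FALSE)
  class(out) <- c("niche_model", "data.frame")
  out
}

#' Assemble communities by Gaussian niche filtering
#'
#' Presence of species `s` at site `j` is an independent Bernoulli draw with
#' `P = p_max[s] * exp(-(x_j - mu[s])^2 / (2 tau[s]^2))`, where `x_j` is the
#' site's log10 base-cation concentration. Sites that end up empty are
#' retained.
#'
#' @param env environment data.frame (needs `site`, `base_cation`).
#' @param niche a `niche_model`.
#' @return binary site x species matrix.
#' @export
assemble_communities <- function(env, niche) {
  x <- log10(env$base_cation)
  p <- vapply(seq_len(nrow(niche)), function(s) {
    niche$p_max[s] * exp(-(x - niche$mu[s])^2 / (2 * niche$tau[s]^2))
  }, numeric(length(x)))
  p <- matrix(p, nrow = length(x),
              dimnames = list(env$site, niche$species))
  occ <- matrix(rbinom(length(p), 1L, p), nrow = nrow(p),
                dimnames = dimnames(p))
  storage.mode(occ) <- "double"
  occ
}

#' Pseudo-posterior tree sample by branch-length jitter
#'
#' Emulates a posterior sample of dated trees: topology fixed, every branch
#' length multiplied by an independent log-normal factor with mean 1 and
#' coefficient of variation `cv`.
#'
#' @param tree a `phylo`.
#' @param n_trees number of draws (>= 1).
#' @param cv coefficient of variation of the branch factors (>= 0).
#' @return a `tree_sample`.
#' @export
jitter_tree_sample <- function(tree, n_trees = 10L, cv = 0.1) {
  validate_phylogeny(tree)
  stopifnot(n_trees >= 1L, cv >= 0)
  sdlog <- sqrt(log(1 + cv^2))
  draws <- lapply(seq_len(n_trees), function(i) {
    tr <- tree
    if (cv > 0) {
      tr$edge.length <- tr$edge.length *
        rlnorm(length(tr$edge.length), -sdlog^2 / 2, sdlog)
    }
    tr
  })
  as_tree_sample(draws)
}

# Largest clade with tip count closest to `target`; deterministic given the
# tree. Returns tip labels.
.pick_clade <- function(tree, target) {
  ntip <- length(tree$tip.label)
  sizes <- vapply((ntip + 1L):(ntip + tree$Nnode), function(nd) {
    length(ape::extract.clade(tree, nd)$tip.label)
  }, integer(1L))
  cand <- which(sizes < ntip)  # exclude the root clade
  best <- cand[which.min(abs(sizes[cand] - target))]
  ape::extract.clade(tree, ntip + best)$tip.label
}

.scenarios <- c("fern_like", "palm_like", "clustered", "neutral")

#' Generate a complete synthetic dataset with known assembly truth
#'
#' Bundles tree simulation, environment simulation, niche evolution, niche
#' filtering and pseudo-posterior jitter into named scenarios emulating the
#' study's assembly hypotheses:
#' * `"fern_like"`: deep, strongly biased two-state niches (`q_pr >> q_rp`,
#'   poor root): a majority rich-adapted pool with poor-soil specialists
#'   concentrated in few deep lineages; narrow tolerances (specialists).
#'   Species richness increases with soil cation concentration.
#' * `"palm_like"`: younger tree, mostly poor-adapted pool with broad
#'   tolerances (generalists); richness decreases along the gradient.
#' * `"clustered"`: one clade (about a quarter of the tips) exclusively
#'   poor-adapted, everything else rich-adapted: poor-soil communities are
#'   drawn from a single clade and are phylogenetically clustered.
#' * `"neutral"`: optima independent of the phylogeny and uniform over the
#'   gradient, with a tolerance far broader than the gradient span so
#'   filtering is effectively absent and expected occupancy is flat across
#'   sites: no built-in richness trend or phylogenetic structure (the
#'   negative control).
#'
#' The dataset regenerates byte-identically from `(scenario, seed)`.
#'
#' @param scenario one of `"fern_like"`, `"palm_like"`, `"clustered"`,
#'   `"neutral"`.
#' @param seed integer RNG seed.
#' @param n_tips species-pool size (default 60).
#' @param n_trees pseudo-posterior sample size (default 10).
#' @param cv branch-length jitter coefficient of variation (default 0.1).
#' @param n_sites per-stratum site counts as in [simulate_environment()].
#' @return an object of class `synthetic_dataset`: list with `tree`, `trees`,
#'   `community`, `env`, `truth`.
#' @export
generate_dataset <- function(scenario, seed, n_tips = 60L, n_trees = 10L,
                             cv = 0.1,
                             n_sites = c(solimoes = 9L, ica = 12L,
                                         terrace = 19L)) {
  if (!scenario %in% .scenarios) {
    stop("unknown scenario '", scenario, "'; valid: ",
         paste(.scenarios, collapse = ", "))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))

  crown_age <- switch(scenario, fern_like = 330, palm_like = 106, 100)
  tree <- simulate_tree(n_tips, crown_age)
  env <- simulate_environment(n_sites)

  params <- switch(scenario,
    fern_like = list(generator = "biased_two_state", q_pr = 3, q_rp = 0.3,
                     root_state = "poor", mu_poor = c(-0.65, 0.2),
                     mu_rich = c(0.85, 0.2), tau = 0.35, p_max = 0.7),
    palm_like = list(generator = "biased_two_state", q_pr = 0.5, q_rp = 0.5,
                     root_state = "poor", mu_poor = c(-0.5, 0.25),
                     mu_rich = c(0.7, 0.25), tau = 0.7, p_max = 0.85),
    clustered = list(clade_fraction = 0.25, mu_poor = c(-0.6, 0.15),
                     mu_rich = c(0.8, 0.3), tau = 0.4, p_max = 0.8),
    neutral = list(mu_range = c(-2, 2.4), tau = 12, p_max = 0.6))

  if (scenario %in% c("fern_like", "palm_like")) {
    niche <- simulate_niche(tree, generator = "biased_two_state",
                            q_pr = params$q_pr, q_rp = params$q_rp,
                            root_state = params$root_state,
                            mu_poor = params$mu_poor, mu_rich = params$mu_rich,
                            tau = params$tau, p_max = params$p_max)
  } else if (scenario == "clustered") {
    clade <- .pick_clade(tree, round(params$clade_fraction * n_tips))
    in_clade <- tree$tip.label %in% clade
    mu <- ifelse(in_clade,
                 stats::rnorm(n_tips, params$mu_poor[1L], params$mu_poor[2L]),
                 stats::rnorm(n_tips, params$mu_rich[1L], params$mu_rich[2L]))
    niche <- data.frame(species = tree$tip.label, mu = mu,
                        tau = rep(params$tau, n_tips),
                        p_max = rep(params$p_max, n_tips),
                        state = ifelse(in_clade, "poor", "rich"),
                        stringsAsFactors = FALSE)
    class(niche) <- c("niche_model", "data.frame")
    params$clade_tips <- clade
  } else {
    mu <- runif(n_tips, params$mu_range[1L], params$mu_range[2L])
    niche <- data.frame(species = tree$tip.label, mu = mu,
                        tau = rep(params$tau, n_tips),
                        p_max = rep(params$p_max, n_tips),
                        state = NA_character_, stringsAsFactors = FALSE)
    class(niche) <- c("niche_model", "data.frame")
  }

  community <- assemble_communities(env, niche)
  trees <- jitter_tree_sample(tree, n_trees, cv)

  truth <- list(scenario = scenario, seed = as.integer(seed),
                n_tips = as.integer(n_tips), n_trees = as.integer(n_trees),
                cv = cv, crown_age = crown_age,
                n_sites = as.list(setNames(as.integer(n_sites),
                                           names(n_sites))),
                params = params[setdiff(names(params), "clade_tips")],
                clade_tips = params$clade_tips,
                niche = as.data.frame(niche))
  structure(list(tree = tree, trees = trees, community = community,
                 env = env, truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset '", x$truth$scenario, "' (seed ", x$truth$seed, "): ",
      nrow(x$community), " sites x ", ncol(x$community), " taxa, ",
      length(x$trees), " tree(s)\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `trees.nwk` (one Newick per line), `community.csv`,
#' `environment.csv`, `truth.json` and `manifest.json` (seed and parameters),
#' so the full pipeline can be re-run from files alone.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(dataset$trees, file.path(dir, "trees.nwk"))
  write_community(dataset$community, file.path(dir, "community.csv"))
  write.csv(dataset$env, file.path(dir, "environment.csv"), row.names = FALSE)
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- dataset$truth[c("scenario", "seed", "n_tips", "n_trees", "cv",
                              "crown_age")]
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
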