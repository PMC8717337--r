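test_that("independent swap preserves row and column sums on every draw", {
  set.seed(101)
  for (i in 1:25) {
    nr <- sample(3:10, 1L); nc <- sample(3:12, 1L)
    m <- matrix(rbinom(nr * nc, 1, runif(1, 0.2, 0.8)), nr, nc,
                dimnames = list(paste0("s", 1:nr), paste0("t", 1:nc)))
    storage.mode(m) <- "double"
    out <- suppressWarnings(independent_swap(m, n_successes = 200L))
    expect_equal(rowSums(out), rowSums(m))
    expect_equal(colSums(out), colSums(m))
    expect_true(all(out %in% c(0, 1)))
  }
})

test_that("the only move on a 2x2 checkerboard is its complement", {
  m <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  set.seed(5)
  out <- independent_swap(m, n_successes = 1L)
  expect_equal(unname(unclass(out))[], matrix(c(0, 1, 1, 0), 2, 2),
               ignore_attr = TRUE)
  expect_equal(attr(out, "swaps"), 1L)
})

test_that("a swap-free matrix is returned unchanged with a warning", {
  nested <- matrix(c(1, 1, 1, 0, 1, 1, 0, 0, 1), 3, 3, byrow = TRUE,
                   dimnames = list(paste0("s", 1:3), paste0("t", 1:3)))
  expect_warning(out <- independent_swap(nested, n_successes = 10L,
                                         max_attempts = 2000L),
                 "unchanged")
  expect_equal(unclass(out), nested, ignore_attr = TRUE)
})

test_that("long-run swap states are near-uniform over reachable states", {
  # identity 3x3: reachable states are the 6 permutation matrices, so under
  # uniform sampling P(out[1,1] == 1) = 1/3
  m <- matrix(0, 3, 3, dimnames = list(paste0("s", 1:3), paste0("t", 1:3)))
  m[1, 1] <- 1; m[2, 2] <- 1; m[3, 3] <- 1
  set.seed(7)
  hits <- replicate(600, {
    out <- suppressWarnings(independent_swap(m, n_successes = 25L,
                                             max_attempts = 10000L))
    out[1, 1]
  })
  expect_gt(mean(hits), 1 / 3 - 0.08)
  expect_lt(mean(hits), 1 / 3 + 0.08)
})

test_that("tip shuffle keeps the shape and permutes labels uniformly", {
  tr <- toy5()
  set.seed(11)
  sh <- tip_shuffle(tr)
  expect_setequal(sh$tip.label, tr$tip.label)
  expect_equal(sort(as.vector(cophenetic_dist(sh))),
               sort(as.vector(cophenetic_dist(tr))))

  tr3 <- read_newick(text = "((A:1,B:2):1,C:3);")[[1L]]
  set.seed(13)
  perms <- replicate(6000, paste(tip_shuffle(tr3)$tip.label, collapse = ""))
  tab <- table(perms)
  expect_equal(length(tab), 6L)
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 1e-4)
})

test_that("ses_alpha is deterministic and centered under its own null", {
  set.seed(201)
  tree <- simulate_tree(30, 100)
  comm <- random_community(tree, 20, fill = 0.5)
  ts <- as_tree_sample(tree)

  cfg <- null_config(n_null_per_tree = 49L, seed = 77L)
  r1 <- ses_alpha(comm, ts, metrics = "MPD", config = cfg)
  r2 <- ses_alpha(comm, ts, metrics = "MPD", config = cfg)
  expect_identical(r1$summary, r2$summary)

  # community drawn from the swap null itself: median SES near 0
  set.seed(202)
  nullcomm <- independent_swap(comm)
  sa <- ses_alpha(nullcomm, ts, metrics = "MPD",
                  config = null_config(n_null_per_tree = 199L, seed = 3L))
  expect_lt(abs(median(sa$summary$ses, na.rm = TRUE)), 0.2)

  # single tree: summary equals the per-tree SES
  expect_equal(sa$summary$ses, unname(sa$per_tree_ses[, 1L, 1L]))

  # effort counters
  expect_equal(sa$effort$n_null_per_tree, 199L)
  expect_equal(sa$effort$null_matrices_total, 199L)
})

test_that("cross-tree aggregation takes the median of per-tree SES", {
  set.seed(211)
  tree <- simulate_tree(15, 50)
  comm <- random_community(tree, 8, fill = 0.6)
  ts <- jitter_tree_sample(tree, 5L, cv = 0.2)
  sa <- ses_alpha(comm, ts, metrics = c("PD", "MPD"),
                  config = null_config(n_null_per_tree = 29L, seed = 9L))
  med <- apply(sa$per_tree_ses, c(1L, 2L), median, na.rm = TRUE)
  for (m in c("PD", "MPD")) {
    rows <- sa$summary[sa$summary$metric == m, ]
    expect_equal(rows$ses, unname(med[rows$site, m]))
  }
  expect_equal(sa$effort$null_matrices_total, 5L * 29L)
})

test_that("ses_phylosor pools tip-shuffle nulls and tags strata", {
  set.seed(301)
  tree <- simulate_tree(20, 80)
  comm <- random_community(tree, 8, fill = 0.5)
  comm[rowSums(comm) == 0, 1L] <- 1
  comm[2L, ] <- comm[1L, ]  # two identical communities
  env <- data.frame(site = rownames(comm),
                    base_cation = c(0.2, 0.2, 0.3, 5, 7, 0.15, 0.4, 9),
                    formation = factor(c("Ica", "Ica", "Terrace", "Solimoes",
                                         "Solimoes", "Ica", "Terrace",
                                         "Solimoes")))
  ts <- jitter_tree_sample(tree, 4L, cv = 0.1)
  sb <- ses_phylosor(comm, ts, env = env,
                     config = null_config(model = "tip_shuffle",
                                          n_null_per_tree = 10L, seed = 5L))
  expect_equal(sb$effort$pooled_null_per_pair, 40L)
  expect_equal(unique(sb$pairs$n_null), 40L)
  expect_equal(ncol(sb$null_values), 40L)

  # identical communities: dissimilarity 0 under every tree, so the
  # tip-shuffle null is degenerate there and SES is undefined (missing)
  pair12 <- sb$pairs[sb$pairs$site_i == "site01" & sb$pairs$site_j == "site02", ]
  expect_equal(pair12$observed, 0)
  expect_true(is.na(pair12$ses))
  expect_equal(pair12$stratum, "within:Ica")

  # two communities that both span the deep split share the long basal
  # branches, far more than tip-shuffled nulls allow: strongly negative SES
  deep <- ape::read.tree(text = paste0(
    "(((a1:1,a2:1):1,(a3:1,a4:1):1):20,((b1:1,b2:1):1,(b3:1,b4:1):1):20);"))
  comm3 <- matrix(0, 2, 8, dimnames = list(c("p1", "p2"), deep$tip.label))
  comm3["p1", c("a1", "b1")] <- 1
  comm3["p2", c("a2", "b2")] <- 1
  sb3 <- ses_phylosor(comm3, as_tree_sample(deep),
                      config = null_config(model = "tip_shuffle",
                                           n_null_per_tree = 500L, seed = 1L))
  expect_lt(sb3$pairs$ses[1L], -1)
  expect_true(all(grepl("^(within|between):", sb$pairs$stratum)))

  strat <- summarize_ses_by_stratum(sb)
  expect_equal(nrow(strat), 6L)
  expect_setequal(strat$type, c("within", "between"))
})

test_that("stratum summaries are five-number order statistics", {
  pairs <- data.frame(site_i = "a", site_j = "b",
                      stratum = "within:Ica",
                      ses = c(-2, -1, 0, 1, 2))
  s <- summarize_ses_by_stratum(pairs)
  expect_equal(nrow(s), 1L)
  expect_equal(s$median, 0)
  expect_equal(s$q1, -1)
  expect_equal(s$q3, 1)
  expect_equal(s$min, -2)
  expect_equal(s$max, 2)
})

test_that("tip-shuffle SES is centered when labels carry no signal", {
  set.seed(401)
  ds <- generate_dataset("neutral", 19, n_tips = 40L, n_trees = 10L)
  base <- ds$community[1:20, ]
  base <- base[, colSums(base) > 0]
  base <- base[rowSums(base) > 0, , drop = FALSE]
  trees <- as_tree_sample(lapply(unclass(ds$trees), prune_to,
                                 taxa = colnames(base)))
  # pair-level SES values are strongly correlated through the one labelling
  # of the tree (per-labeling means scatter with sd ~ 0.23), so average over
  # independent random labelings
  labeling_mean <- vapply(1:20, function(r) {
    comm <- base
    colnames(comm) <- sample(colnames(comm))
    sb <- ses_phylosor(comm, trees[1:5],
                       config = null_config(model = "tip_shuffle",
                                            n_null_per_tree = 10L, seed = r))
    mean(sb$pairs$ses, na.rm = TRUE)
  }, numeric(1L))
  expect_lt(abs(mean(labeling_mean)), 0.15)
})
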