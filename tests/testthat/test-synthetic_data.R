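test_that("simulate_tree yields ultrametric trees of the requested crown age", {
  set.seed(111)
  cherry <- simulate_tree(2, crown_age = 100)
  expect_equal(sort(cherry$edge.length), c(100, 100))
  tr <- simulate_tree(60, crown_age = 106)
  depths <- ape::node.depth.edgelength(tr)[seq_len(60)]
  expect_equal(max(depths), 106, tolerance = 1e-9)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_equal(length(tr$tip.label), 60L)
})

test_that("simulate_environment matches the stratified design", {
  set.seed(121)
  env <- simulate_environment()
  expect_equal(nrow(env), 40L)
  expect_equal(as.vector(table(env$formation)[c("Solimoes", "Ica", "Terrace")]),
               c(9L, 12L, 19L))
  expect_true(all(env$base_cation > 0))
  expect_true(all(c("phosphorus", "aluminum", "pH") %in% names(env)))

  only_ter <- simulate_environment(c(solimoes = 0, ica = 0, terrace = 5))
  expect_equal(nrow(only_ter), 5L)
  expect_true(all(only_ter$formation == "Terrace"))

  # stratum arithmetic means converge to the design values
  set.seed(122)
  big <- simulate_environment(c(solimoes = 10000, ica = 10000, terrace = 10000))
  means <- tapply(big$base_cation, big$formation, mean)
  expect_equal(unname(means[["Solimoes"]]), 7.59, tolerance = 0.3 / 7.59)
  expect_equal(unname(means[["Ica"]]), 0.16, tolerance = 0.05)
  expect_equal(unname(means[["Terrace"]]), 0.37, tolerance = 0.05)
})

test_that("niche evolution is phylogenetically structured as configured", {
  set.seed(131)
  tree <- simulate_tree(50, 100)

  flat <- simulate_niche(tree, "brownian", sigma = 0, root_value = 0.4)
  expect_true(all(flat$mu == 0.4))

  # Brownian: variance of tip differences grows with patristic distance
  bm <- simulate_niche(tree, "brownian")
  d <- cophenetic_dist(tree)
  dm <- abs(outer(bm$mu, bm$mu, "-"))[upper.tri(d)]
  dp <- d[upper.tri(d)]
  close_pairs <- dm[dp < quantile(dp, 0.2)]
  far_pairs <- dm[dp > quantile(dp, 0.8)]
  expect_lt(mean(close_pairs), mean(far_pairs))

  # biased two-state: mostly rich tips, poor tips clumped into few clades
  set.seed(132)
  b2 <- simulate_niche(tree, "biased_two_state", q_pr = 3, q_rp = 0.3,
                       root_state = "poor")
  expect_gt(mean(b2$state == "rich"), 0.5)
  poor <- b2$species[b2$state == "poor"]
  if (length(poor) >= 3L) {
    poor_d <- cophenetic_dist(tree)[poor, poor]
    all_d <- cophenetic_dist(tree)
    expect_lt(mean(poor_d[upper.tri(poor_d)]), mean(all_d[upper.tri(all_d)]))
  }
})

test_that("niche filtering assembles communities at the analytic rates", {
  env <- data.frame(site = c("a", "b"), base_cation = c(0.1, 10))
  niche <- data.frame(species = c("s1", "s2"), mu = c(-1, 1),
                      tau = c(0.5, 0.5), p_max = c(0.8, 0.6),
                      state = NA_character_)
  # mu equal to site's log10 cation: presence probability is exactly p_max
  set.seed(141)
  hits <- replicate(3000, assemble_communities(env, niche)["a", "s1"])
  expect_equal(mean(hits), 0.8, tolerance = 0.03)

  # broad tolerance limit: probability ~ p_max everywhere
  niche$tau <- 1e6
  set.seed(142)
  occ <- replicate(2000, assemble_communities(env, niche)["b", "s1"])
  expect_equal(mean(occ), 0.8, tolerance = 0.04)

  # expected richness = sum of presence probabilities, within 3 SE
  set.seed(143)
  env2 <- data.frame(site = "x", base_cation = 1)
  niche2 <- data.frame(species = sprintf("s%d", 1:30),
                       mu = seq(-1, 1, length.out = 30),
                       tau = 0.6, p_max = 0.7, state = NA_character_)
  p <- 0.7 * exp(-(0 - niche2$mu)^2 / (2 * 0.6^2))
  reps <- replicate(200, sum(assemble_communities(env2, niche2)))
  se <- sqrt(sum(p * (1 - p)) / 200)
  expect_lt(abs(mean(reps) - sum(p)), 3 * se)
})

test_that("jitter_tree_sample perturbs lengths but not topology", {
  set.seed(151)
  tree <- simulate_tree(20, 100)
  same <- jitter_tree_sample(tree, 4L, cv = 0)
  for (tr in unclass(same)) expect_equal(tr$edge.length, tree$edge.length)

  js <- jitter_tree_sample(tree, 50L, cv = 0.1)
  for (tr in unclass(js)[c(1L, 25L)]) {
    expect_identical(tr$edge, tree$edge)
    expect_identical(tr$tip.label, tree$tip.label)
  }
  # mean-1 multiplicative noise: per-branch averages near the original
  lens <- vapply(unclass(js), function(tr) tr$edge.length,
                 numeric(length(tree$edge.length)))
  ratio <- rowMeans(lens) / tree$edge.length
  expect_lt(max(abs(ratio - 1)), 0.1)
  expect_lt(abs(mean(ratio) - 1), 0.02)
})

test_that("datasets regenerate byte-identically and scenarios are named", {
  d1 <- generate_dataset("clustered", 33, n_tips = 30L, n_trees = 3L)
  d2 <- generate_dataset("clustered", 33, n_tips = 30L, n_trees = 3L)
  expect_identical(d1$community, d2$community)
  expect_identical(d1$env, d2$env)
  expect_identical(d1$trees[[3L]], d2$trees[[3L]])
  expect_identical(d1$truth, d2$truth)
  expect_error(generate_dataset("weird", 1), "fern_like")

  dir <- withr::local_tempdir()
  write_dataset(d1, dir)
  expect_true(all(file.exists(file.path(dir, c("trees.nwk", "community.csv",
                                               "environment.csv", "truth.json",
                                               "manifest.json")))))
  back <- read_community(file.path(dir, "community.csv"))
  expect_equal(back, d1$community)
  env_back <- read_environment(file.path(dir, "environment.csv"))
  expect_equal(env_back$base_cation, d1$env$base_cation, tolerance = 1e-12)
})

test_that("scenario richness gradients have the designed directions", {
  fern <- generate_dataset("fern_like", 42)
  palm <- generate_dataset("palm_like", 42)
  reg <- function(ds) {
    a <- data.frame(site = rownames(ds$community),
                    S = as.numeric(rowSums(ds$community)))
    fit_gradient_models(a, ds$env, metrics = "S")
  }
  rf <- reg(fern); rp <- reg(palm)
  expect_gt(rf$linear_slope, 0)
  expect_true(rf$linear_significant)
  expect_lt(rp$linear_slope, 0)
  expect_true(rp$linear_significant)

  # neutral scenario: no systematic richness trend across seeds
  flat <- vapply(1:50, function(s) {
    ds <- generate_dataset("neutral", s)
    reg(ds)$linear_p
  }, numeric(1L))
  expect_gte(mean(flat > 0.05), 0.9)
})
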