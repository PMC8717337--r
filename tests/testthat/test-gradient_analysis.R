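test_that("pcoa reproduces Gower-centering arithmetic on 3 sites", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  ord <- pcoa_ord(d, k = 2L)
  expect_equal(sum(ord$eigenvalues), (9 + 16 + 25) / 3, tolerance = 1e-10)
  expect_equal(sum(ord$eigenvalues > 1e-8), 2L)
  expect_equal(unname(colMeans(ord$scores)), c(0, 0), tolerance = 1e-10)
  # embedded distances reproduce the input (3,4,5 is Euclidean-realizable)
  emb <- as.matrix(dist(ord$scores))
  expect_equal(unname(emb), unname(d), tolerance = 1e-8)
})

test_that("pcoa recovers collinear and planar configurations", {
  x <- c(0, 1, 2, 5, 9)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:5), paste0("s", 1:5))
  ord <- suppressWarnings(pcoa_ord(d, k = 2L))
  expect_equal(ord$k, 1L)
  recovered <- ord$scores[, 1L]
  expect_equal(sort(as.vector(dist(recovered))), sort(as.vector(dist(x))),
               tolerance = 1e-8)
  expect_lt(max(abs(ord$eigenvalues[-1L])), 1e-8)

  # 2-D configuration up to rotation/reflection (Procrustes residual)
  set.seed(55)
  pts <- matrix(rnorm(20), 10, 2)
  d2 <- as.matrix(dist(pts))
  dimnames(d2) <- list(paste0("p", 1:10), paste0("p", 1:10))
  ord2 <- pcoa_ord(d2, k = 2L)
  a <- scale(pts, scale = FALSE)
  b <- scale(ord2$scores, scale = FALSE)
  sv <- svd(crossprod(a, b))
  resid <- sum((b %*% sv$v %*% t(sv$u) - a)^2)
  expect_lt(resid, 1e-8)

  # duplicated sites get identical scores
  d3 <- as.matrix(dist(c(0, 0, 1, 3)))
  dimnames(d3) <- list(paste0("q", 1:4), paste0("q", 1:4))
  ord3 <- suppressWarnings(pcoa_ord(d3, k = 1L))
  expect_equal(ord3$scores["q1", 1L], ord3$scores["q2", 1L], tolerance = 1e-10)
})

test_that("axis orientation is deterministic and eigenvalue sum equals the trace", {
  set.seed(65)
  tree <- random_tree(12)
  comm <- random_community(tree, 8, fill = 0.6)
  comm[rowSums(comm) == 0, 1L] <- 1
  d <- sorensen_matrix(comm)
  ord <- pcoa_ord(d, k = 2L)
  for (j in 1:2) {
    expect_gt(ord$scores[which.max(abs(ord$scores[, j])), j], 0)
  }
  n <- nrow(d)
  C <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * C %*% unclass(d)^2 %*% C
  expect_equal(sum(ord$eigenvalues), sum(diag(B)), tolerance = 1e-10)
})

test_that("environmental arrows are axis correlations bounded by 1", {
  set.seed(75)
  pts <- matrix(rnorm(40), 20, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("T%02d", 1:20), sprintf("T%02d", 1:20))
  ord <- pcoa_ord(d, k = 2L)
  env <- data.frame(site = rownames(ord$scores),
                    base_cation = 10^ord$scores[, 1L],   # log10 == axis 1
                    neg_ax2 = -ord$scores[, 2L],
                    flat = 1)
  arr <- envfit_axes(ord, env, variables = c(base_cation = "log10",
                                             neg_ax2 = "identity"))
  expect_equal(arr$r1[arr$variable == "base_cation"], 1, tolerance = 1e-10)
  expect_equal(abs(arr$r2[arr$variable == "base_cation"]), 0, tolerance = 1e-8)
  expect_equal(arr$r2[arr$variable == "neg_ax2"], -1, tolerance = 1e-10)
  expect_true(all(abs(arr[, c("r1", "r2")]) <= 1 + 1e-12))

  expect_message(arr2 <- envfit_axes(ord, env, variables = c(flat = "identity")),
                 "zero-variance")
  expect_true(is.na(arr2$r1))
})

test_that("gradient regressions recover exact and noisy linear/quadratic fits", {
  env <- data.frame(site = sprintf("T%02d", 1:12),
                    base_cation = 10^seq(-1, 1, length.out = 12))
  x <- log10(env$base_cation)
  exact <- data.frame(site = env$site, lin = 2 * x + 1, quad = x^2)
  # exact data: lm warns that the fit is perfect, which is the point here
  fits <- suppressWarnings(fit_gradient_models(exact, env))
  lin <- fits[fits$metric == "lin", ]
  expect_equal(lin$linear_slope, 2, tolerance = 1e-10)
  expect_equal(lin$linear_intercept, 1, tolerance = 1e-10)
  expect_equal(lin$linear_adj_r2, 1, tolerance = 1e-8)
  qd <- fits[fits$metric == "quad", ]
  expect_equal(qd$quad_b2, 1, tolerance = 1e-8)
  expect_equal(qd$quad_b1, 0, tolerance = 1e-8)
  expect_equal(qd$linear_slope, 0, tolerance = 1e-8)  # symmetric x

  # noisy data against closed-form normal equations
  set.seed(85)
  y <- 3 * x - 0.5 + rnorm(12, 0, 0.3)
  noisy <- data.frame(site = env$site, y = y)
  f2 <- fit_gradient_models(noisy, env)
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(f2$linear_intercept, beta[1L], tolerance = 1e-10)
  expect_equal(f2$linear_slope, beta[2L], tolerance = 1e-10)
  Xq <- cbind(1, x, x^2)
  bq <- solve(crossprod(Xq), crossprod(Xq, y))
  expect_equal(c(f2$quad_b0, f2$quad_b1, f2$quad_b2), as.vector(bq),
               tolerance = 1e-8)
  expect_gte(f2$quad_r2, f2$linear_r2)

  # site-order invariance and missing handling
  shuf <- noisy[sample(nrow(noisy)), ]
  f3 <- fit_gradient_models(shuf, env)
  expect_equal(f3$linear_slope, f2$linear_slope, tolerance = 1e-12)
  noisy$y[1:9] <- NA
  expect_message(f4 <- fit_gradient_models(noisy, env), "fewer than 4")
  expect_null(f4)
})
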