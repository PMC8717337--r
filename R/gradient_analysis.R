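#' Principal Coordinates Analysis of a dissimilarity matrix
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition.
#' Scores are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; axes are ordered by decreasing eigenvalue. Negative
#' eigenvalues (possible for non-Euclidean dissimilarities such as Sorensen)
#' are reported, not corrected, so their magnitude can be judged. Each axis is
#' deterministically oriented so that its largest-magnitude score is positive.
#'
#' @param d a `beta_matrix` or symmetric dissimilarity matrix with site ids as
#'   dimnames (no missing values).
#' @param k number of axes to return (default 2); truncated with a warning if
#'   it exceeds the number of positive eigenvalues.
#' @return an object of class `pcoa_ord`: list with `scores` (sites x k,
#'   column-centered), `eigenvalues` (all n), `relative_eigenvalues`
#'   (proportion of the positive eigenvalue mass), `k`.
#' @export
pcoa_ord <- function(d, k = 2L) {
  d <- as.matrix(d)
  if (anyNA(d)) stop("dissimilarity matrix contains missing values")
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12)) {
    stop("dissimilarity matrix must be square and symmetric")
  }
  n <- nrow(d)
  C <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * C %*% (d^2) %*% C
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  ev <- eig$values
  pos <- which(ev > max(ev[1L], 0) * 1e-10)
  n_pos <- length(pos)
  if (k > n_pos) {
    warning("only ", n_pos, " positive eigenvalue(s); returning ", n_pos, " axes")
    k <- n_pos
  }
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k, k)
  for (j in seq_len(k)) {
    if (scores[which.max(abs(scores[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(d), paste0("axis", seq_len(k)))
  structure(list(scores = scores, eigenvalues = ev,
                 relative_eigenvalues = ev / sum(ev[ev > 0]), k = k),
            class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat("pcoa_ord:", nrow(x$scores), "sites,", x$k, "axes; relative eigenvalues:",
      paste(sprintf("%.3f", x$relative_eigenvalues[seq_len(x$k)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Environmental arrows for a PCoA ordination
#'
#' Pearson correlation of each (optionally transformed) environmental
#' variable with the first two ordination axes; the pair `(r1, r2)` is the
#' arrow plotted in ordination diagrams. Zero-variance variables get a
#' missing arrow with a message.
#'
#' @param ord a `pcoa_ord` with at least 2 axes.
#' @param env environment data.frame covering every ordinated site.
#' @param variables named character vector: names are `env` columns, values
#'   are transforms (`"log10"`, `"log"`, or `"identity"`). Default: log10
#'   base-cation plus any of phosphorus (log10), aluminum, pH present.
#' @return data.frame: variable, transform, r1, r2.
#' @export
envfit_axes <- function(ord, env, variables = NULL) {
  if (!inherits(ord, "pcoa_ord") || ord$k < 2L) {
    stop("need a pcoa_ord with at least 2 axes")
  }
  sites <- rownames(ord$scores)
  if (!all(sites %in% env$site)) {
    stop("environment table does not cover all ordinated sites")
  }
  if (is.null(variables)) {
    variables <- c(base_cation = "log10")
    if ("phosphorus" %in% names(env)) variables["phosphorus"] <- "log10"
    if ("aluminum" %in% names(env)) variables["aluminum"] <- "identity"
    if ("pH" %in% names(env)) variables["pH"] <- "identity"
  }
  ev <- env[match(sites, env$site), , drop = FALSE]
  rows <- lapply(names(variables), function(v) {
    if (!v %in% names(ev)) stop("variable not in environment table: ", v)
    x <- switch(variables[[v]],
                log10 = log10(ev[[v]]), log = log(ev[[v]]),
                identity = ev[[v]],
                stop("unknown transform: ", variables[[v]]))
    if (sd(x) == 0) {
      message("zero-variance variable, arrow omitted: ", v)
      return(data.frame(variable = v, transform = variables[[v]],
                        r1 = NA_real_, r2 = NA_real_))
    }
    data.frame(variable = v, transform = variables[[v]],
               r1 = cor(x, ord$scores[, 1L]), r2 = cor(x, ord$scores[, 2L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear and quadratic regressions of community metrics on the soil gradient
#'
#' For each metric column, ordinary least squares of `y = b0 + b1 x` and
#' `y = b0 + b1 x + b2 x^2` with `x = log10(base_cation)` by default. The
#' quadratic is fit on centered x for conditioning and the coefficients are
#' reported in the raw polynomial basis. Model p-values come from the F-test
#' against the intercept-only model (set `p_from = "t"` for the
#' highest-order-coefficient t-test). Both fits are always reported;
#' `*_significant` flags use p < 0.05. Sites with a missing metric are
#' dropped (with a message); metrics with fewer than 4 complete sites are
#' skipped.
#'
#' @param metrics_df data.frame with a `site` column and one column per
#'   metric (e.g. from [alpha_over_trees()] or a reshaped SES table).
#' @param env environment data.frame with `site` and `base_cation`.
#' @param metrics metric column names to fit (default: all numeric columns).
#' @param predictor `"log10"` (default) or `"raw"` base-cation scale.
#' @param p_from `"F"` (default) or `"t"`.
#' @return data.frame, one row per metric: n, linear_slope, linear_intercept,
#'   linear_r2, linear_adj_r2, linear_p, linear_significant, quad_b0, quad_b1,
#'   quad_b2, quad_r2, quad_adj_r2, quad_p, quad_significant.
#' @export
fit_gradient_models <- function(metrics_df, env, metrics = NULL,
                                predictor = c("log10", "raw"),
                                p_from = c("F", "t")) {
  predictor <- match.arg(predictor)
  p_from <- match.arg(p_from)
  if (!"site" %in% names(metrics_df)) stop("metrics_df needs a 'site' column")
  if (is.null(metrics)) {
    metrics <- setdiff(names(metrics_df)[vapply(metrics_df, is.numeric, logical(1L))],
                       "site")
  }
  bc <- env$base_cation[match(metrics_df$site, env$site)]
  if (anyNA(bc)) stop("environment table missing site(s): ",
                      paste(metrics_df$site[is.na(bc)], collapse = ", "))
  x <- if (predictor == "log10") log10(bc) else bc

  rows <- lapply(metrics, function(mname) {
    y <- metrics_df[[mname]]
    ok <- is.finite(y) & is.finite(x)
    if (sum(!ok)) message(mname, ": dropping ", sum(!ok), " site(s) with missing values")
    if (sum(ok) < 4L) {
      message(mname, ": fewer than 4 complete sites, skipped")
      return(NULL)
    }
    xi <- x[ok]; yi <- y[ok]; n <- length(yi)
    lin <- lm(yi ~ xi)
    xc <- xi - mean(xi)
    quad <- lm(yi ~ xc + I(xc^2))
    # back-transform centered-basis coefficients to the raw polynomial
    cb <- coef(quad); m <- mean(xi)
    b2 <- cb[[3L]]; b1 <- cb[[2L]] - 2 * b2 * m
    b0 <- cb[[1L]] - cb[[2L]] * m + b2 * m^2
    model_p <- function(fit) {
      fs <- summary(fit)$fstatistic
      if (is.null(fs)) return(NA_real_)
      unname(pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
    }
    tail_p <- function(fit) {
      ct <- summary(fit)$coefficients
      ct[nrow(ct), 4L]
    }
    pick_p <- if (p_from == "F") model_p else tail_p
    lin_s <- summary(lin); quad_s <- summary(quad)
    data.frame(metric = mname, n = n, predictor = predictor,
               linear_slope = coef(lin)[[2L]],
               linear_intercept = coef(lin)[[1L]],
               linear_r2 = lin_s$r.squared,
               linear_adj_r2 = lin_s$adj.r.squared,
               linear_p = pick_p(lin),
               quad_b0 = b0, quad_b1 = b1, quad_b2 = b2,
               quad_r2 = quad_s$r.squared,
               quad_adj_r2 = quad_s$adj.r.squared,
               quad_p = pick_p(quad),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) return(NULL)
  out$linear_significant <- out$linear_p < 0.05
  out$quad_significant <- out$quad_p < 0.05
  rownames(out) <- NULL
  out
}
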