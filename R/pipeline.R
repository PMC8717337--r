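# Recognized run-configuration keys and their defaults. The configuration is
# strict: unknown keys are rejected by name.
.config_defaults <- function() {
  list(
    scenario = NULL, seed = NULL,
    trees = NULL, community = NULL, environment = NULL,
    n_tips = 60L, n_trees = 10L, cv = 0.1,
    metrics = c("PD", "MPD", "MNTD"),
    n_null_per_tree = 99L, n_shuffle_per_tree = 10L,
    swap_successes = 1000L, swap_attempts_factor = 100L,
    summary = "median", beta_summary = "median",
    predictor = "log10", p_from = "F",
    paper_scale = FALSE,
    stages = c("alpha", "ses", "beta", "ordinate", "regress")
  )
}

#' Build and validate a pipeline run configuration
#'
#' Exactly one input mode must be configured: a synthetic `scenario` (with
#' `seed`), or the three input paths `trees` / `community` / `environment`.
#' Unknown keys are rejected by name. `paper_scale = TRUE` switches the
#' null-model effort to the study-scale settings (999 nulls per tree for the
#' alpha SES metrics; 100 trees when simulating) instead of the scaled-down
#' interactive defaults (99 nulls, 10 trees).
#'
#' @param ... configuration entries, or a single list of them.
#' @return a validated configuration list of class `run_config`.
#' @export
run_config <- function(...) {
  supplied <- list(...)
  if (length(supplied) == 1L && is.null(names(supplied)) &&
      is.list(supplied[[1L]])) {
    supplied <- supplied[[1L]]
  }
  defaults <- .config_defaults()
  unknown <- setdiff(names(supplied), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, supplied, keep.null = TRUE)
  from_files <- !is.null(cfg$trees) || !is.null(cfg$community) ||
    !is.null(cfg$environment)
  if (is.null(cfg$scenario) == !from_files) {
    stop("configure exactly one of: scenario, or trees/community/environment paths")
  }
  if (from_files &&
      (is.null(cfg$trees) || is.null(cfg$community) || is.null(cfg$environment))) {
    stop("file mode needs all of trees, community, environment")
  }
  if (isTRUE(cfg$paper_scale)) {
    cfg$n_null_per_tree <- 999L
    if (!is.null(cfg$scenario)) cfg$n_trees <- 100L
  }
  bad <- setdiff(cfg$stages, c("alpha", "ses", "beta", "ordinate", "regress"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' @param path configuration file (`.yml`/`.yaml` or `.json`).
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  run_config(cfg)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

.write_matrix_csv <- function(m, path) {
  df <- data.frame(site = rownames(m), as.matrix(m), check.names = FALSE)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  path
}

#' Run the community-phylogenetics pipeline end to end
#'
#' Loads or simulates the aligned dataset, then runs the configured stages:
#' `alpha` (per-site metrics, cross-tree summarized), `ses` (SES.PD/MPD/MNTD
#' under the independent-swap null and SES.PhyloSor under the tip-shuffle
#' null, plus the stratified summary), `beta` (Sorensen and cross-tree
#' PhyloSor matrices), `ordinate` (PCoA of both beta matrices with
#' environmental arrows), `regress` (linear + quadratic gradient models of S,
#' VPD and the SES metrics). Each stage writes its tables into `output_dir`
#' and appends one JSON line to `log.jsonl` recording the seed, effort
#' counters (null communities per tree, pooled nulls per pair) and timing.
#' Identical configuration and seed produce identical outputs.
#'
#' @param config a `run_config`, a plain list of config entries, or a path to
#'   a YAML/JSON config file.
#' @param output_dir run directory (created if absent).
#' @return invisibly, a list with the output `paths`, the parsed `log`, and
#'   the in-memory stage results.
#' @export
run_pipeline <- function(config, output_dir) {
  cfg <- if (inherits(config, "run_config")) config
         else if (is.character(config)) read_config(config)
         else run_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(output_dir, "log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  log_entries <- list()
  paths <- list()
  results <- list()
  log_stage <- function(stage, extra = list()) {
    entry <- c(list(stage = stage, seed = cfg$seed,
                    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA, null = "null"),
        "\n", file = log_path, append = TRUE, sep = "")
    log_entries[[length(log_entries) + 1L]] <<- entry
  }

  stage_seeds <- derive_seeds(cfg$seed, 4L)

  # ---- input stage: simulate or load, then align -------------------------
  t0 <- proc.time()[[3L]]
  if (!is.null(cfg$scenario)) {
    ds <- generate_dataset(cfg$scenario, cfg$seed, n_tips = cfg$n_tips,
                           n_trees = cfg$n_trees, cv = cfg$cv)
    community <- ds$community; env <- ds$env; trees <- ds$trees
    paths$dataset <- write_dataset(ds, file.path(output_dir, "dataset"))
    results$dataset <- ds
  } else {
    trees <- read_newick(cfg$trees)
    community <- read_community(cfg$community)
    env <- read_environment(cfg$environment)
  }
  aligned <- align_dataset(community, env, trees)
  results$aligned <- aligned
  log_stage("input", list(
    n_sites = nrow(aligned$community), n_taxa = ncol(aligned$community),
    n_trees = length(aligned$trees),
    scenario = if (is.null(cfg$scenario)) NA else cfg$scenario,
    elapsed_s = round(proc.time()[[3L]] - t0, 3)))

  comm <- aligned$community; env <- aligned$env; trees <- aligned$trees

  if ("alpha" %in% cfg$stages) {
    t0 <- proc.time()[[3L]]
    alpha <- alpha_over_trees(comm, trees, summary = cfg$summary)
    results$alpha <- alpha
    paths$alpha <- .write_tsv(alpha, file.path(output_dir, "alpha.tsv"))
    log_stage("alpha", list(n_trees = length(trees),
                            summary = cfg$summary,
                            elapsed_s = round(proc.time()[[3L]] - t0, 3)))
  }

  if ("ses" %in% cfg$stages) {
    t0 <- proc.time()[[3L]]
    cfg_a <- null_config(model = "independent_swap",
                         n_null_per_tree = cfg$n_null_per_tree,
                         swap_successes = cfg$swap_successes,
                         swap_attempts_factor = cfg$swap_attempts_factor,
                         seed = stage_seeds[[1L]], summary = cfg$summary)
    sa <- ses_alpha(comm, trees, metrics = cfg$metrics, config = cfg_a)
    results$ses_alpha <- sa
    paths$ses_alpha <- .write_tsv(sa$summary, file.path(output_dir, "ses_alpha.tsv"))
    log_stage("ses_alpha", c(sa$effort,
                             list(elapsed_s = round(proc.time()[[3L]] - t0, 3))))

    t0 <- proc.time()[[3L]]
    cfg_b <- null_config(model = "tip_shuffle",
                         n_null_per_tree = cfg$n_shuffle_per_tree,
                         seed = stage_seeds[[2L]], summary = cfg$beta_summary)
    sb <- ses_phylosor(comm, trees, env = env, config = cfg_b)
    results$ses_beta <- sb
    paths$ses_beta <- .write_tsv(sb$pairs, file.path(output_dir, "ses_phylosor.tsv"))
    strat <- summarize_ses_by_stratum(sb)
    paths$stratum_summary <- .write_tsv(strat,
                                        file.path(output_dir, "ses_phylosor_by_stratum.tsv"))
    results$stratum_summary <- strat
    log_stage("ses_beta", c(sb$effort,
                            list(elapsed_s = round(proc.time()[[3L]] - t0, 3))))
  }

  if ("beta" %in% cfg$stages || "ordinate" %in% cfg$stages) {
    t0 <- proc.time()[[3L]]
    sor <- sorensen_matrix(comm)
    phy <- beta_over_trees(comm, trees, metric = "phylosor",
                           summary = cfg$beta_summary)
    results$sorensen <- sor; results$phylosor <- phy
    paths$sorensen <- .write_matrix_csv(sor, file.path(output_dir, "sorensen.csv"))
    paths$phylosor <- .write_matrix_csv(phy, file.path(output_dir, "phylosor.csv"))
    log_stage("beta", list(n_trees = length(trees),
                           beta_summary = cfg$beta_summary,
                           elapsed_s = round(proc.time()[[3L]] - t0, 3)))
  }

  if ("ordinate" %in% cfg$stages) {
    t0 <- proc.time()[[3L]]
    for (nm in c("sorensen", "phylosor")) {
      b <- results[[nm]]
      keep <- rowSums(is.na(as.matrix(b))) < nrow(b) - 1L
      b2 <- as.matrix(b)[keep, keep, drop = FALSE]
      if (anyNA(b2)) {
        ok <- stats::complete.cases(b2)
        b2 <- b2[ok, ok, drop = FALSE]
      }
      ord <- pcoa_ord(b2, k = 2L)
      arrows <- envfit_axes(ord, env)
      results[[paste0("pcoa_", nm)]] <- ord
      paths[[paste0("pcoa_", nm)]] <- .write_tsv(
        data.frame(site = rownames(ord$scores), ord$scores,
                   stringsAsFactors = FALSE),
        file.path(output_dir, paste0("pcoa_", nm, "_scores.tsv")))
      paths[[paste0("arrows_", nm)]] <- .write_tsv(
        arrows, file.path(output_dir, paste0("pcoa_", nm, "_arrows.tsv")))
    }
    log_stage("ordinate", list(elapsed_s = round(proc.time()[[3L]] - t0, 3)))
  }

  if ("regress" %in% cfg$stages) {
    t0 <- proc.time()[[3L]]
    if (is.null(results$alpha)) {
      results$alpha <- alpha_over_trees(comm, trees, summary = cfg$summary)
    }
    mdf <- results$alpha[, c("site", "S", "VPD")]
    if (!is.null(results$ses_alpha)) {
      for (m in unique(results$ses_alpha$summary$metric)) {
        sub <- results$ses_alpha$summary
        sub <- sub[sub$metric == m, c("site", "ses")]
        names(sub)[2L] <- paste0("SES.", m)
        mdf <- merge(mdf, sub, by = "site", sort = TRUE)
      }
    }
    reg <- fit_gradient_models(mdf, env, predictor = cfg$predictor,
                               p_from = cfg$p_from)
    results$regressions <- reg
    paths$regressions <- .write_tsv(reg, file.path(output_dir, "regressions.tsv"))
    log_stage("regress", list(predictor = cfg$predictor,
                              n_metrics = nrow(reg),
                              elapsed_s = round(proc.time()[[3L]] - t0, 3)))
  }

  invisible(list(paths = paths, log = log_entries, results = results,
                 config = cfg, output_dir = output_dir))
}

#' Read a pipeline run log
#'
#' @param output_dir a pipeline run directory (or a path to `log.jsonl`).
#' @return list of per-stage log entries.
#' @export
read_run_log <- function(output_dir) {
  path <- if (dir.exists(output_dir)) file.path(output_dir, "log.jsonl")
          else output_dir
  lapply(readLines(path), function(l) jsonlite::fromJSON(l))
}
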