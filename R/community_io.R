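#' Validate a binary site x species community matrix
#'
#' @param x a numeric matrix with site ids as rownames and taxon labels as
#'   colnames; entries must be 0/1.
#' @return `x`, invisibly.
#' @export
validate_community <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("community must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("community matrix needs site rownames and taxon colnames")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate site ids")
  if (anyDuplicated(colnames(x))) stop("duplicate taxon labels")
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop("community entries must be 0/1 (use coerce = TRUE to binarize counts)")
  }
  invisible(x)
}

#' Read a site x species presence-absence matrix from CSV/TSV
#'
#' Expects sites as rows (first column = site id) and taxa as columns; set
#' `sites_in = "cols"` for the transpose. Positive counts are coerced to 1
#' only when `coerce = TRUE` (with a warning); otherwise non-binary values are
#' an error.
#'
#' @param path CSV file path.
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @param sites_in `"rows"` (default) or `"cols"`.
#' @param coerce binarize positive counts with a warning? Default `FALSE`.
#' @return a binary matrix (sites x taxa).
#' @export
read_community <- function(path, sep = ",", sites_in = c("rows", "cols"),
                           coerce = FALSE) {
  sites_in <- match.arg(sites_in)
  df <- read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- trimws(as.character(df[[1L]]))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric occurrence cell(s) in ", path)
  rownames(m) <- ids
  colnames(m) <- trimws(colnames(m))
  if (sites_in == "cols") m <- t(m)
  if (anyNA(m)) stop("missing occurrence value(s) in ", path)
  if (any(m < 0)) stop("negative occurrence value(s) in ", path)
  if (any(m > 1)) {
    if (!coerce) stop("non-binary counts found; pass coerce = TRUE to binarize")
    warning(sum(m > 1), " count cell(s) > 1 coerced to presence")
    m[m > 1] <- 1
  }
  validate_community(m)
  m
}

#' Write a community matrix to CSV
#' @param x binary community matrix.
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_community <- function(x, path, sep = ",") {
  df <- data.frame(site = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.formation_levels <- c("Solimoes", "Ica", "Terrace")

normalize_formation <- function(x) {
  key <- tolower(trimws(as.character(x)))
  # tolerate the accented spellings and regional synonyms
  key <- chartr("çãõéí", "caoei", key)
  map <- c(solimoes = "Solimoes", pebas = "Solimoes",
           ica = "Ica", nauta = "Ica",
           terrace = "Terrace", terraces = "Terrace")
  out <- unname(map[key])
  if (anyNA(out)) {
    stop("unknown formation label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected Solimoes / Ica / Terrace)")
  }
  factor(out, levels = .formation_levels)
}

#' Read the site environment table
#'
#' Requires columns `site`, `base_cation` (sum of exchangeable Ca + K + Mg +
#' Na, cmol(+)/kg, strictly positive so a log transform is defined) and
#' `formation` (Solimoes / Ica / Terrace, matched case-insensitively, accents
#' tolerated). Optional columns `phosphorus` (mg/kg), `aluminum` (cmol(+)/kg)
#' and `pH` are carried through when present.
#'
#' @param path CSV file path.
#' @param sep field delimiter.
#' @return a data.frame with one row per site.
#' @export
read_environment <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- trimws(names(df))
  need <- c("site", "base_cation", "formation")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("environment table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$site <- trimws(as.character(df$site))
  if (anyDuplicated(df$site)) stop("duplicate site id(s) in environment table")
  df$base_cation <- as.numeric(df$base_cation)
  bad <- is.na(df$base_cation) | df$base_cation <= 0
  if (any(bad)) {
    stop("non-positive or missing base_cation at site(s): ",
         paste(df$site[bad], collapse = ", "))
  }
  df$formation <- normalize_formation(df$formation)
  keep <- intersect(c("site", "base_cation", "formation",
                      "phosphorus", "aluminum", "pH"), names(df))
  df[, keep, drop = FALSE]
}

#' Merge taxa into a single terminal
#'
#' Pre-processing utility for taxa that cannot be distinguished in the field:
#' the named columns are OR-combined into one presence column labelled
#' `new_label`.
#'
#' @param community binary community matrix.
#' @param taxa labels of the columns to merge (>= 2).
#' @param new_label label of the merged column (default: first of `taxa`).
#' @return the community matrix with the merged column.
#' @export
merge_taxa <- function(community, taxa, new_label = taxa[1L]) {
  validate_community(community)
  taxa <- as.character(taxa)
  if (length(taxa) < 2L) stop("need at least 2 taxa to merge")
  unknown <- setdiff(taxa, colnames(community))
  if (length(unknown)) stop("taxa not in matrix: ", paste(unknown, collapse = ", "))
  merged <- as.numeric(rowSums(community[, taxa, drop = FALSE]) > 0)
  out <- community[, setdiff(colnames(community), taxa), drop = FALSE]
  out <- cbind(out, merged)
  colnames(out)[ncol(out)] <- new_label
  out
}

#' Align community, environment and trees to a common site and taxon set
#'
#' Restricts sites to the intersection of community and environment ids,
#' restricts taxa to the trees' tip set (or errors, per `on_missing_taxa`),
#' prunes the trees to the matrix taxa, optionally drops taxa observed at no
#' site, and fixes site and taxon orders so every downstream output is
#' consistently ordered. Idempotent.
#'
#' @param community binary site x species matrix.
#' @param env environment data.frame as from [read_environment()].
#' @param trees a `tree_sample` (or coercible).
#' @param drop_empty_taxa drop taxa with zero occurrences? Default `TRUE`.
#' @param on_missing_taxa what to do with matrix taxa absent from the trees:
#'   `"drop"` (report and drop) or `"error"`.
#' @return a list of class `aligned_dataset` with elements `community`, `env`,
#'   `trees`.
#' @export
align_dataset <- function(community, env, trees, drop_empty_taxa = TRUE,
                          on_missing_taxa = c("drop", "error")) {
  on_missing_taxa <- match.arg(on_missing_taxa)
  validate_community(community)
  trees <- as_tree_sample(trees)

  sites <- intersect(rownames(community), env$site)
  if (length(sites) == 0L) stop("no common sites between community and environment")
  lost_c <- setdiff(rownames(community), sites)
  lost_e <- setdiff(env$site, sites)
  if (length(lost_c)) message("dropping ", length(lost_c),
                              " community site(s) without environment: ",
                              paste(lost_c, collapse = ", "))
  if (length(lost_e)) message("dropping ", length(lost_e),
                              " environment site(s) without community data")

  tips <- trees[[1L]]$tip.label
  absent <- setdiff(colnames(community), tips)
  if (length(absent)) {
    if (on_missing_taxa == "error") {
      stop("taxa absent from trees: ", paste(absent, collapse = ", "))
    }
    message("dropping ", length(absent), " taxa absent from trees: ",
            paste(absent, collapse = ", "))
  }
  taxa <- intersect(colnames(community), tips)
  comm <- community[sites, taxa, drop = FALSE]
  if (drop_empty_taxa) {
    taxa <- taxa[colSums(comm) > 0]
    comm <- comm[, taxa, drop = FALSE]
  }
  if (length(taxa) < 2L) stop("fewer than 2 taxa remain after alignment")
  taxa <- sort(taxa)
  sites <- sort(sites)
  comm <- comm[sites, taxa, drop = FALSE]
  trees <- as_tree_sample(lapply(unclass(trees), prune_to, taxa = taxa))
  env <- env[match(sites, env$site), , drop = FALSE]
  rownames(env) <- NULL
  structure(list(community = comm, env = env, trees = trees),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("aligned_dataset:", nrow(x$community), "sites,",
      ncol(x$community), "taxa,", length(x$trees), "tree(s)\n")
  invisible(x)
}
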