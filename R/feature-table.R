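# Feature-table container and TSV IO.
#
# A feature_table is a samples x features numeric matrix with a `unit`
# attribute ("counts" or "relabund"). Matrices are the field's convention for
# abundance data (vegan, phyloseq); everything tabular around them is a
# tibble.

#' Construct a validated feature table
#'
#' @param values Numeric matrix, samples in rows, features in columns, with
#'   unique row and column names.
#' @param unit Either `"counts"` (non-negative integers or reals) or
#'   `"relabund"` (each sample row sums to 1).
#' @return A `feature_table`: the matrix with a `unit` attribute.
#' @export
feature_table <- function(values, unit = c("counts", "relabund")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_pb("`values` must be a numeric matrix (samples x features)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_pb("feature table needs sample (row) and feature (column) names")
  }
  dup_s <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_s)) {
    stop_pb("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "))
  }
  dup_f <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_f)) {
    stop_pb("duplicated feature id(s): ", paste(unique(dup_f), collapse = ", "))
  }
  if (anyNA(values)) stop_pb("feature table contains missing values")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop_pb("negative abundance at sample '", rownames(values)[bad[1]],
            "', feature '", colnames(values)[bad[2]], "'")
  }
  if (unit == "relabund") {
    rs <- rowSums(values)
    if (any(abs(rs - 1) > 1e-9)) {
      stop_pb("relative-abundance rows must sum to 1 (worst deviation ",
              format(max(abs(rs - 1))), ")")
    }
  }
  structure(values, unit = unit, class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x), " samples x ", ncol(x), " features (",
      attr(x, "unit"), ")\n", sep = "")
  invisible(x)
}

ft_unit <- function(x) attr(x, "unit")

#' Convert counts to relative abundances
#'
#' @param table A `feature_table`.
#' @return A `feature_table` with unit `"relabund"`.
#' @export
to_relabund <- function(table) {
  if (ft_unit(table) == "relabund") return(table)
  tot <- rowSums(table)
  if (any(tot == 0)) {
    stop_pb("cannot convert zero-total sample(s) to relative abundance: ",
            paste(rownames(table)[tot == 0], collapse = ", "))
  }
  feature_table(unclass(table) / tot, unit = "relabund")
}

#' Read a feature table from TSV
#'
#' The on-disk orientation must be stated explicitly: silent transposition is
#' the classic microbiome bug, so no auto-detection is attempted.
#'
#' @param path TSV file; first column holds row identifiers.
#' @param dialect `"samples_rows"` if rows are samples, `"features_rows"` if
#'   rows are features (the table is transposed on read).
#' @param unit Passed to [feature_table()].
#' @return A `feature_table`, samples x features.
#' @export
read_feature_table <- function(path, dialect = c("samples_rows", "features_rows"),
                               unit = c("counts", "relabund")) {
  dialect <- match.arg(dialect)
  unit <- match.arg(unit)
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 2) stop_pb("feature table needs an id column plus data")
  ids <- df[[1]]
  body <- as.matrix(df[-1])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop_pb("non-numeric cell at row ", bad[1], " ('", ids[bad[1]],
            "'), column '", colnames(body)[bad[2]], "'")
  }
  rownames(num) <- ids
  colnames(num) <- colnames(body)
  if (dialect == "features_rows") num <- t(num)
  feature_table(num, unit = unit)
}

#' Write a feature table to TSV
#'
#' @param table A `feature_table`.
#' @param path Output path.
#' @param id_column Name for the identifier column (default `"sample_id"`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, id_column = "sample_id") {
  df <- tibble::as_tibble(unclass(table), rownames = id_column)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Tidy a feature table into long form
#'
#' @param x A `feature_table`.
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `feature_id`, `value`, `unit`.
#' @export
tidy.feature_table <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "feature_id",
                        values_to = "value") |>
    dplyr::mutate(unit = ft_unit(x))
}

#' Read a feature taxonomy map
#'
#' @param path TSV with columns `feature_id` and `lineage`
#'   (semicolon-separated ranked strings, Greengenes-style prefixes
#'   `k__;p__;...;g__;s__`, possibly truncated).
#' @return Tibble with columns `feature_id`, `lineage`, `genus`, `family`.
#'   `genus` falls back to `g__unclassified.<family>` when no genus rank is
#'   present.
#' @export
read_taxonomy <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (!all(c("feature_id", "lineage") %in% names(df))) {
    stop_pb("taxonomy TSV needs `feature_id` and `lineage` columns")
  }
  parse_taxonomy(df$feature_id, df$lineage)
}

#' Build a taxonomy map from lineage strings
#'
#' @param feature_id Character vector of feature identifiers.
#' @param lineage Matching lineage strings.
#' @return Tibble with columns `feature_id`, `lineage`, `genus`, `family`.
#' @export
parse_taxonomy <- function(feature_id, lineage) {
  if (length(feature_id) == 0) stop_pb("empty taxonomy")
  if (anyDuplicated(feature_id)) stop_pb("duplicated feature_id in taxonomy")
  if (any(!nzchar(lineage) | is.na(lineage))) stop_pb("empty lineage string")
  get_rank <- function(lin, prefix) {
    parts <- strsplit(lin, ";", fixed = TRUE)
    vapply(parts, function(p) {
      p <- trimws(p)
      hit <- p[startsWith(p, prefix)]
      val <- if (length(hit)) sub(prefix, "", hit[1]) else ""
      if (nzchar(val)) val else NA_character_
    }, character(1))
  }
  genus <- get_rank(lineage, "g__")
  family <- get_rank(lineage, "f__")
  genus_label <- ifelse(
    is.na(genus),
    paste0("g__unclassified.", ifelse(is.na(family), "unknown", family)),
    paste0("g__", genus)
  )
  tibble::tibble(feature_id = feature_id, lineage = lineage,
                 genus = genus_label,
                 family = ifelse(is.na(family), NA_character_, family))
}

#' Read a rooted phylogenetic tree from Newick
#'
#' @param path Newick file. Branch lengths are required and must be
#'   non-negative and finite.
#' @param feature_ids Optional character vector; leaves absent from it are
#'   reported via a message (they are pruned downstream, not an error).
#' @return An [ape::read.tree()] `phylo` object, rooted.
#' @export
read_tree <- function(path, feature_ids = NULL) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop_pb("unparsable Newick in '", path,
                                               "': ", conditionMessage(e)))
  if (is.null(tree)) stop_pb("unparsable Newick in '", path, "'")
  validate_tree(tree)
  if (!is.null(feature_ids)) {
    extra <- setdiff(tree$tip.label, feature_ids)
    if (length(extra)) {
      message(length(extra), " tree leaf/leaves absent from the feature table ",
              "(pruned downstream): ", paste(utils::head(extra, 5), collapse = ", "))
    }
  }
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop_pb("not a phylo object")
  if (anyDuplicated(tree$tip.label)) stop_pb("duplicated leaf names in tree")
  if (is.null(tree$edge.length)) stop_pb("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length))) stop_pb("non-finite branch length")
  if (any(tree$edge.length < 0)) stop_pb("negative branch length")
  if (!ape::is.rooted(tree)) stop_pb("tree must be rooted")
  invisible(tree)
}
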