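#' @importFrom utils read.table write.table packageVersion
NULL

# delimiter from extension, falling back to sniffing the first line
sniff_sep <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return(",")
  if (ext %in% c("tsv", "tab", "txt")) return("\t")
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a delimited feature table
#'
#' Reads a CSV/TSV abundance table (first row and first column are headers)
#' into the canonical samples-in-rows layout, transposing when the file
#' stores features in rows. Cells must parse as finite numbers.
#'
#' @param path Path to a `.csv` or `.tsv` file.
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`.
#' @param feature_kind Feature kind tag, see [feature_table()].
#' @param transform_tag Transform tag of the stored values; `"raw"` (the
#'   default) enforces non-negativity, other tags allow re-reading tables
#'   written after transformation.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_in_rows",
                                               "features_in_rows"),
                               feature_kind = "generic",
                               transform_tag = "raw") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- sniff_sep(path)
  raw <- read.table(path, sep = sep, header = TRUE, row.names = NULL,
                    check.names = FALSE, colClasses = "character",
                    comment.char = "#", quote = "\"", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) stopf("empty table in %s", path)
  row_ids <- raw[[1L]]
  if (anyDuplicated(row_ids)) {
    stopf("duplicated row ids in %s: %s", path,
          paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  }
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("non-numeric cell '%s' at row '%s', column '%s' in %s",
          body[bad[1L, 1L], bad[1L, 2L]], row_ids[bad[1L, 1L]],
          colnames(body)[bad[1L, 2L]], path)
  }
  if (anyNA(num)) stopf("missing values are not allowed in feature tables (%s)", path)
  dimnames(num) <- list(row_ids, colnames(raw)[-1L])
  if (orientation == "features_in_rows") num <- t(num)
  feature_table(num, feature_kind = feature_kind, transform_tag = transform_tag)
}

#' Write a feature table to TSV
#'
#' Emits a tab-separated file with a commented provenance header (tool
#' version and any parameters supplied) that [read_feature_table()] skips.
#'
#' @param t A `feature_table`.
#' @param path Output path.
#' @param params Optional named list recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(t, path, params = list()) {
  stopifnot(inherits(t, "feature_table"))
  write_result_tsv(
    data.frame(sample_id = sample_ids(t), t$values, check.names = FALSE),
    path,
    params = c(list(feature_kind = t$feature_kind,
                    transform_tag = t$transform_tag), params)
  )
}

#' Write a result data frame to TSV with a provenance header
#'
#' @param df A data frame.
#' @param path Output path.
#' @param params Named list of parameters recorded as `# key=value` comments.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mgtools %s", as.character(packageVersion("mgtools"))), con)
  for (k in names(params)) {
    writeLines(sprintf("# %s=%s", k, paste(format(params[[k]], digits = 15),
                                           collapse = ",")), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' First column is the sample identifier. Remaining columns are auto-typed:
#' all-numeric columns become continuous, anything else categorical;
#' `type_hints` overrides the guess. Missing cells are allowed and kept as
#' `NA` so downstream tests can exclude those samples explicitly.
#'
#' @param path Path to CSV/TSV metadata.
#' @param type_hints Optional named character vector/list mapping column
#'   names to `"categorical"` or `"continuous"`.
#' @return An object of class `sample_metadata`: a data frame with sample
#'   ids as row names, factor columns for categorical variables and numeric
#'   columns for continuous ones.
#' @export
read_sample_metadata <- function(path, type_hints = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- sniff_sep(path)
  raw <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", comment.char = "#",
                    quote = "\"", stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stopf("duplicated sample ids in metadata: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- raw[, -1L, drop = FALSE]
  for (nm in names(out)) {
    hint <- if (!is.null(type_hints)) type_hints[[nm]] else NULL
    col <- out[[nm]]
    num <- suppressWarnings(as.numeric(col))
    is_numeric <- !any(is.na(num) & !is.na(col))
    type <- hint %||% if (is_numeric) "continuous" else "categorical"
    if (!type %in% c("continuous", "categorical")) {
      stopf("unknown type hint '%s' for column '%s'", type, nm)
    }
    if (type == "continuous") {
      if (!is_numeric) stopf("column '%s' hinted continuous but is not numeric", nm)
      out[[nm]] <- num
    } else {
      out[[nm]] <- factor(col)
    }
  }
  rownames(out) <- ids
  class(out) <- c("sample_metadata", "data.frame")
  out
}

#' Read a two-column mapping table
#'
#' Used for contig-to-cluster assignments (CONCOCT output), feature-to-KO
#' annotations and KO-to-pathway membership. Duplicate identical pairs are
#' collapsed; a contig assigned to two different clusters is an error.
#'
#' @param path Path to a two-column delimited file.
#' @param role `"contig_to_cluster"`, `"ko_to_pathway"` or `"feature_to_ko"`.
#' @param header Does the file carry a header line? Default `FALSE`.
#' @return An object of class `mapping_table`: a data frame with columns
#'   `element_id` and `group_id` plus a `role` attribute.
#' @export
read_mapping <- function(path,
                         role = c("contig_to_cluster", "ko_to_pathway",
                                  "feature_to_ko"),
                         header = FALSE) {
  role <- match.arg(role)
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- sniff_sep(path)
  raw <- read.table(path, sep = sep, header = header, check.names = FALSE,
                    colClasses = "character", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stopf("mapping file %s must have two columns", path)
  mapping_table(raw[[1L]], raw[[2L]], role = role)
}

#' Construct a mapping table from vectors
#'
#' @param element_id,group_id Character vectors of equal length.
#' @param role Mapping role, see [read_mapping()].
#' @return A `mapping_table`.
#' @export
mapping_table <- function(element_id, group_id,
                          role = c("contig_to_cluster", "ko_to_pathway",
                                   "feature_to_ko")) {
  role <- match.arg(role)
  df <- unique(data.frame(element_id = as.character(element_id),
                          group_id = as.character(group_id),
                          stringsAsFactors = FALSE))
  if (nrow(df) == 0L) stopf("mapping table is empty")
  if (role == "contig_to_cluster" && anyDuplicated(df$element_id)) {
    dup <- unique(df$element_id[duplicated(df$element_id)])
    stopf("contig(s) assigned to more than one cluster: %s",
          paste(dup, collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df, class = c("mapping_table", "data.frame"), role = role)
}

#' Read a rooted newick tree
#'
#' Thin wrapper over [ape::read.tree()] that enforces unique tip labels and
#' defined non-negative branch lengths (missing lengths become 0 with a
#' warning).
#'
#' @param path Path to a newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick_tree <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stopf("newick parse error in %s: %s",
                                             path, conditionMessage(e)))
  if (is.null(tree)) stopf("newick parse error in %s", path)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("not a phylogenetic tree")
  if (anyDuplicated(tree$tip.label)) stopf("duplicated tip labels in tree")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("tree has undefined branch lengths; set to 0", call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stopf("tree has negative branch lengths")
  tree
}

#' Harmonize sample identifiers across datasets
#'
#' Restricts every table (and the metadata, when given) to the exact-match
#' intersection of their sample ids, in a single lexicographic order, and
#' reports the ids dropped from each input. Harmonization is idempotent.
#'
#' @param tables A list of `feature_table` objects (at least one).
#' @param metadata Optional `sample_metadata`.
#' @return A list with elements `tables`, `metadata` and `report` (a data
#'   frame of input name and dropped sample id).
#' @export
harmonize_samples <- function(tables, metadata = NULL) {
  if (inherits(tables, "feature_table")) tables <- list(tables)
  if (length(tables) < 1L) stopf("need at least one feature table")
  id_sets <- lapply(tables, sample_ids)
  names(id_sets) <- names(tables) %||% paste0("table", seq_along(tables))
  if (!is.null(metadata)) id_sets$metadata <- rownames(metadata)
  common <- Reduce(intersect, id_sets)
  if (length(common) == 0L) stopf("no sample ids shared by all inputs")
  common <- lex_sort(common)
  report <- do.call(rbind, lapply(names(id_sets), function(nm) {
    dropped <- setdiff(id_sets[[nm]], common)
    if (length(dropped) == 0L) return(NULL)
    data.frame(input = nm, dropped_sample = lex_sort(dropped),
               stringsAsFactors = FALSE)
  }))
  if (is.null(report)) {
    report <- data.frame(input = character(), dropped_sample = character(),
                         stringsAsFactors = FALSE)
  }
  out_tables <- lapply(tables, function(t) {
    feature_table(t$values[common, , drop = FALSE],
                  feature_kind = t$feature_kind,
                  transform_tag = t$transform_tag)
  })
  names(out_tables) <- names(tables)
  out_meta <- if (is.null(metadata)) NULL else metadata[common, , drop = FALSE]
  list(tables = out_tables, metadata = out_meta, report = report)
}
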