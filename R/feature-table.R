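#' Construct a feature table
#'
#' A feature table holds one row per quantified molecular species (metabolite
#' feature, NMR bin or protein) and one column per sample, with nonnegative
#' abundance values on an arbitrary intensity scale. Missing measurements are
#' stored as `NA`; a literal 0 is treated as a real measurement, not as
#' missing, because upstream pipelines differ in how they encode dropouts.
#'
#' @param values numeric matrix, features in rows, samples in columns. Must
#'   carry unique rownames (feature ids) and colnames (sample ids).
#' @param annotations optional named character vector mapping feature ids to
#'   functional-category labels. Names must be a subset of the feature ids.
#' @return An object of class `feature_table`: a list with elements
#'   `values`, `feature_ids`, `sample_ids`, `annotations`.
#' @examples
#' m <- matrix(rexp(12, 1 / 100), 3, 4,
#'             dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' ft <- feature_table(m)
#' dim(ft)
#' @export
feature_table <- function(values, annotations = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("'values' must have rownames (feature ids) and colnames (sample ids)")
  if (anyDuplicated(fid))
    stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1L])
  bad <- which(!is.na(values) & !is.finite(values))
  if (length(bad))
    stop("non-finite value at feature '", fid[row(values)[bad[1L]]],
         "', sample '", sid[col(values)[bad[1L]]], "'")
  neg <- which(!is.na(values) & values < 0)
  if (length(neg))
    stop("negative intensity at feature '", fid[row(values)[neg[1L]]],
         "', sample '", sid[col(values)[neg[1L]]],
         "': processed abundance tables must be nonnegative")
  if (!is.null(annotations)) {
    if (is.null(names(annotations)))
      stop("'annotations' must be a named character vector (feature id -> category)")
    unknown <- setdiff(names(annotations), fid)
    if (length(unknown))
      stop("annotation for unknown feature id: ", unknown[1L])
    annotations <- structure(as.character(annotations), names = names(annotations))
  }
  structure(list(values = values,
                 feature_ids = fid,
                 sample_ids = sid,
                 annotations = annotations),
            class = "feature_table")
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x$values), "features x", ncol(x$values), "samples\n")
  nmiss <- sum(is.na(x$values))
  if (nmiss) cat("  missing cells:", nmiss, "\n")
  if (!is.null(x$annotations))
    cat("  annotated features:", length(x$annotations), "\n")
  invisible(x)
}

#' Read a feature table from CSV/TSV
#'
#' Expects features in rows and samples in columns: the first column holds
#' feature identifiers and the header row holds sample identifiers. Cells
#' equal to `missing_token` (or empty) load as missing values; any other
#' non-numeric cell, any negative value, and any duplicated identifier abort
#' the load with a message naming the offending coordinates.
#'
#' @param path path to the delimited file.
#' @param dialect `"tsv"` or `"csv"`; default guessed from the file extension
#'   (`.csv` means csv, anything else tsv).
#' @param missing_token string encoding a missing measurement; empty cells are
#'   always treated as missing.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, dialect = NULL, missing_token = "NA") {
  if (!file.exists(path)) stop("feature table file not found: ", path)
  if (is.null(dialect))
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  dialect <- match.arg(dialect, c("tsv", "csv"))
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("feature table needs a feature-id column plus >= 1 sample column")
  fid <- raw[[1L]]
  sid <- colnames(raw)[-1L]
  if (anyDuplicated(fid))
    stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells[cells == missing_token | cells == ""] <- NA_character_
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !is.na(cells))
  if (length(bad))
    stop("non-numeric cell '", cells[bad[1L]], "' at feature '",
         fid[row(cells)[bad[1L]]], "', sample '", sid[col(cells)[bad[1L]]], "'")
  dimnames(num) <- list(fid, sid)
  feature_table(num)
}

#' Read a feature annotation file
#'
#' Two-column delimited file mapping feature id to a functional-category
#' label; used by [delta_cv_table()] to summarise which categories gained or
#' lost variation.
#'
#' @param path path to a TSV/CSV with columns feature id, category.
#' @return named character vector.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  a <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(a) < 2L) stop("annotation file needs two columns: feature_id, category")
  if (anyDuplicated(a[[1L]]))
    stop("duplicate annotation for feature id: ", a[[1L]][duplicated(a[[1L]])][1L])
  structure(a[[2L]], names = a[[1L]])
}

#' Construct a sample design
#'
#' Maps each sample to an experimental group, with optional timepoint (hours
#' post-stress) and replicate index. Analyses require at least three
#' biological replicates per group, mirroring the standard repository
#' inclusion rule for replicate-variation studies.
#'
#' @param sample_id character vector of unique sample ids.
#' @param group character vector of group labels, same length.
#' @param timepoint optional numeric vector of nonnegative hours.
#' @param replicate optional integer vector of replicate indices.
#' @return object of class `sample_design` (a data frame).
#' @export
sample_design <- function(sample_id, group, timepoint = NULL, replicate = NULL) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(group) != length(sample_id))
    stop("'group' and 'sample_id' lengths differ")
  if (anyDuplicated(sample_id))
    stop("sample listed twice in design: ", sample_id[duplicated(sample_id)][1L])
  d <- data.frame(sample_id = sample_id, group = group,
                  stringsAsFactors = FALSE)
  if (!is.null(timepoint)) {
    timepoint <- as.numeric(timepoint)
    if (any(!is.na(timepoint) & timepoint < 0))
      stop("timepoints must be nonnegative hours")
    d$timepoint <- timepoint
  }
  if (!is.null(replicate)) d$replicate <- as.integer(replicate)
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Read a sample design file
#'
#' Delimited file with columns `sample_id`, `group` and optional `timepoint`
#' (hours) and `replicate`. Groups keep file order.
#'
#' @param path path to the design TSV/CSV.
#' @return A [sample_design].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         colClasses = "character", stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% colnames(d)))
    stop("design file must have columns 'sample_id' and 'group'")
  tp <- NULL
  if ("timepoint" %in% colnames(d)) {
    tp <- suppressWarnings(as.numeric(d$timepoint))
    bad <- !is.na(d$timepoint) & d$timepoint != "" & is.na(tp)
    if (any(bad))
      stop("non-numeric timepoint '", d$timepoint[bad][1L], "' for sample '",
           d$sample_id[bad][1L], "'")
  }
  rep_idx <- if ("replicate" %in% colnames(d)) suppressWarnings(as.integer(d$replicate))
  sample_design(d$sample_id, d$group, timepoint = tp, replicate = rep_idx)
}

#' @export
print.sample_design <- function(x, ...) {
  cat("Sample design:", nrow(x), "samples,",
      length(unique(x$group)), "groups\n")
  print(table(group = x$group))
  invisible(x)
}

# samples of one group present in a feature table, in design order
group_samples <- function(design, table, group) {
  if (!group %in% design$group)
    stop("group not found in design: '", group, "'")
  ids <- design$sample_id[design$group == group]
  ids[ids %in% table$sample_ids]
}

#' Write comparison results
#'
#' Serialises one [rva_comparison] or a table of comparisons (e.g. from
#' [recovery_summary()]) to TSV or JSON. Numeric fields are written at full
#' precision so that reading the file back reproduces them exactly.
#'
#' @param result an `rva_comparison` or a data frame.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`; default guessed from the extension.
#' @export
write_results <- function(result, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  format <- match.arg(format, c("tsv", "json"))
  df <- if (inherits(result, "rva_comparison")) as.data.frame(result) else
    as.data.frame(result)
  if (format == "json") {
    # digits = I(17): every double survives the decimal round trip exactly
    jsonlite::write_json(df, path, auto_unbox = FALSE, digits = I(17), na = "null")
  } else {
    out <- df
    num <- vapply(out, is.numeric, logical(1L))
    out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back results written by [write_results()]
#'
#' @param path file written by [write_results()].
#' @param format `"tsv"` or `"json"`; default guessed from the extension.
#' @return data frame with one row per comparison.
#' @export
read_results <- function(path, format = NULL) {
  if (!file.exists(path)) stop("results file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  format <- match.arg(format, c("tsv", "json"))
  if (format == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
}
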