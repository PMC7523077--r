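#' Construct an abundance matrix with sample metadata
#'
#' The central data container: a samples x metabolites table of relative
#' abundances (non-negative, unitless, as produced by LC-MS/GC-MS relative
#' quantification) plus per-sample metadata carrying the condition label and
#' the phenotype trait (tumor volume in mm^3 or cell number). Missing values
#' are permitted and propagate to pairwise-complete correlation later; they
#' are never imputed here.
#'
#' @param values numeric matrix, samples in rows, metabolites in columns,
#'   with unique row and column names.
#' @param metadata data frame with columns `sample_id`, `condition`, and
#'   optionally `trait` and `tissue`; one row per sample, in any order.
#' @return An object of class `abundance_matrix` with elements `values`
#'   (matrix, metadata-aligned row order) and `metadata`.
#' @export
abundance_matrix <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values))
    mc_stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    mc_stop("values must have sample row names and metabolite column names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    mc_stop("duplicate sample ids: ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    mc_stop("duplicate metabolite ids: ", paste(unique(dup), collapse = ", "))
  if (any(!is.na(values) & !is.finite(values)))
    mc_stop("values must be finite or NA")
  if (any(!is.na(values) & values < 0))
    mc_stop("abundances must be non-negative")
  if (!is.data.frame(metadata) ||
      !all(c("sample_id", "condition") %in% names(metadata)))
    mc_stop("metadata needs at least sample_id and condition columns")
  if (anyDuplicated(metadata$sample_id))
    mc_stop("duplicate sample ids in metadata")
  missing_meta <- setdiff(rownames(values), metadata$sample_id)
  if (length(missing_meta))
    mc_stop("samples without metadata: ", paste(missing_meta, collapse = ", "))
  metadata <- metadata[match(rownames(values), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix:", nrow(x$values), "samples x",
      ncol(x$values), "metabolites\n")
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(table(x$metadata$condition)),
                    table(x$metadata$condition)), collapse = ", "), "\n")
  if ("trait" %in% names(x$metadata)) cat("trait present\n")
  na <- sum(is.na(x$values))
  if (na) cat(na, "missing values\n")
  invisible(x)
}

#' Samples belonging to one condition
#' @param data an `abundance_matrix`.
#' @param condition a condition label present in the metadata.
#' @return The `abundance_matrix` restricted to that condition's samples.
#' @export
subset_condition <- function(data, condition) {
  stopifnot(inherits(data, "abundance_matrix"))
  keep <- data$metadata$condition == condition
  if (!any(keep))
    mc_stop("condition '", condition, "' not present in metadata (have: ",
            paste(unique(data$metadata$condition), collapse = ", "), ")")
  abundance_matrix(data$values[keep, , drop = FALSE],
                   data$metadata[keep, , drop = FALSE])
}

sniff_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_checked <- function(path, delim, missing) {
  raw <- utils::read.delim(path, sep = delim, header = TRUE,
                           check.names = FALSE, row.names = NULL,
                           stringsAsFactors = FALSE,
                           na.strings = missing, colClasses = "character")
  if (ncol(raw) < 2) mc_stop("table in ", path, " has no data columns")
  hdr <- names(raw)[-1]
  if (anyDuplicated(hdr))
    mc_stop("duplicate column ids in ", path, ": ",
            paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    mc_stop("duplicate row ids in ", path, ": ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat),
                                dimnames = dimnames(mat)))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    mc_stop("non-numeric cell at row '", ids[bad[1, 1]], "', column '",
            colnames(mat)[bad[1, 2]], "' in ", path,
            " (value: ", mat[bad[1, , drop = FALSE]], ")")
  }
  rownames(num) <- ids
  num
}

#' Read an abundance table (and optional metadata) from delimited text
#'
#' Reads a comma- or tab-delimited table with header row and id column.
#' The `orientation` flag states what the file's rows are; the returned
#' object always has samples in rows. Rows/columns that are entirely
#' missing are dropped with a log message. Duplicated ids and non-numeric
#' cells are rejected with the offending address.
#'
#' @param path abundance table file (.csv or .tsv; delimiter sniffed from
#'   the extension, overridable via `delim`).
#' @param meta sample metadata: a path to a delimited table with columns
#'   `sample_id`, `condition`, optionally `trait`/`tissue`, or a data frame,
#'   or `NULL` (all samples then get condition "all").
#' @param orientation `"samples"` if file rows are samples, `"metabolites"`
#'   if file rows are metabolites (the table is transposed on read).
#' @param delim field delimiter override.
#' @param missing strings to treat as missing values.
#' @return An [abundance_matrix()].
#' @export
read_abundance <- function(path, meta = NULL,
                           orientation = c("samples", "metabolites"),
                           delim = NULL, missing = c("NA", "")) {
  orientation <- match.arg(orientation)
  num <- read_table_checked(path, sniff_delim(path, delim), missing)
  dup <- rownames(num)[duplicated(rownames(num))]
  if (length(dup))
    mc_stop("duplicate row ids in ", path, ": ",
            paste(unique(dup), collapse = ", "))
  dup <- colnames(num)[duplicated(colnames(num))]
  if (length(dup))
    mc_stop("duplicate column ids in ", path, ": ",
            paste(unique(dup), collapse = ", "))
  if (orientation == "metabolites") num <- t(num)
  all_na_row <- rowSums(!is.na(num)) == 0
  all_na_col <- colSums(!is.na(num)) == 0
  if (any(all_na_row) || any(all_na_col))
    mc_log("dropped ", sum(all_na_row), " all-missing samples and ",
           sum(all_na_col), " all-missing metabolites from ", path)
  num <- num[!all_na_row, !all_na_col, drop = FALSE]

  metadata <- if (is.null(meta)) {
    data.frame(sample_id = rownames(num), condition = "all",
               stringsAsFactors = FALSE)
  } else if (is.character(meta)) {
    read_sample_metadata(meta)
  } else {
    meta
  }
  abundance_matrix(num, metadata)
}

#' Read a sample metadata table
#' @param path delimited text with columns `sample_id`, `condition`,
#'   optionally `trait` (numeric) and `tissue`.
#' @param delim delimiter override (sniffed from extension otherwise).
#' @return data frame.
#' @export
read_sample_metadata <- function(path, delim = NULL) {
  md <- utils::read.delim(path, sep = sniff_delim(path, delim),
                          header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(md)))
    mc_stop("metadata in ", path, " must have sample_id and condition columns")
  if ("trait" %in% names(md)) md$trait <- as.numeric(md$trait)
  md
}

#' Write an abundance matrix (and its metadata) as delimited text
#'
#' Values are written with 15 significant digits so a write/read round trip
#' is lossless well past 12 significant digits.
#'
#' @param data an `abundance_matrix`.
#' @param path abundance output file (.csv or .tsv).
#' @param meta_path optional metadata output file.
#' @param delim delimiter override.
#' @return Invisibly, `path`.
#' @export
write_abundance <- function(data, path, meta_path = NULL, delim = NULL) {
  stopifnot(inherits(data, "abundance_matrix"))
  d <- sniff_delim(path, delim)
  df <- data.frame(sample_id = rownames(data$values),
                   format(data$values, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = d, quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!is.null(meta_path))
    utils::write.table(data$metadata, meta_path,
                       sep = sniff_delim(meta_path, delim),
                       quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a metabolite-to-pathway map
#'
#' Two-column delimited text (`metabolite`, `pathway`), one row per
#' assignment; a metabolite appearing in several rows belongs to several
#' pathways (common for hub metabolites such as ADP or coenzyme A).
#'
#' @param path map file.
#' @param delim delimiter override.
#' @return Named list: metabolite id -> character vector of pathway names.
#' @export
read_pathway_map <- function(path, delim = NULL) {
  df <- utils::read.delim(path, sep = sniff_delim(path, delim),
                          header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    mc_stop("pathway map in ", path, " needs metabolite and pathway columns")
  split(as.character(df[[2]]), factor(df[[1]], levels = unique(df[[1]])))
}

#' @rdname read_pathway_map
#' @param map named list metabolite -> pathway names.
#' @export
write_pathway_map <- function(map, path, delim = NULL) {
  df <- data.frame(
    metabolite = rep(names(map), lengths(map)),
    pathway = unlist(map, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sniff_delim(path, delim),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Invert a pathway map to pathway -> members, matching a dataset
#'
#' Matching is by exact, case-sensitive metabolite id. Metabolites of the
#' dataset absent from the map are collected under pathway "unassigned"
#' with a warning.
#'
#' @param map named list metabolite -> pathway names.
#' @param metabolite_ids metabolite ids present in the dataset.
#' @return Named list pathway -> character vector of member metabolites.
#' @export
pathway_members <- function(map, metabolite_ids) {
  map <- map[intersect(names(map), metabolite_ids)]
  unmatched <- setdiff(metabolite_ids, names(map))
  if (length(unmatched)) {
    mc_warn(length(unmatched),
            " metabolites not in the pathway map; assigned to 'unassigned'")
    map[unmatched] <- list("unassigned")
  }
  long_met <- rep(names(map), lengths(map))
  long_pw <- unlist(map, use.names = FALSE)
  out <- split(long_met, long_pw)
  lapply(out, function(v) sort(unique(v)))
}
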