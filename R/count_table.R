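#' Construct a count table
#'
#' A count table holds nonnegative integer read counts for taxa (ASVs/zOTUs)
#' in rows and samples in columns, with unique ids on both margins. It is the
#' substrate of every downstream stage: QC filtering, normalization,
#' diversity, and null-model analysis. Optional taxonomy strings are carried
#' along untouched.
#'
#' @param counts numeric matrix of nonnegative integers, taxa in rows and
#'   samples in columns; both dimensions must carry unique names.
#' @param taxonomy optional character vector of lineage strings, either named
#'   by taxon id or in row order of `counts`.
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  # a filter may legitimately empty the taxon set; R stores no rownames
  # for zero-row matrices, so only nonempty tables must carry them
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
      is.null(colnames(counts)))
    stop("counts must have taxon row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative")
  if (any(counts != round(counts)))
    stop("counts must be integral")
  storage.mode(counts) <- "double"
  if (!is.null(taxonomy)) {
    if (!is.null(names(taxonomy))) {
      taxonomy <- taxonomy[rownames(counts)]
    } else if (length(taxonomy) == nrow(counts)) {
      names(taxonomy) <- rownames(counts)
    } else {
      stop("taxonomy must be named by taxon id or match the number of taxa")
    }
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table: ", nrow(x$counts), " taxa x ", ncol(x$counts),
      " samples; total reads ", format(sum(x$counts), big.mark = ","),
      if (!is.null(x$taxonomy)) "; taxonomy carried" else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Accessors for count tables
#'
#' @param table a `count_table` or a bare counts matrix.
#' @return `ct_counts()` the counts matrix; `taxon_ids()` / `sample_ids()`
#'   the margin ids.
#' @export
ct_counts <- function(table) {
  if (inherits(table, "count_table")) return(table$counts)
  if (is.matrix(table)) {
    if ((is.null(rownames(table)) && nrow(table) > 0) ||
        is.null(colnames(table)))
      stop("a bare counts matrix must carry dimnames")
    return(table)
  }
  stop("not a count_table or counts matrix")
}

#' @rdname ct_counts
#' @export
taxon_ids <- function(table) {
  rn <- rownames(ct_counts(table))
  if (is.null(rn)) character(0) else rn
}

#' @rdname ct_counts
#' @export
sample_ids <- function(table) colnames(ct_counts(table))

## internal: rebuild a count_table keeping taxonomy aligned
ct_replace <- function(table, counts) {
  tax <- if (inherits(table, "count_table")) table$taxonomy else NULL
  if (!is.null(tax)) tax <- tax[rownames(counts)]
  count_table(counts, taxonomy = tax)
}

#' Subset a count table by taxa and/or samples
#'
#' @param table a `count_table`.
#' @param taxa,samples character vectors of ids to keep (default: all).
#' @return a `count_table`.
#' @export
ct_subset <- function(table, taxa = NULL, samples = NULL) {
  m <- ct_counts(table)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(m))
    if (length(missing))
      stop("unknown taxon ids: ", paste(missing, collapse = ", "))
    m <- m[taxa, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing))
      stop("unknown sample ids: ", paste(missing, collapse = ", "))
    m <- m[, samples, drop = FALSE]
  }
  ct_replace(table, m)
}

#' Read a taxa-by-samples count table from tab-separated text
#'
#' Expects a header row of sample ids, a first column of taxon ids, and
#' integer cells. A trailing column named `taxonomy` (case-insensitive) is
#' treated as lineage annotation and carried, not counted.
#'
#' @param path file path.
#' @return a `count_table`.
#' @export
read_count_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (nrow(raw) == 0) stop("no taxa in ", path)
  if (ncol(raw) < 2) stop("no samples in ", path)
  taxa <- raw[[1]]
  if (anyDuplicated(taxa))
    stop("duplicate taxon ids in ", path, ": ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  body <- raw[, -1, drop = FALSE]
  tax <- NULL
  tax_col <- which(tolower(names(body)) == "taxonomy")
  if (length(tax_col)) {
    tax <- stats::setNames(body[[tax_col[1]]], taxa)
    body <- body[, -tax_col, drop = FALSE]
  }
  if (ncol(body) == 0) stop("no samples in ", path)
  if (anyDuplicated(names(body)))
    stop("duplicate sample ids in ", path)
  m <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(taxa, names(body)))
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop("non-integer or negative count at taxon '", taxa[bad[1]],
           "', sample '", names(body)[j], "': '", body[[j]][bad[1]], "'")
    m[, j] <- v
  }
  count_table(m, taxonomy = tax)
}

#' Write a count table as tab-separated text
#'
#' Integer tables round-trip byte-stably through [read_count_table()].
#'
#' @param table a `count_table`.
#' @param path file path.
#' @export
write_count_table <- function(table, path) {
  m <- ct_counts(table)
  df <- data.frame(taxon_id = rownames(m),
                   format(m, scientific = FALSE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  tax <- if (inherits(table, "count_table")) table$taxonomy else NULL
  if (!is.null(tax)) df$taxonomy <- unname(tax)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read and validate a sample metadata table
#'
#' Tab-separated with columns `sample_id`, `sample_type`, `water_treatment`,
#' `strain`, `flask_id`, `day_dph`. Sample types follow the flask rearing
#' design: individual gut samples, per-flask rearing-water samples,
#' added-water (source community) samples, and negative controls.
#'
#' @param path file path.
#' @return a `data.frame` with validated columns.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(md)
}

#' @rdname read_sample_metadata
#' @param metadata a data.frame to validate in place.
#' @export
validate_metadata <- function(metadata) {
  required <- c("sample_id", "sample_type", "water_treatment", "strain",
                "flask_id", "day_dph")
  missing <- setdiff(required, names(metadata))
  if (length(missing))
    stop("metadata lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample ids in metadata")
  types <- c("gut", "rearing_water", "added_water", "negative_control")
  bad <- setdiff(unique(metadata$sample_type), types)
  if (length(bad))
    stop("unknown sample_type: ", paste(bad, collapse = ", "))
  treatments <- c("Add-r", "Add-K", "none")
  bad <- setdiff(unique(metadata$water_treatment), treatments)
  if (length(bad))
    stop("unknown water_treatment: ", paste(bad, collapse = ", "))
  needs_flask <- metadata$sample_type %in% c("gut", "rearing_water")
  if (any(needs_flask & (is.na(metadata$flask_id) | metadata$flask_id == "")))
    stop("gut and rearing_water samples must carry a flask_id")
  metadata$day_dph <- as.integer(metadata$day_dph)
  metadata
}

#' @rdname read_sample_metadata
#' @param metadata a validated metadata data.frame.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
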