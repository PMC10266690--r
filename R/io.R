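#' Construct a replicate read table
#'
#' The raw metabarcoding observation unit: an ASV-by-replicate matrix of
#' sequence read counts whose columns are keyed by (site, bottle, pcr, marker).
#'
#' @param counts integer matrix, ASVs in rows (rownames = ASV ids), replicates
#'   in columns (colnames = replicate labels).
#' @param keys data.frame of parsed replicate keys, one row per column of
#'   `counts` (see [parse_replicate_key()]).
#' @return An object of class `replicate_read_table`: a list with elements
#'   `counts` and `keys`.
#' @export
replicate_read_table <- function(counts, keys) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  stopifnot(is.data.frame(keys), nrow(keys) == ncol(counts))
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("ASV ids (rownames) must be present and unique", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0L)) {
    bad <- which(is.na(counts) | counts < 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("read counts must be nonnegative integers (row %s, column %s)",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]),
         call. = FALSE)
  }
  structure(list(counts = counts, keys = keys), class = "replicate_read_table")
}

#' @export
print.replicate_read_table <- function(x, ...) {
  cat(sprintf("replicate_read_table: %d ASVs x %d replicates (%d sites, %s reads)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$keys$site)),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
dim.replicate_read_table <- function(x) dim(x$counts)

#' Read an ASV-by-replicate read table from TSV/CSV
#'
#' The first column holds ASV ids; every remaining column is one technical
#' replicate whose header encodes (site, bottle, pcr, marker).
#'
#' @param path file path; the delimiter is taken from the extension
#'   (`.csv` = comma, otherwise tab).
#' @param delim replicate-label field delimiter (see [parse_replicate_key()]).
#' @return A [replicate_read_table()].
#' @export
read_read_table <- function(path, delim = "__") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) stop("read table needs an ASV id column plus >= 1 replicate column",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate ASV ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != round(m))) {
    bad <- which(is.na(m) | !is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad) == 0L) bad <- matrix(c(1L, 1L), 1L)  # non-numeric coercion
    stop(sprintf("cell is not a nonnegative integer at row '%s', column '%s'",
                 ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]), call. = FALSE)
  }
  rownames(m) <- ids
  replicate_read_table(m, parse_replicate_key(colnames(m), delim = delim))
}

#' Write a replicate (or taxon) read table to TSV/CSV
#'
#' @param x a `replicate_read_table` or `taxon_read_table`.
#' @param path output path; `.csv` writes comma-separated, otherwise tab.
#' @param id_col header for the first (id) column.
#' @return `path`, invisibly.
#' @export
write_read_table <- function(x, path, id_col = "asv_id") {
  stopifnot(inherits(x, c("replicate_read_table", "taxon_read_table")))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(id = rownames(x$counts), x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read long-format capture/visual survey records
#'
#' Expects a CSV with columns `site, method, replicate, species, value`:
#' seine catch counts per haul, or BRUV MaxN per deployment (the maximum
#' number of individuals of one species visible in a single video frame).
#'
#' @param path CSV file path.
#' @param methods allowed method labels.
#' @return data.frame with the five columns, `replicate` integer, `value`
#'   nonnegative numeric.
#' @export
read_survey_records <- function(path, methods = c("seine", "bruv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("site", "method", "replicate", "species", "value")
  if (!all(required %in% names(df))) {
    stop("survey records need columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  df <- df[required]
  if (nrow(df) == 0L) return(df)
  unknown <- setdiff(unique(df$method), methods)
  if (length(unknown)) {
    stop("unknown survey method(s) ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(methods, collapse = ", "), call. = FALSE)
  }
  if (anyNA(df$value) || any(df$value < 0)) {
    stop("survey record values must be nonnegative", call. = FALSE)
  }
  if (any(df$replicate < 1L | df$replicate != round(df$replicate))) {
    stop("replicate indices must be integers >= 1", call. = FALSE)
  }
  df$replicate <- as.integer(df$replicate)
  df$species <- normalize_species(df$species)
  df
}

#' Write survey records to CSV
#' @param records data.frame as returned by [read_survey_records()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASV taxonomy table
#'
#' Two-column TSV: `asv_id` and a semicolon-delimited ranked path
#' (class;order;family;genus;species — the path may stop above species, e.g.
#' at family for surfperches sharing an identical barcode).
#'
#' @param path TSV file path.
#' @return data.frame with columns `asv_id`, `path`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (!all(c("asv_id", "path") %in% names(df))) {
    stop("taxonomy table needs columns asv_id, path", call. = FALSE)
  }
  if (anyDuplicated(df$asv_id)) stop("duplicate asv_id in taxonomy", call. = FALSE)
  if (any(!nzchar(df$path))) stop("empty taxonomic path", call. = FALSE)
  df[c("asv_id", "path")]
}

#' Write an ASV taxonomy table
#' @param taxonomy data.frame with columns `asv_id`, `path`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy[c("asv_id", "path")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Free-text binomials are matched by trimmed, case-folded comparison only;
# no taxonomy-service lookups.
normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  paste0(toupper(substring(x, 1L, 1L)), tolower(substring(x, 2L)))
}
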