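#' Parse replicate labels into their key components
#'
#' eDNA replicate columns are labelled `site<delim>bottle<delim>pcr<delim>marker`,
#' e.g. `"BecherBay__2__3__teleost"`: the water sample (bottle) replicate and the
#' technical PCR replicate taken at a site with a given primer set (marker).
#'
#' @param label character vector of replicate labels.
#' @param delim field delimiter (default `"__"`); treated as a fixed string.
#' @return A data.frame with columns `site` (character), `bottle` (integer,
#'   >= 1), `pcr` (integer, >= 1) and `marker` (character), one row per label.
#' @seealso [format_replicate_key()] for the inverse.
#' @examples
#' parse_replicate_key("BecherBay__2__3__teleost")
#' @export
parse_replicate_key <- function(label, delim = "__") {
  stopifnot(is.character(label), length(label) >= 1L,
            is.character(delim), length(delim) == 1L, nzchar(delim))
  parts <- strsplit(label, delim, fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed replicate label (expected 4 '", delim, "'-delimited fields): ",
         paste(utils::head(label[bad], 3L), collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  empty <- apply(m, 1L, function(r) any(!nzchar(r)))
  if (any(empty)) {
    stop("malformed replicate label: empty field in ",
         paste(utils::head(label[empty], 3L), collapse = ", "), call. = FALSE)
  }
  for (j in 2:3) {
    field <- c("bottle", "pcr")[j - 1L]
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v) || any(v != round(v))) {
      stop("malformed replicate label: field '", field, "' is not an integer in ",
           paste(utils::head(label[is.na(v) | v != round(v)], 3L), collapse = ", "),
           call. = FALSE)
    }
    if (any(v < 1)) {
      stop("invalid replicate label: field '", field, "' must be >= 1 in ",
           paste(utils::head(label[v < 1], 3L), collapse = ", "), call. = FALSE)
    }
  }
  key <- data.frame(site = m[, 1L], bottle = as.integer(m[, 2L]),
                    pcr = as.integer(m[, 3L]), marker = m[, 4L],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(label)) {
    stop("duplicate replicate labels: ",
         paste(unique(label[duplicated(label)]), collapse = ", "), call. = FALSE)
  }
  key
}

#' Format replicate keys back into labels
#'
#' @param key data.frame with columns `site`, `bottle`, `pcr`, `marker`.
#' @param delim field delimiter (default `"__"`).
#' @return Character vector of labels; `parse_replicate_key()` round-trips.
#' @export
format_replicate_key <- function(key, delim = "__") {
  stopifnot(is.data.frame(key),
            all(c("site", "bottle", "pcr", "marker") %in% names(key)))
  paste(key$site, key$bottle, key$pcr, key$marker, sep = delim)
}
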