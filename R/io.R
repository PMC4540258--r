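#' Read a signature library from CSV
#'
#' Expected header: `sample_id, group, species, deposit`, then one column
#' per FA bin.  Values are fractions summing to one per row; with
#' `renormalize = TRUE` any positive scale (e.g. percent summing to 100) is
#' accepted and re-closed.  Rows violating the closure check or containing
#' negative or non-numeric cells are rejected with the offending row (and
#' column) named.
#'
#' @param path CSV file path
#' @param renormalize re-close each row instead of enforcing sum-to-one
#' @param tol closure tolerance when `renormalize = FALSE`
#' @return an [fa_library()]
#' @export
read_signature_csv <- function(path, renormalize = FALSE, tol = 1e-6) {
  if (!file.exists(path)) stop("signature file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("sample_id", "group", "species", "deposit")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  bin_cols <- setdiff(names(raw), required)
  if (length(bin_cols) < 2) stop("fewer than 2 FA bin columns in ", path)
  num <- matrix(NA_real_, nrow(raw), length(bin_cols),
                dimnames = list(NULL, bin_cols))
  for (j in seq_along(bin_cols)) {
    v <- suppressWarnings(as.numeric(raw[[bin_cols[j]]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value at row %d, column '%s'",
                   bad[1], bin_cols[j]))
    }
    num[, j] <- v
  }
  neg <- which(num < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative value at row %d, column '%s'",
                 neg[1, 1], bin_cols[neg[1, 2]]))
  }
  if (!renormalize) {
    bad <- which(abs(rowSums(num) - 1) > tol)
    if (length(bad)) {
      stop(sprintf("row %d does not sum to 1 (sum = %.8g); use renormalize = TRUE for percent input",
                   bad[1], rowSums(num)[bad[1]]))
    }
  }
  meta <- raw[required]
  fa_library(num, meta = meta, bins = bin_cols, normalize = TRUE)
}

#' Write a signature library to CSV
#'
#' Proportions are written as fractions with enough significant digits that
#' a write/read round trip is lossless to at least 10 significant digits.
#'
#' @param lib an [fa_library()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_signature_csv <- function(lib, path) {
  stopifnot(inherits(lib, "fa_library"))
  props <- lib$proportions
  chr <- matrix(sprintf("%.12g", props), nrow(props),
                dimnames = dimnames(props))
  out <- cbind(lib$meta[c("sample_id", "group", "species", "deposit")],
               as.data.frame(chr, stringsAsFactors = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chromatographic peak table from CSV
#'
#' Expected header: `sample_id, retention_time_min, area_fraction` and an
#' optional `known_label` column (blank = unidentified peak).
#'
#' @param path CSV file path
#' @return data frame with those columns (`known_label` `NA` when absent)
#' @export
read_peak_csv <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "retention_time_min", "area_fraction")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  if (is.null(raw$known_label)) raw$known_label <- NA_character_
  raw$known_label[!nzchar(trimws(as.character(raw$known_label))) |
                    is.na(raw$known_label)] <- NA_character_
  if (any(raw$retention_time_min < 0)) stop("negative retention time")
  if (any(raw$area_fraction < 0)) stop("negative area fraction")
  raw[c(required, "known_label")]
}
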