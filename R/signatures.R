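#' Construct a fatty acid signature library
#'
#' A signature library holds one compositional fatty acid (FA) signature per
#' sample over a fixed, ordered set of FA bins, together with sample
#' metadata.  Signatures are stored internally as fractions summing to one
#' (closure); all reporting functions convert to percent by mass.
#'
#' @param proportions numeric matrix, samples in rows and FA bins in
#'   columns.  Entries must be non-negative and each row must sum to one
#'   within `tol` unless `normalize = TRUE`.
#' @param meta data frame with one row per sample.  Recognised columns are
#'   `sample_id`, `group`, `species`, `deposit` and `season`; missing ones
#'   are filled with defaults.
#' @param bins character vector of bin labels; defaults to the column names
#'   of `proportions`.  Labels must be unique and at least two bins are
#'   required.
#' @param normalize if `TRUE`, rows are rescaled to sum to one (accepts
#'   percent input).
#' @param tol closure tolerance applied when `normalize = FALSE`.
#' @return an object of class `fa_library`: a list with elements
#'   `proportions` (matrix of fractions), `meta` (data frame) and `bins`.
#' @export
fa_library <- function(proportions, meta = NULL, bins = colnames(proportions),
                       normalize = FALSE, tol = 1e-6) {
  proportions <- as.matrix(proportions)
  storage.mode(proportions) <- "double"
  if (is.null(bins)) {
    bins <- sprintf("bin%02d", seq_len(ncol(proportions)))
  }
  bins <- as.character(bins)
  if (length(bins) != ncol(proportions)) {
    stop("number of bin labels must match the number of columns")
  }
  if (anyDuplicated(bins)) stop("bin labels must be unique")
  if (length(bins) < 2) stop("a bin set needs at least 2 bins")
  if (anyNA(proportions)) stop("proportions contain missing values")
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (normalize) {
    proportions <- normalize_composition(proportions)
  } else {
    bad <- which(abs(rowSums(proportions) - 1) > tol)
    if (length(bad)) {
      stop("rows not summing to 1 within tolerance: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    proportions <- proportions / rowSums(proportions)
  }
  n <- nrow(proportions)
  if (is.null(meta)) meta <- data.frame(sample_id = sprintf("s%03d", seq_len(n)))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n) stop("meta must have one row per sample")
  if (is.null(meta$sample_id)) meta$sample_id <- sprintf("s%03d", seq_len(n))
  for (col in c("group", "species", "deposit")) {
    if (is.null(meta[[col]])) meta[[col]] <- "none"
    meta[[col]] <- as.character(meta[[col]])
  }
  colnames(proportions) <- bins
  rownames(proportions) <- meta$sample_id
  structure(list(proportions = proportions, meta = meta, bins = bins),
            class = "fa_library")
}

#' @export
print.fa_library <- function(x, ...) {
  cat(sprintf("fa_library: %d samples x %d FA bins\n",
              nrow(x$proportions), length(x$bins)))
  groups <- table(x$meta$group)
  cat("groups: ",
      paste(sprintf("%s (n=%d)", names(groups), as.integer(groups)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of samples in a signature library
#' @param lib an `fa_library`
#' @return integer sample count
#' @export
n_samples <- function(lib) nrow(lib$proportions)

#' Close a non-negative vector (or matrix of row vectors) to sum one
#'
#' @param x non-negative numeric vector, or matrix with samples in rows.
#'   At least two entries per composition; no negative entries; each
#'   composition must have positive total.
#' @return vector or matrix of the same shape, rows summing to one.
#' @export
normalize_composition <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) < 2) stop("compositions need at least 2 parts")
    if (any(x < 0)) stop("invalid composition: negative entry")
    s <- rowSums(x)
    if (any(s <= 0)) stop("invalid composition: row with no positive entry")
    return(x / s)
  }
  if (length(x) < 2) stop("compositions need at least 2 parts")
  if (any(x < 0)) stop("invalid composition: negative entry")
  s <- sum(x)
  if (s <= 0) stop("invalid composition: all entries zero")
  x / s
}

#' Replace zeros (and near-zeros) in a composition
#'
#' Log-ratio based distances such as the Kullback-Leibler distance require
#' strictly positive compositions.  Entries below `eps` receive an additive
#' `eps` and the whole composition is re-closed:
#' `y = (x + eps * [x < eps]) / sum(...)`.  Entries already at or above
#' `eps` change only through the re-closure.
#'
#' @param x strictly non-negative composition (vector, matrix rows, or an
#'   `fa_library`).
#' @param eps replacement floor, in `(0, 1e-3]`.  Default `1e-5`, well below
#'   the 0.1 percent resolution at which signatures are usually reported.
#' @return same shape as `x`, strictly positive, rows summing to one.
#' @export
replace_zeros <- function(x, eps = 1e-5) {
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0 || eps > 1e-3) {
    stop("eps must be a single value in (0, 1e-3]")
  }
  if (inherits(x, "fa_library")) {
    x$proportions <- replace_zeros(x$proportions, eps)
    return(x)
  }
  if (any(x < 0)) stop("invalid composition: negative entry")
  if (is.matrix(x)) {
    y <- x + eps * (x < eps)
    return(y / rowSums(y))
  }
  y <- x + eps * (x < eps)
  y / sum(y)
}

#' Per-group mean and standard deviation of FA signatures
#'
#' Summaries are reported in percent by mass to match the conventional
#' presentation of FA composition tables.  The standard deviation uses the
#' n - 1 denominator; groups of a single sample report sd = 0.
#'
#' @param lib an `fa_library`
#' @param by metadata column defining groups (default `"group"`)
#' @return data frame with columns `group`, `fa`, `n`, `mean`, `sd`
#'   (`mean`, `sd` in percent), one row per group x bin.
#' @export
group_summary <- function(lib, by = "group") {
  stopifnot(inherits(lib, "fa_library"))
  if (!by %in% names(lib$meta)) stop("unknown grouping key: ", by)
  g <- lib$meta[[by]]
  groups <- unique(g)
  out <- lapply(groups, function(gr) {
    rows <- lib$proportions[g == gr, , drop = FALSE]
    n <- nrow(rows)
    mu <- colMeans(rows) * 100
    sdv <- if (n == 1) rep(0, ncol(rows)) else apply(rows, 2, stats::sd) * 100
    data.frame(group = gr, fa = lib$bins, n = n, mean = mu, sd = sdv,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sample-size weighted grand mean of the summed proportions of a bin subset
#'
#' For a set of FA bins (e.g. the predominant 16:0, 16:1, 18:0 and 18:1),
#' computes each group's summed mean proportion over the set, then the
#' n-weighted grand mean over groups — mathematically equal to the mean over
#' all individual samples when the group summaries were computed from them.
#'
#' @param summaries data frame as returned by [group_summary()]
#' @param fa_set character vector of bin labels (must all be present)
#' @param weights per-group sample sizes, named by group or in the order the
#'   groups first appear in `summaries`; defaults to the `n` recorded in the
#'   summaries.
#' @return grand mean in percent
#' @export
predominant_fraction <- function(summaries, fa_set, weights = NULL) {
  stopifnot(is.data.frame(summaries),
            all(c("group", "fa", "mean") %in% names(summaries)))
  missing <- setdiff(fa_set, unique(summaries$fa))
  if (length(missing)) {
    stop("bins not present in summaries: ", paste(missing, collapse = ", "))
  }
  groups <- unique(summaries$group)
  if (is.null(weights)) {
    weights <- vapply(groups, function(gr) {
      summaries$n[summaries$group == gr][1]
    }, numeric(1))
    names(weights) <- groups
  }
  if (!is.null(names(weights)) && all(groups %in% names(weights))) {
    weights <- weights[groups]
  } else if (length(weights) != length(groups)) {
    stop("weights must be named by group or match the number of groups")
  }
  if (any(weights <= 0)) stop("weights must be positive")
  sums <- vapply(groups, function(gr) {
    sub <- summaries[summaries$group == gr & summaries$fa %in% fa_set, ]
    sum(sub$mean)
  }, numeric(1))
  sum(weights * sums) / sum(weights)
}
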