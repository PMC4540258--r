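#' Principal components analysis of FA signatures
#'
#' Each FA bin's proportion is treated as a variable and the samples are
#' projected onto the principal components.  By default variables are
#' standardized (correlation-matrix PCA), so abundant and rare FA
#' contribute on equal footing; set `standardize = FALSE` for
#' covariance-matrix PCA.  Constant (zero-variance) bins are dropped with a
#' message before standardization.  Each component's sign is fixed so that
#' its largest-magnitude loading is positive.
#'
#' @param lib an [fa_library()] with at least 2 samples
#' @param standardize scale variables to unit variance (default `TRUE`)
#' @return object of class `fa_pca`: `scores` (samples x components),
#'   `explained` (fraction of retained variance per component,
#'   non-increasing), `loadings` (FA x components), `fa_correlations`
#'   (Pearson correlation of each retained FA with each score column),
#'   `sdev`, `dropped` (labels of constant bins), `meta`.
#' @export
run_pca <- function(lib, standardize = TRUE) {
  stopifnot(inherits(lib, "fa_library"))
  x <- lib$proportions
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  v <- apply(x, 2, stats::var)
  dropped <- colnames(x)[v <= .Machine$double.eps]
  if (length(dropped)) {
    message("dropping ", length(dropped), " constant FA bin(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, v > .Machine$double.eps, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  # orient each component so its dominant loading is positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  res <- structure(list(scores = pc$x, explained = explained,
                        loadings = pc$rotation, sdev = pc$sdev,
                        dropped = dropped, meta = lib$meta,
                        standardize = standardize),
                   class = "fa_pca")
  res$fa_correlations <- fa_component_correlation(res, lib)
  res
}

#' @export
print.fa_pca <- function(x, ...) {
  cat(sprintf("fa_pca: %d samples, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("explained variance: ",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 5)),
            collapse = ", "),
      if (length(x$explained) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Correlation of each FA proportion with each principal component
#'
#' Pearson correlations between the retained FA bins and the component
#' scores.  For standardized PCA this equals loading times the square root
#' of the eigenvalue.  A zero-variance column would yield an undefined
#' correlation; it is reported as 0 with a message.
#'
#' @param pca an `fa_pca` computed from `lib`
#' @param lib the same [fa_library()]
#' @return matrix, retained FA bins x components
#' @export
fa_component_correlation <- function(pca, lib) {
  stopifnot(inherits(pca, "fa_pca"), inherits(lib, "fa_library"))
  keep <- setdiff(lib$bins, pca$dropped)
  x <- lib$proportions[, keep, drop = FALSE]
  out <- matrix(0, ncol(x), ncol(pca$scores),
                dimnames = list(keep, colnames(pca$scores)))
  for (j in seq_len(ncol(x))) {
    if (stats::var(x[, j]) <= .Machine$double.eps) {
      message("zero-variance bin '", keep[j], "': correlation reported as 0")
      next
    }
    out[j, ] <- stats::cor(x[, j], pca$scores)
  }
  out
}

#' Per-component ANOVA with Tukey HSD pairwise group comparisons
#'
#' For each of the first `components` score columns, fits a one-way ANOVA
#' of score on group and adjusts every pairwise comparison with Tukey's
#' Honest Significant Differences (studentized-range distribution).
#' Adjusted p values are floored at 1e-16 for numerical stability of the
#' studentized-range tail.
#'
#' @param x an `fa_pca` (groups taken from its metadata) or a numeric score
#'   matrix
#' @param groups group label per sample; defaults to the `by` metadata
#'   column when `x` is an `fa_pca`
#' @param components how many leading components to test (default 5)
#' @param by metadata column used for groups when `x` is an `fa_pca`
#' @return data frame with columns `component`, `group_a`, `group_b`,
#'   `diff` (mean score difference a - b), `p_adj`
#' @export
anova_tukey <- function(x, groups = NULL, components = 5, by = "group") {
  if (inherits(x, "fa_pca")) {
    if (is.null(groups)) groups <- x$meta[[by]]
    x <- x$scores
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("PC", seq_len(ncol(x)))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(groups) - nlevels(groups) < 1) {
    stop("no residual degrees of freedom: every group has a single sample")
  }
  m <- min(components, ncol(x))
  out <- vector("list", m)
  for (j in seq_len(m)) {
    fit <- stats::aov(x[, j] ~ groups)
    tk <- stats::TukeyHSD(fit)$groups
    pair <- strsplit(rownames(tk), "-", fixed = TRUE)
    out[[j]] <- data.frame(
      component = colnames(x)[j],
      group_a = vapply(pair, `[`, character(1), 1L),
      group_b = vapply(pair, `[`, character(1), 2L),
      diff = unname(tk[, "diff"]),
      p_adj = pmax(unname(tk[, "p adj"]), 1e-16),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
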