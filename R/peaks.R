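# Peak-to-bin assignment by 1-D k-means on retention times.
#
# Retention times drift between chromatographic runs, so peaks that were
# not matched to a standard are pooled across runs and grouped into K bins
# by Lloyd's algorithm with many uniform-random centroid initializations;
# the restart maximizing variance explained (SS_between / SS_total) wins.

# Nearest-centroid assignment in 1-D via interval search on the midpoints
# between sorted centroids.  A value exactly on a midpoint goes to the
# lower-retention-time centroid (deterministic tie-break).
.assign_nearest_1d <- function(values, centroids_sorted) {
  k <- length(centroids_sorted)
  if (k == 1L) return(rep(1L, length(values)))
  mids <- (centroids_sorted[-k] + centroids_sorted[-1]) / 2
  findInterval(values, mids, left.open = TRUE) + 1L
}

#' One-dimensional k-means (Lloyd's algorithm)
#'
#' Clusters scalar values (retention times) into `k` groups starting from
#' the given centroids.  Iterates until the assignment no longer changes or
#' `max_iter` is reached.  Empty clusters are re-seeded at the value
#' farthest from its nearest centroid, so the number of clusters stays
#' fixed.  Returned clusters are indexed by ascending centroid value.
#'
#' @param values numeric vector, non-empty
#' @param centers `k` initial centroids, or an integer `k` (then `k`
#'   distinct data quantiles are used)
#' @param max_iter iteration cap (default 300)
#' @param allow_empty permit `k` greater than the number of distinct values
#'   (clusters that cannot be filled stay empty); default `FALSE`
#' @return list of class `kmeans_1d`: `centroids` (ascending), `cluster`
#'   (index per value), `variance_explained` (SS_between / SS_total; defined
#'   as 1 when all values are identical), `ss_total`, `ss_within`,
#'   `iterations`.
#' @export
kmeans_1d <- function(values, centers, max_iter = 300, allow_empty = FALSE) {
  values <- as.numeric(values)
  if (!length(values)) stop("values must be non-empty")
  if (length(centers) == 1L && centers >= 1 && centers == round(centers)) {
    k <- as.integer(centers)
    centers <- stats::quantile(unique(values), probs = seq(0, 1, length.out = k),
                               names = FALSE, type = 7)
  }
  centroids <- sort(as.numeric(centers))
  k <- length(centroids)
  if (k < 1) stop("k must be at least 1")
  n_distinct <- length(unique(values))
  if (k > n_distinct && !allow_empty) {
    stop(sprintf("degenerate k: %d clusters requested for %d distinct values",
                 k, n_distinct))
  }
  cl <- rep(-1L, length(values))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    new_cl <- .assign_nearest_1d(values, centroids)
    # re-seed empty clusters at the worst-served value, one at a time
    repeat {
      counts <- tabulate(new_cl, nbins = k)
      empty <- which(counts == 0L)
      if (!length(empty) || length(unique(values)) < k) break
      d_near <- abs(values - centroids[new_cl])
      centroids[empty[1]] <- values[which.max(d_near)]
      centroids <- sort(centroids)
      new_cl <- .assign_nearest_1d(values, centroids)
    }
    changed <- !identical(new_cl, cl)
    cl <- new_cl
    sums <- vapply(seq_len(k), function(j) sum(values[cl == j]), numeric(1))
    counts <- tabulate(cl, nbins = k)
    nonempty <- counts > 0L
    centroids[nonempty] <- sums[nonempty] / counts[nonempty]
    centroids <- sort(centroids)
    if (!changed || iter >= max_iter) break
  }
  cl <- .assign_nearest_1d(values, centroids)
  gm <- mean(values)
  ss_total <- sum((values - gm)^2)
  ss_within <- sum((values - centroids[cl])^2)
  ve <- if (ss_total <= 0) 1 else 1 - ss_within / ss_total
  structure(list(centroids = centroids, cluster = cl,
                 variance_explained = ve, ss_total = ss_total,
                 ss_within = ss_within, iterations = iter),
            class = "kmeans_1d")
}

#' Assign chromatographic peaks to FA bins by restarted 1-D k-means
#'
#' Pools the retention times of all samples' unidentified peaks, clusters
#' them into bins with [kmeans_1d()] under `restarts` independent
#' uniform-random centroid initializations on `[min(rt), max(rt)]`, and
#' keeps the run with the greatest variance explained.  Peaks carrying a
#' `known_label` (matched to a standard) are pinned to their label's bin and
#' excluded from clustering by default, so the clustered bins fill the
#' remaining `k - n_known_labels` slots.  Final bins are ordered by
#' ascending centroid retention time; unidentified bins are named by
#' position (`bin01`, `bin02`, ...).
#'
#' @param peaks data frame with columns `sample_id`, `retention_time_min`,
#'   `area_fraction` and optionally `known_label` (NA/blank = unknown), as
#'   read by [read_peak_csv()]
#' @param k total number of FA bins (default 60)
#' @param restarts number of random initializations (default 1000)
#' @param seed integer master seed; the r-th restart draws the r-th set of
#'   initial centroids from the seeded stream, so results are reproducible
#'   given `(seed, restarts)` and best-of-n is nested in n.
#' @param cluster_known if `TRUE`, peaks with known labels participate in
#'   the clustering like any other peak (labels are then ignored)
#' @param allow_empty passed to [kmeans_1d()]
#' @return list of class `peak_assignment`: `best_run` ([kmeans_1d()]
#'   result), `variance_explained`, `bins` (data frame `bin`, `centroid_rt`,
#'   `known`), `peak_bin` (assigned bin label per input peak row),
#'   `sample_bins` (matrix sample x bin of summed area fractions),
#'   `restarts`, `seed`.
#' @export
assign_peaks <- function(peaks, k = 60, restarts = 1000, seed = NULL,
                         cluster_known = FALSE, allow_empty = FALSE) {
  stopifnot(is.data.frame(peaks))
  if (restarts < 1) stop("restarts must be at least 1")
  if (is.null(peaks$known_label)) peaks$known_label <- NA_character_
  if (cluster_known) peaks$known_label <- NA_character_
  known <- !is.na(peaks$known_label)
  known_labels <- sort(unique(peaks$known_label[known]))
  k_cluster <- k - length(known_labels)
  if (k_cluster < 1) {
    stop("k must exceed the number of distinct known labels")
  }
  rt <- peaks$retention_time_min[!known]
  if (length(rt) < k_cluster && !allow_empty) {
    stop(sprintf("degenerate k: %d unidentified peaks for %d bins",
                 length(rt), k_cluster))
  }
  if (!is.null(seed)) set.seed(seed)
  lo <- min(rt); hi <- max(rt)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- stats::runif(k_cluster, lo, hi)
    run <- kmeans_1d(rt, init, allow_empty = allow_empty)
    if (is.null(best) || run$variance_explained > best$variance_explained) {
      best <- run
    }
  }
  # merge pinned known bins with the clustered bins, ordered by centroid RT
  known_rt <- vapply(known_labels, function(lb) {
    mean(peaks$retention_time_min[known & peaks$known_label == lb])
  }, numeric(1))
  bins <- data.frame(
    label = c(known_labels, rep(NA_character_, k_cluster)),
    centroid_rt = c(known_rt, best$centroids),
    known = c(rep(TRUE, length(known_labels)), rep(FALSE, k_cluster)),
    cluster = c(rep(NA_integer_, length(known_labels)), seq_len(k_cluster)),
    stringsAsFactors = FALSE)
  bins <- bins[order(bins$centroid_rt), ]
  bins$bin <- ifelse(bins$known, bins$label,
                     sprintf("bin%02d", seq_len(nrow(bins))))
  rownames(bins) <- NULL

  peak_bin <- character(nrow(peaks))
  peak_bin[known] <- peaks$known_label[known]
  cl_to_bin <- bins$bin[match(seq_len(k_cluster), bins$cluster)]
  peak_bin[!known] <- cl_to_bin[best$cluster]

  samples <- unique(peaks$sample_id)
  sample_bins <- matrix(0, length(samples), nrow(bins),
                        dimnames = list(samples, bins$bin))
  idx <- cbind(match(peaks$sample_id, samples), match(peak_bin, bins$bin))
  for (i in seq_len(nrow(peaks))) {
    sample_bins[idx[i, 1], idx[i, 2]] <-
      sample_bins[idx[i, 1], idx[i, 2]] + peaks$area_fraction[i]
  }
  structure(list(best_run = best,
                 variance_explained = best$variance_explained,
                 bins = bins[c("bin", "centroid_rt", "known")],
                 peak_bin = peak_bin, sample_bins = sample_bins,
                 restarts = restarts, seed = seed),
            class = "peak_assignment")
}

#' @export
print.peak_assignment <- function(x, ...) {
  cat(sprintf("peak_assignment: %d bins, %d restarts, VE = %.4f\n",
              nrow(x$bins), x$restarts, x$variance_explained))
  invisible(x)
}
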