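# Synthetic-study generator.
#
# Emulates the statistical structure of the Illinois river otter study
# system: nine group-level FA signatures (otter tail and footpad adipose,
# crayfish, frogs, molluscs, and four fish orders) with printed means and
# standard deviations over 29 identified FA bins plus a pooled
# "other"/unidentified remainder; predators constructed as noisy convex
# mixtures of prey signatures with a known true diet; and peak tables with
# a known bin structure.

#' Reference group-level FA signatures for the river otter study system
#'
#' Mean and standard deviation of each identified FA (percent by mass) for
#' nine groups: river otter tail and footpad adipose, crayfish, frogs,
#' molluscs, and fish of four orders (Clupeiformes, Cypriniformes,
#' Perciformes, Siluriformes), together with per-group sample sizes from
#' the sampling design (fish counts follow the per-species sampling table:
#' 15 species totalling n = 90).  The 29 identified bins sum to roughly 94
#' percent per group; a pooled `other` bin holding the unidentified
#' remainder (sd 0) is appended so every column is a closed composition.
#'
#' @return list of class `fa_reference`: `bins` (30 labels incl. `other`),
#'   `groups`, `taxon` (taxon per group), `n` (named sample sizes), `mean`
#'   and `sd` (bins x groups matrices, percent)
#' @export
reference_signatures <- function() {
  f <- system.file("extdata", "fa_reference_means.csv", package = "fadiet",
                   mustWork = TRUE)
  g <- system.file("extdata", "fa_reference_groups.csv", package = "fadiet",
                   mustWork = TRUE)
  tab <- utils::read.csv(f, check.names = FALSE, stringsAsFactors = FALSE)
  grp <- utils::read.csv(g, stringsAsFactors = FALSE)
  groups <- grp$group
  mean_m <- as.matrix(tab[paste0(groups, "_mean")])
  sd_m <- as.matrix(tab[paste0(groups, "_sd")])
  dimnames(mean_m) <- dimnames(sd_m) <- list(tab$fa, groups)
  other_mean <- 100 - colSums(mean_m)
  mean_m <- rbind(mean_m, other = other_mean)
  sd_m <- rbind(sd_m, other = rep(0, length(groups)))
  n <- stats::setNames(grp$n, groups)
  taxon <- stats::setNames(grp$taxon, groups)
  structure(list(bins = rownames(mean_m), groups = groups, taxon = taxon,
                 n = n, mean = mean_m, sd = sd_m),
            class = "fa_reference")
}

#' @export
print.fa_reference <- function(x, ...) {
  cat(sprintf("fa_reference: %d FA bins x %d groups (total n = %d)\n",
              length(x$bins), length(x$groups), sum(x$n)))
  invisible(x)
}

# one taxon's (mean, sd) in percent -> n simulated compositions (fractions)
.simulate_compositions <- function(mean_pct, sd_pct, n) {
  m <- mean_pct / 100
  s <- sd_pct / 100
  k <- length(m)
  x <- matrix(rep(m, each = n), n, k)
  vary <- which(m > 0 & s > 0)
  for (j in vary) {
    # lognormal perturbation moment-matched to (m, s) before closure
    sigma2 <- log(1 + (s[j] / m[j])^2)
    x[, j] <- m[j] * exp(stats::rnorm(n, -sigma2 / 2, sqrt(sigma2)))
  }
  x / rowSums(x)
}

#' Simulate individual FA signatures for one group
#'
#' Draws each FA independently from a lognormal distribution
#' moment-matched to the target mean and standard deviation (a
#' logistic-normal scheme: normal perturbation on the log scale followed by
#' closure to sum one).  Bins with sd = 0 reproduce the mean exactly before
#' closure; bins with mean 0 stay at 0 (they are handled downstream by zero
#' replacement).  Closure makes the moment matching approximate; the
#' approximation is validated by the group-summary round trip.
#'
#' @param mean_pct,sd_pct numeric vectors in percent (same length), or a
#'   `fa_reference` passed as `mean_pct` with the group named in `group`
#' @param n number of individuals (>= 1)
#' @param seed optional integer seed
#' @param group group label for the generated samples (and the reference
#'   column when `mean_pct` is a `fa_reference`)
#' @param bins bin labels (default names of `mean_pct`)
#' @return an [fa_library()]
#' @export
simulate_individuals <- function(mean_pct, sd_pct = NULL, n, seed = NULL,
                                 group = "sim", bins = NULL) {
  if (inherits(mean_pct, "fa_reference")) {
    ref <- mean_pct
    if (!group %in% ref$groups) stop("unknown reference group: ", group)
    bins <- ref$bins
    sd_pct <- ref$sd[, group]
    mean_pct <- ref$mean[, group]
  }
  if (n < 1) stop("n must be at least 1")
  if (length(mean_pct) != length(sd_pct)) stop("mean and sd differ in length")
  if (any(mean_pct < 0) || any(sd_pct < 0)) stop("mean and sd must be >= 0")
  if (is.null(bins)) bins <- names(mean_pct)
  if (!is.null(seed)) set.seed(seed)
  x <- .simulate_compositions(mean_pct, sd_pct, n)
  colnames(x) <- bins
  fa_library(x,
             meta = data.frame(sample_id = sprintf("%s_%04d", group, seq_len(n)),
                               group = group, stringsAsFactors = FALSE),
             bins = bins)
}

#' Simulate a full prey library from the reference signatures
#'
#' Generates individuals for every prey group (crayfish, frog, mollusc and
#' the four fish orders) at the reference sample sizes.  Sample metadata
#' records the taxon (`group` column: fish, mollusc, frog, crayfish) and
#' the reference group (`species` column), so both taxon-level and
#' finer-grained analyses are possible.
#'
#' @param ref a `fa_reference` (default [reference_signatures()])
#' @param n named per-group sample sizes (default the reference ones)
#' @param seed optional integer seed
#' @return an [fa_library()]
#' @export
simulate_prey_library <- function(ref = reference_signatures(), n = NULL,
                                  seed = NULL) {
  prey_groups <- ref$groups[ref$taxon != "otter"]
  if (is.null(n)) n <- ref$n[prey_groups]
  if (!is.null(seed)) set.seed(seed)
  libs <- lapply(prey_groups, function(gr) {
    lib <- simulate_individuals(ref$mean[, gr], ref$sd[, gr], n[[gr]],
                                group = gr, bins = ref$bins)
    lib$meta$species <- gr
    lib$meta$group <- unname(ref$taxon[gr])
    lib$meta$sample_id <- sprintf("%s_%04d", gr, seq_len(n[[gr]]))
    lib
  })
  props <- do.call(rbind, lapply(libs, `[[`, "proportions"))
  meta <- do.call(rbind, lapply(libs, `[[`, "meta"))
  fa_library(props, meta = meta, bins = ref$bins)
}

# taxon-level (mean, sd) matrices: n-weighted across reference groups
.taxon_moments <- function(ref, taxa) {
  mean_m <- vapply(taxa, function(tx) {
    gr <- ref$groups[ref$taxon == tx]
    w <- ref$n[gr] / sum(ref$n[gr])
    drop(ref$mean[, gr, drop = FALSE] %*% w)
  }, numeric(length(ref$bins)))
  sd_m <- vapply(taxa, function(tx) {
    gr <- ref$groups[ref$taxon == tx]
    w <- ref$n[gr] / sum(ref$n[gr])
    drop(ref$sd[, gr, drop = FALSE] %*% w)
  }, numeric(length(ref$bins)))
  list(mean = mean_m, sd = sd_m)
}

#' Simulate predators as noisy convex mixtures of prey signatures
#'
#' Each predator's signature is built by (1) freshly resampling a mean
#' signature for every prey taxon (the mean of `prey_per_mean` simulated
#' individuals, by default the taxon's full reference sample size), (2)
#' mixing those taxon means at the true diet, and (3) applying per-FA
#' lognormal noise whose standard deviation is `noise_scale` times the
#' diet-weighted reference sd, followed by closure.
#'
#' @param true_diet simplex vector named by prey taxa (e.g. `fish`,
#'   `mollusc`, `frog`, `crayfish`)
#' @param ref a `fa_reference`
#' @param n number of predators
#' @param noise_scale multiplier on the diet-weighted reference sd used for
#'   the per-predator noise (default 1; 0 = deterministic mixtures)
#' @param prey_per_mean individuals drawn per taxon when resampling each
#'   predator's taxon means (default `NULL` = the taxon's reference sample
#'   size; 0 = use the reference means exactly)
#' @param seed optional integer seed
#' @return list of class `predator_sim`: `library` ([fa_library()]),
#'   `true_diet`
#' @export
simulate_predators <- function(true_diet, ref = reference_signatures(), n,
                               noise_scale = 1, prey_per_mean = NULL,
                               seed = NULL) {
  taxa <- names(true_diet)
  if (is.null(taxa)) stop("true_diet must be named by prey taxa")
  if (!all(taxa %in% ref$taxon)) {
    stop("taxa missing from the reference: ",
         paste(setdiff(taxa, ref$taxon), collapse = ", "))
  }
  if (any(true_diet < 0) || abs(sum(true_diet) - 1) > 1e-8) {
    stop("true_diet must be a simplex vector (non-negative, summing to 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  mom <- .taxon_moments(ref, taxa)
  k <- length(ref$bins)
  taxon_n <- vapply(taxa, function(tx) {
    sum(ref$n[ref$groups[ref$taxon == tx]])
  }, numeric(1))
  if (is.null(prey_per_mean)) prey_per_mean <- taxon_n
  mix_mean <- drop(mom$mean %*% true_diet) / 100
  mix_sd <- drop(mom$sd %*% true_diet) / 100
  x <- matrix(NA_real_, n, k, dimnames = list(NULL, ref$bins))
  for (i in seq_len(n)) {
    taxon_means <- if (any(prey_per_mean > 0)) {
      npm <- rep_len(prey_per_mean, length(taxa))
      vapply(seq_along(taxa), function(t_i) {
        tx <- taxa[t_i]
        colMeans(.simulate_compositions(mom$mean[, tx], mom$sd[, tx],
                                        npm[t_i]))
      }, numeric(k))
    } else {
      sweep(mom$mean, 2, colSums(mom$mean), "/")
    }
    base <- drop(taxon_means %*% true_diet)
    if (noise_scale > 0) {
      vary <- mix_mean > 0 & mix_sd > 0
      sigma2 <- ifelse(vary,
                       log(1 + (noise_scale * mix_sd / mix_mean)^2), 0)
      base <- base * exp(stats::rnorm(k, -sigma2 / 2, sqrt(sigma2)))
    }
    x[i, ] <- base / sum(base)
  }
  lib <- fa_library(x,
                    meta = data.frame(
                      sample_id = sprintf("pred_%04d", seq_len(n)),
                      group = "otter", deposit = "tail",
                      stringsAsFactors = FALSE),
                    bins = ref$bins)
  structure(list(library = lib, true_diet = true_diet),
            class = "predator_sim")
}

#' Simulate chromatographic peak tables with known bin structure
#'
#' Lays out `k` true retention-time centers `spacing` minutes apart and
#' gives every sample one peak per center, jittered by a normal deviate of
#' sd `jitter_sd` (run-to-run retention drift).  Peak areas are drawn from
#' a flat Dirichlet per sample.
#'
#' @param n_samples number of chromatographic runs
#' @param k number of true bins (default 60)
#' @param spacing center-to-center distance in minutes (default 1)
#' @param jitter_sd retention-time jitter sd in minutes
#' @param rt_min retention time of the first center (default 5 min)
#' @param seed optional integer seed
#' @return list: `peaks` (data frame `sample_id`, `retention_time_min`,
#'   `area_fraction`, `known_label` = NA, `true_bin`), `centers`
#' @export
simulate_peak_tables <- function(n_samples, k = 60, spacing = 1,
                                 jitter_sd = 0.02, rt_min = 5, seed = NULL) {
  if (spacing <= 0) stop("spacing must be positive")
  if (jitter_sd < 0) stop("jitter_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  centers <- rt_min + spacing * (seq_len(k) - 1)
  out <- lapply(seq_len(n_samples), function(i) {
    rt <- centers + stats::rnorm(k, 0, jitter_sd)
    a <- stats::rexp(k); a <- a / sum(a)
    data.frame(sample_id = sprintf("run_%03d", i),
               retention_time_min = rt, area_fraction = a,
               known_label = NA_character_, true_bin = seq_len(k),
               stringsAsFactors = FALSE)
  })
  list(peaks = do.call(rbind, out), centers = centers)
}

#' Simulate a complete synthetic study
#'
#' Bundles a prey library, a predator library with known true diet, and
#' peak tables, all regenerable bit-for-bit from `(parameters, seed)`.
#'
#' @param true_diet named simplex vector over prey taxa; default the
#'   4-taxon diet used throughout the package examples
#' @param n_predators number of predators (default 46)
#' @param noise_scale predator noise multiplier (default 1)
#' @param seed integer master seed
#' @param peaks also generate peak tables (default `FALSE`)
#' @return list of class `synthetic_study`: `prey`, `predators`,
#'   `true_diet`, `seed`, optionally `peak_tables`
#' @export
simulate_study <- function(true_diet = c(fish = 0.377, mollusc = 0.320,
                                         frog = 0.273, crayfish = 0.030),
                           n_predators = 46, noise_scale = 1, seed = NULL,
                           peaks = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  ref <- reference_signatures()
  prey <- simulate_prey_library(ref)
  pred <- simulate_predators(true_diet, ref, n = n_predators,
                             noise_scale = noise_scale)
  out <- list(prey = prey, predators = pred$library, true_diet = true_diet,
              seed = seed)
  if (peaks) out$peak_tables <- simulate_peak_tables(10, k = 60)
  structure(out, class = "synthetic_study")
}
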