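# Pipeline stages wired for scripted use: each stage reads/writes plain
# CSV/JSON, logs what it did, and is fully determined by (config, seed).

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.run_log <- function(stage, config) {
  list(stage = stage, package = "fadiet",
       version = as.character(utils::packageVersion("fadiet")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       config = config)
}

#' Pipeline stage: simulate a synthetic study to disk
#'
#' Writes `prey.csv`, `predators.csv` (signature CSVs) and `truth.json`
#' (true diet, seed, parameters, and the modeling note that unidentified FA
#' mass is pooled into a single `other` bin) into `out_dir`.
#'
#' @param out_dir output directory (created if needed)
#' @param diet named simplex vector over prey taxa
#' @param n_predators number of predators
#' @param noise_scale predator noise multiplier
#' @param seed integer seed
#' @return paths of the written files, invisibly
#' @export
pipeline_simulate <- function(out_dir,
                              diet = c(fish = 0.377, mollusc = 0.320,
                                       frog = 0.273, crayfish = 0.030),
                              n_predators = 46, noise_scale = 1, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(diet, n_predators = n_predators,
                          noise_scale = noise_scale, seed = seed)
  prey_path <- file.path(out_dir, "prey.csv")
  pred_path <- file.path(out_dir, "predators.csv")
  truth_path <- file.path(out_dir, "truth.json")
  write_signature_csv(study$prey, prey_path)
  write_signature_csv(study$predators, pred_path)
  log <- .run_log("simulate", list(diet = as.list(diet),
                                   n_predators = n_predators,
                                   noise_scale = noise_scale, seed = seed))
  log$true_diet <- as.list(diet)
  log$note <- paste("unidentified FA mass is pooled into a single 'other'",
                    "bin; its distribution over individual unidentified",
                    "bins is not modeled")
  .write_json(log, truth_path)
  invisible(c(prey = prey_path, predators = pred_path, truth = truth_path))
}

#' Pipeline stage: assign peaks from a peak CSV
#'
#' @param in_csv peak table CSV (see [read_peak_csv()])
#' @param out_csv output CSV of per-peak bin assignments
#' @param k,restarts,seed,cluster_known passed to [assign_peaks()]
#' @return the [assign_peaks()] result, invisibly
#' @export
pipeline_assign_peaks <- function(in_csv, out_csv, k = 60, restarts = 1000,
                                  seed = 1, cluster_known = FALSE) {
  peaks <- read_peak_csv(in_csv)
  res <- assign_peaks(peaks, k = k, restarts = restarts, seed = seed,
                      cluster_known = cluster_known)
  out <- cbind(peaks, bin = res$peak_bin)
  utils::write.csv(out, out_csv, row.names = FALSE, quote = FALSE)
  .write_json(c(.run_log("assign-peaks",
                         list(k = k, restarts = restarts, seed = seed)),
                list(variance_explained = res$variance_explained)),
              sub("\\.csv$", "_log.json", out_csv))
  invisible(res)
}

#' Pipeline stage: PCA with per-component group tests
#'
#' Writes `scores.csv`, `explained.csv`, `correlations.csv` and
#' `tukey.csv` into `out_dir`.
#'
#' @param in_csv signature CSV
#' @param out_dir output directory
#' @param by metadata column defining the ANOVA groups
#' @param components leading components to test
#' @return list with the `fa_pca` and the Tukey table, invisibly
#' @export
pipeline_pca <- function(in_csv, out_dir, by = "group", components = 5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lib <- read_signature_csv(in_csv)
  pca <- run_pca(lib)
  tk <- anova_tukey(pca, components = components, by = by)
  utils::write.csv(data.frame(sample_id = lib$meta$sample_id,
                              group = lib$meta[[by]], pca$scores),
                   file.path(out_dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(component = colnames(pca$scores),
                              explained = pca$explained),
                   file.path(out_dir, "explained.csv"), row.names = FALSE)
  utils::write.csv(data.frame(fa = rownames(pca$fa_correlations),
                              pca$fa_correlations),
                   file.path(out_dir, "correlations.csv"), row.names = FALSE)
  utils::write.csv(tk, file.path(out_dir, "tukey.csv"), row.names = FALSE)
  invisible(list(pca = pca, tukey = tk))
}

#' Pipeline stage: bootstrap diet estimation
#'
#' Fits the diet of every predator against taxon-level prey mean
#' signatures and bootstraps means and standard errors.  Writes
#' `diet.csv` (taxon, mean_percent, se_percent) and `diet_log.json`.
#'
#' @param prey_csv,predators_csv signature CSVs
#' @param out_dir output directory
#' @param reps bootstrap replicates
#' @param seed integer seed
#' @param eps zero-replacement floor
#' @param by prey taxon column
#' @param form KL form
#' @param calibration optional path to a CSV with columns `fa`,
#'   `coefficient` (identity when omitted)
#' @return the `diet_estimate`, invisibly
#' @export
pipeline_estimate_diet <- function(prey_csv, predators_csv, out_dir,
                                   reps = 500, seed = 1, eps = 1e-5,
                                   by = "group", form = "symmetric",
                                   calibration = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prey <- read_signature_csv(prey_csv)
  predators <- read_signature_csv(predators_csv)
  if ("deposit" %in% names(predators$meta) &&
      any(predators$meta$deposit == "tail")) {
    keep <- predators$meta$deposit == "tail"
    predators <- fa_library(predators$proportions[keep, , drop = FALSE],
                            meta = predators$meta[keep, , drop = FALSE],
                            bins = predators$bins)
  }
  cal <- NULL
  if (!is.null(calibration)) {
    ct <- utils::read.csv(calibration, stringsAsFactors = FALSE)
    cal <- ct$coefficient[match(prey$bins, ct$fa)]
    if (anyNA(cal)) stop("calibration file missing coefficients for some bins")
  }
  est <- bootstrap_diet(predators, prey, reps = reps, seed = seed, by = by,
                        eps = eps, form = form, calibration = cal)
  utils::write.csv(data.frame(taxon = names(est$proportions),
                              mean_percent = 100 * est$proportions,
                              se_percent = 100 * est$se),
                   file.path(out_dir, "diet.csv"), row.names = FALSE)
  .write_json(c(.run_log("estimate-diet",
                         list(reps = reps, seed = seed, eps = eps,
                              distance_form = form,
                              calibration = if (is.null(calibration))
                                "identity" else calibration)),
                list(diet_mean_percent = as.list(100 * est$proportions),
                     diet_se_percent = as.list(100 * est$se))),
              file.path(out_dir, "diet_log.json"))
  invisible(est)
}

#' Run the full pipeline on a synthetic study
#'
#' Composes the stages in analysis order — simulate, group summary,
#' ordination with group tests, diet estimation — writing every artifact
#' under `out_dir` together with a JSON run log.  Identical config and seed
#' produce byte-identical outputs.
#'
#' @param out_dir output directory
#' @param seed integer master seed
#' @param diet named true diet over prey taxa
#' @param n_predators number of predators
#' @param reps bootstrap replicates
#' @param components leading components to test
#' @return named list of stage results, invisibly
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         diet = c(fish = 0.377, mollusc = 0.320,
                                  frog = 0.273, crayfish = 0.030),
                         n_predators = 46, reps = 500, components = 5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  message("stage simulate: writing synthetic study")
  paths <- pipeline_simulate(out_dir, diet = diet,
                             n_predators = n_predators, seed = seed)
  message("stage summarize: group summary table")
  prey <- read_signature_csv(paths[["prey"]])
  utils::write.csv(group_summary(prey, by = "species"),
                   file.path(out_dir, "group_summary.csv"),
                   row.names = FALSE)
  message("stage pca: ordination and group tests")
  pca <- pipeline_pca(paths[["prey"]], file.path(out_dir, "pca"),
                      components = components)
  message("stage estimate-diet: QFASA with bootstrap")
  est <- pipeline_estimate_diet(paths[["prey"]], paths[["predators"]],
                                out_dir, reps = reps, seed = seed)
  .write_json(c(.run_log("pipeline",
                         list(seed = seed, diet = as.list(diet),
                              n_predators = n_predators, reps = reps,
                              components = components)),
                list(artifacts = list(out_dir = out_dir))),
              file.path(out_dir, "run_log.json"))
  invisible(list(paths = paths, pca = pca, diet = est))
}

#' Predominant-FA statistic from the reference signatures
#'
#' The sample-size weighted grand mean of the summed 16:0, 16:1, 18:0 and
#' 18:1 mean proportions over the nine reference groups — the share of the
#' four predominant FA across all samples of the study system.
#'
#' @param ref a `fa_reference` (default [reference_signatures()])
#' @param fa_set the predominant bins
#' @return percent, scalar
#' @export
predominant_fa_reference <- function(ref = reference_signatures(),
                                     fa_set = c("16:0", "16:1", "18:0", "18:1")) {
  sums <- colSums(ref$mean[fa_set, , drop = FALSE])
  sum(ref$n * sums) / sum(ref$n)
}
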