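test_that("reference signatures carry the published group values", {
  ref <- reference_signatures()
  expect_equal(ref$mean["16:0", "otter_tail"], 14.7)
  expect_equal(ref$sd["16:0", "otter_tail"], 3.33)
  expect_equal(ref$mean["20:1", "mollusc"], 8.8)
  expect_equal(ref$sd["20:1", "mollusc"], 2.98)
  expect_equal(ref$mean["22:2", "crayfish"], 0)
  expect_equal(ref$sd["22:2", "crayfish"], 0)
  expect_equal(ref$mean["18:1", "otter_tail"], 29)
  # every column is a closed composition once "other" is appended
  expect_equal(unname(colSums(ref$mean)), rep(100, 9))
  expect_true(all(ref$mean["other", ] > 0))
  expect_equal(unname(ref$n),
               c(46, 19, 14, 12, 37, 6, 15, 43, 26))
  expect_equal(length(ref$bins), 30)
})

test_that("simulated individuals honor degenerate and stochastic bins", {
  ref <- reference_signatures()
  # sd = 0 everywhere: every individual equals the (closed) mean
  lib <- simulate_individuals(c(a = 40, b = 60), c(0, 0), n = 5, seed = 1)
  expect_equal(lib$proportions,
               matrix(c(0.4, 0.6), 5, 2, byrow = TRUE,
                      dimnames = dimnames(lib$proportions)))
  # determinism: same seed, same library
  l1 <- simulate_individuals(ref, n = 50, seed = 9, group = "mollusc")
  l2 <- simulate_individuals(ref, n = 50, seed = 9, group = "mollusc")
  expect_identical(l1$proportions, l2$proportions)
  # closure and non-negativity
  expect_true(all(l1$proportions >= 0))
  expect_equal(rowSums(l1$proportions), rep(1, 50), ignore_attr = TRUE)
  # mean-zero bins never become positive
  zero_bins <- ref$mean[, "mollusc"] == 0
  expect_true(all(l1$proportions[, zero_bins] == 0))
})

test_that("moment matching round-trips the reference summaries", {
  ref <- reference_signatures()
  n <- 2000
  for (gr in c("otter_tail", "mollusc", "fish_perc")) {
    lib <- simulate_individuals(ref, n = n, seed = 11, group = gr)
    gs <- group_summary(lib)
    err <- abs(gs$mean - ref$mean[, gr])
    stoch <- ref$sd[, gr] > 0
    # stochastic bins: Monte-Carlo error band
    expect_true(all(err[stoch] <= 3 * ref$sd[stoch, gr] / sqrt(n)))
    # sd = 0 bins are only displaced by closure, a < 0.2 point effect
    expect_true(all(err[!stoch] <= 0.2))
    # generator spread is close to the target spread for bins of moderate
    # relative variability (heavy-tailed bins with sd >> mean have sample
    # sds too volatile for a sharp finite-n check)
    moderate <- stoch & ref$sd[, gr] <= 1.5 * ref$mean[, gr]
    expect_true(all(abs(gs$sd[moderate] - ref$sd[moderate, gr]) <=
                      pmax(0.2 * ref$sd[moderate, gr], 0.1)))
  }
})

test_that("noiseless predators recover the exact diet end to end", {
  # strictly positive toy reference: the generated mixture is an exact
  # member of the fitted model family, so recovery is sharp
  toy <- structure(list(
    bins = c("16:0", "18:1", "20:5n3", "other"),
    groups = c("fish", "mollusc"),
    taxon = c(fish = "fish", mollusc = "mollusc"),
    n = c(fish = 5, mollusc = 5),
    mean = cbind(fish = c(20, 40, 30, 10), mollusc = c(45, 15, 10, 30)),
    sd = cbind(fish = c(0, 0, 0, 0), mollusc = c(0, 0, 0, 0))),
    class = "fa_reference")
  rownames(toy$mean) <- rownames(toy$sd) <- toy$bins
  diet <- c(fish = 0.7, mollusc = 0.3)
  sim <- simulate_predators(diet, toy, n = 3, noise_scale = 0,
                            prey_per_mean = 0, seed = 1)
  expect_equal(sim$library$proportions[1, ], sim$library$proportions[3, ])
  basis <- prey_basis(toy$mean / 100)
  est <- estimate_diet(sim$library$proportions[1, ], basis, restarts = 0)
  expect_equal(est$proportions, diet, tolerance = 1e-6)

  # full reference: zero bins are eps-floored on the basis side only, so
  # recovery is exact up to the floor scale
  ref <- reference_signatures()
  diet4 <- c(fish = 0.5, mollusc = 0.3, frog = 0.15, crayfish = 0.05)
  sim4 <- simulate_predators(diet4, ref, n = 1, noise_scale = 0,
                             prey_per_mean = 0, seed = 1)
  est4 <- estimate_diet(sim4$library$proportions[1, ], taxon_basis(),
                        restarts = 0)
  expect_equal(est4$proportions[names(diet4)], diet4, tolerance = 1e-3)
  expect_error(simulate_predators(c(bird = 1), ref, n = 2), "missing")
  expect_error(simulate_predators(c(fish = 0.7), ref, n = 2), "simplex")
})

test_that("predators dominated by one taxon are identified as such", {
  ref <- reference_signatures()
  diet <- c(fish = 0.94, mollusc = 0.02, frog = 0.02, crayfish = 0.02)
  sim <- simulate_predators(diet, ref, n = 20, noise_scale = 0.2, seed = 5)
  basis <- taxon_basis(names(diet))
  props <- vapply(seq_len(20), function(i) {
    estimate_diet(sim$library$proportions[i, ], basis,
                  restarts = 0)$proportions
  }, numeric(4))
  expect_gt(mean(props["fish", ]), 0.85)
  expect_true(all(apply(props, 2, which.max) == 1))
})

test_that("peak-table simulation supports the three jitter regimes", {
  # no jitter: exact recovery, VE = 1
  pt0 <- simulate_peak_tables(4, k = 12, spacing = 1, jitter_sd = 0,
                              seed = 2)
  pa0 <- assign_peaks(pt0$peaks, k = 12, restarts = 20, seed = 1)
  expect_equal(pa0$variance_explained, 1)
  tab0 <- table(pa0$peak_bin, pt0$peaks$true_bin)
  expect_true(all(colSums(tab0 > 0) == 1))
  # small jitter (spacing/50): perfect recovery across seeds
  for (s in 1:5) {
    pt <- simulate_peak_tables(5, k = 12, spacing = 1, jitter_sd = 1 / 50,
                               seed = s)
    pa <- assign_peaks(pt$peaks, k = 12, restarts = 100, seed = s)
    tab <- table(pa$peak_bin, pt$peaks$true_bin)
    expect_true(all(colSums(tab > 0) == 1))
    expect_gt(pa$variance_explained, 0.99)
  }
  # heavy overlap (jitter = spacing): recovery degrades
  pth <- simulate_peak_tables(5, k = 12, spacing = 1, jitter_sd = 1,
                              seed = 3)
  pah <- assign_peaks(pth$peaks, k = 12, restarts = 100, seed = 3)
  tabh <- table(pah$peak_bin, pth$peaks$true_bin)
  expect_false(all(colSums(tabh > 0) == 1))
  expect_error(simulate_peak_tables(2, spacing = 0), "spacing")
})

test_that("simulate_study is regenerable bit for bit from its seed", {
  s1 <- simulate_study(seed = 77, n_predators = 4)
  s2 <- simulate_study(seed = 77, n_predators = 4)
  expect_identical(s1$prey$proportions, s2$prey$proportions)
  expect_identical(s1$predators$proportions, s2$predators$proportions)
  expect_equal(sum(s1$true_diet), 1)
  expect_true(all(s1$prey$proportions >= 0))
  expect_equal(rowSums(s1$predators$proportions), rep(1, 4),
               ignore_attr = TRUE)
  # taxa present at the reference sample sizes
  expect_equal(sort(unique(s1$prey$meta$group)),
               c("crayfish", "fish", "frog", "mollusc"))
  expect_equal(table(s1$prey$meta$group)[["fish"]], 90)
})
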