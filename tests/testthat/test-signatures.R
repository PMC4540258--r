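test_that("normalize_composition closes vectors and preserves ratios", {
  expect_equal(normalize_composition(c(2, 2)), c(0.5, 0.5))
  expect_equal(normalize_composition(c(50, 25, 25)), c(0.5, 0.25, 0.25))
  # scale invariance on random inputs
  set.seed(1)
  for (i in 1:20) {
    x <- runif(8)
    expect_equal(sum(normalize_composition(x)), 1, tolerance = 1e-12)
    expect_equal(normalize_composition(x), normalize_composition(13.7 * x))
  }
  expect_error(normalize_composition(c(0, 0)), "all entries zero")
  expect_error(normalize_composition(c(1, -0.1)), "negative")
})

test_that("renormalized reference otter-tail column has 18:1 = 29 / column sum", {
  ref <- reference_signatures()
  identified <- setdiff(ref$bins, "other")
  col <- ref$mean[identified, "otter_tail"]
  v <- normalize_composition(col)
  expect_equal(unname(v["18:1"]), 29 / sum(col), tolerance = 1e-12)
})

test_that("replace_zeros matches its closed form and leaves positive input alone", {
  expect_equal(replace_zeros(c(0, 1), eps = 1e-5),
               c(1e-5, 1) / (1 + 1e-5), tolerance = 1e-15)
  # strictly positive input with eps below the minimum entry: unchanged
  x <- c(0.3, 0.2, 0.5)
  expect_identical(replace_zeros(x, eps = 1e-5), x / sum(x))
  # direct formula (x + eps * [x < eps]) / Z
  x <- c(0, 0.5, 0.5); eps <- 5e-5
  y <- replace_zeros(x, eps)
  expect_equal(y, (x + eps * (x < eps)) / sum(x + eps * (x < eps)))
  expect_true(all(y > 0))
  expect_equal(sum(y), 1)
  expect_error(replace_zeros(x, eps = 0), "eps")
  expect_error(replace_zeros(x, eps = 0.01), "eps")
  # matrix input keeps closure row-wise
  m <- rbind(c(0, 1), c(0.5, 0.5))
  expect_equal(rowSums(replace_zeros(m)), c(1, 1))
})

test_that("group_summary reports percent means and n-1 sd, 0 for n = 1", {
  lib <- tiny_library()
  gs <- group_summary(lib)
  g1 <- gs[gs$group == "g1", ]
  expect_equal(g1$mean, c(30, 70))
  expect_equal(g1$sd, c(sd(c(0.2, 0.4)) * 100, sd(c(0.8, 0.6)) * 100))
  expect_equal(gs$sd[gs$group == "g2"], c(0, 0))
  # identical signatures -> zero sd
  lib2 <- fa_library(rbind(c(0.2, 0.8), c(0.2, 0.8)),
                     meta = data.frame(group = c("g", "g")))
  expect_equal(group_summary(lib2)$sd, c(0, 0))
  expect_error(group_summary(lib, by = "habitat"), "unknown grouping key")
})

test_that("group_summary recovers hand-computed three-sample summary", {
  lib <- fa_library(rbind(c(0.2, 0.8), c(0.4, 0.6), c(0.6, 0.4)),
                    meta = data.frame(group = rep("g", 3)))
  gs <- group_summary(lib)
  expect_equal(gs$mean, c(40, 60))
  expect_equal(gs$sd, c(20, 20))
})

test_that("predominant_fraction: closure, hand case, and invariances", {
  lib <- tiny_library()
  gs <- group_summary(lib)
  # all bins of a single-group library -> 100%
  one <- gs[gs$group == "g1", ]
  expect_equal(predominant_fraction(one, fa_set = c("16:0", "18:1")), 100)
  # two groups with subset sums 40 and 60, equal weights -> 50
  two <- data.frame(group = c("a", "a", "b", "b"),
                    fa = c("x", "y", "x", "y"),
                    n = 1, mean = c(15, 25, 35, 25), sd = 0)
  expect_equal(predominant_fraction(two, c("x", "y"), c(a = 1, b = 1)), 50)
  # invariant to bin order and weight rescaling
  shuffled <- two[c(3, 1, 4, 2), ]
  expect_equal(predominant_fraction(shuffled, c("y", "x"), c(a = 1, b = 1)), 50)
  expect_equal(predominant_fraction(two, c("x", "y"), c(a = 7, b = 7)), 50)
  w <- c(a = 2, b = 5)
  expect_equal(predominant_fraction(two, c("x", "y"), w),
               predominant_fraction(two, c("x", "y"), 3 * w))
  expect_error(predominant_fraction(two, c("x", "z")), "not present")
})

test_that("signature CSV round trip is lossless and rejects bad rows", {
  lib <- tiny_library()
  path <- withr::local_tempfile(fileext = ".csv")
  write_signature_csv(lib, path)
  back <- read_signature_csv(path)
  expect_equal(back$proportions, lib$proportions, tolerance = 1e-10)
  expect_equal(back$meta$group, lib$meta$group)
  expect_equal(back$bins, lib$bins)

  # percent rows accepted with the renormalize flag
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,species,deposit,16:0,18:1",
               "s1,g,sp,none,40,60"), p2)
  expect_error(read_signature_csv(p2), "does not sum to 1")
  lib2 <- read_signature_csv(p2, renormalize = TRUE)
  expect_equal(unname(lib2$proportions[1, ]), c(0.4, 0.6))

  # negative and non-numeric cells are rejected with their location
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,species,deposit,16:0,18:1",
               "s1,g,sp,none,-0.2,1.2"), p3)
  expect_error(read_signature_csv(p3), "negative value at row 1, column '16:0'")
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,species,deposit,16:0,18:1",
               "s1,g,sp,none,abc,1"), p4)
  expect_error(read_signature_csv(p4), "non-numeric value at row 1, column '16:0'")
  p5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,16:0,18:1", "s1,0.5,0.5"), p5)
  expect_error(read_signature_csv(p5), "missing required columns")
})

test_that("every constructor and transform preserves closure", {
  set.seed(42)
  x <- matrix(rexp(60), 6, 10)
  lib <- fa_library(x, normalize = TRUE)
  expect_equal(rowSums(lib$proportions), rep(1, 6), ignore_attr = TRUE)
  expect_equal(rowSums(replace_zeros(lib)$proportions), rep(1, 6),
               ignore_attr = TRUE)
  expect_error(fa_library(x), "not summing to 1")
  expect_error(fa_library(matrix(c(-1, 2, 1, 1), 2, 2)), "non-negative")
})
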