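test_that("likely-carrier rule fires when any site drops below threshold", {
  expect_true(call_carrier(c(0.22, 0.22, 0.21)))
  expect_true(call_carrier(c(0.40, 0.32, 0.30)))   # a alone is above 1/3
  expect_false(call_carrier(c(0.50, 0.50, 0.50)))
  expect_false(call_carrier(c(1 / 3, 1 / 3, 1 / 3)))  # strictly below
  expect_error(call_carrier(c(0.2, NA, 0.3)))
})

test_that("carrier flagging is monotone in the scaled proportions", {
  set.seed(23)
  cfg <- sma_config()
  for (i in 1:50) {
    pi0 <- runif(3, 0.05, 0.7)
    flagged <- call_carrier(pi0, cfg)
    lower <- pmax(pi0 - runif(3, 0, 0.3), 0)
    if (flagged) expect_true(call_carrier(lower, cfg))
  }
})

test_that("genotype estimation matches ratio candidates then theta", {
  # exact centroids
  expect_identical(estimate_genotype(0.75, c(0.5, 0.5, 0.5)), "1:2")
  expect_identical(estimate_genotype(1.0, c(1 / 3, 1 / 3, 1 / 3)), "1:3")
  expect_identical(estimate_genotype(0.5, c(1, 1, 1)), "1:1")
  # conflicting signals yield inconclusive (theta says ~4 copies, ratios ~1:2)
  expect_identical(estimate_genotype(0.936, c(23 / 30, 19 / 36, 18 / 37)),
                   "inconclusive")
  # ratios matching nothing yield inconclusive
  expect_identical(estimate_genotype(0.75, c(0.75, 0.72, 0.78)),
                   "inconclusive")
  # all ratios undefined yields inconclusive
  expect_identical(estimate_genotype(0.75, c(NA_real_, NA_real_, NA_real_)),
                   "inconclusive")
  # the median protects against one wild site
  expect_identical(estimate_genotype(0.76, c(0.5, 0.52, 3)), "1:2")
})

test_that("silent-carrier rule needs both variants plus theta and pi", {
  both <- data.frame(hgvs_label = c("g.27134T>G", "g.27706_27707delAT"),
                     supporting = c(12L, 14L), covering = c(30L, 31L),
                     stringsAsFactors = FALSE)
  cc <- fake_counts("sc", 15, 15, 30, dup = both)
  r <- detect_silent_carrier(cc, theta = 0.76, pi = c(0.49, 0.51, 0.50))
  expect_true(r$flag)
  r2 <- detect_silent_carrier(cc, theta = 0.52, pi = c(0.5, 0.5, 0.5))
  expect_true(r2$flag)   # 2:0 configuration
  # theta near 1 is inconsistent with a 2+0/2+1 haplotype
  r3 <- detect_silent_carrier(cc, theta = 1.0, pi = c(0.5, 0.5, 0.5))
  expect_false(r3$flag)
  expect_true(any(grepl("inconsistent with 2\\+0/2\\+1", r3$notes)))
  # pi far from 1/2 fails
  expect_false(detect_silent_carrier(cc, 0.75, c(0.3, 0.5, 0.5))$flag)

  absent <- both
  absent$supporting <- c(0L, 0L)
  cc2 <- fake_counts("ns", 15, 15, 30, dup = absent)
  expect_false(detect_silent_carrier(cc2, 0.75, c(0.5, 0.5, 0.5))$flag)
  one <- both
  one$supporting[2] <- 0L
  cc3 <- fake_counts("half", 15, 15, 30, dup = one)
  expect_false(detect_silent_carrier(cc3, 0.75, c(0.5, 0.5, 0.5))$flag)
})

test_that("unassessable variants never raise the silent flag", {
  nocov <- data.frame(hgvs_label = c("g.27134T>G", "g.27706_27707delAT"),
                      supporting = c(0L, 0L), covering = c(0L, 0L),
                      stringsAsFactors = FALSE)
  cc <- fake_counts("nc", 15, 15, 30, dup = nocov)
  r <- detect_silent_carrier(cc, 0.75, c(0.5, 0.5, 0.5))
  expect_false(r$flag)
  expect_true(any(grepl("unassessable", r$notes)))
})

test_that("full sample classification composes the three rules", {
  cc <- fake_counts("norm", 30, 30, 30)
  call <- classify_sample(cc, theta = 1.0, pi = c(0.5, 0.5, 0.5),
                          raw_ratios = c(1, 1, 1))
  expect_false(call$likely_carrier)
  expect_identical(call$genotype_estimate, "not-carrier")
  expect_false(call$silent_carrier_flag)

  carrier <- fake_counts("car", 22, 30, 28,
                         d1 = c(a = 15L, b = 15L, c = 13L),
                         d2 = c(a = 42L, b = 41L, c = 38L))
  call2 <- classify_sample(carrier, theta = 0.842,
                           pi = c(0.222, 0.226, 0.215),
                           raw_ratios = c(15 / 42, 15 / 41, 13 / 38))
  expect_true(call2$likely_carrier)
  expect_identical(call2$genotype_estimate, "1:2")

  # a missing proportion never classifies silently
  call3 <- classify_sample(cc, theta = 1.0, pi = c(NA, 0.5, 0.5),
                           raw_ratios = c(NA, 1, 1))
  expect_true(is.na(call3$likely_carrier))
  expect_identical(call3$genotype_estimate, "inconclusive")
  expect_true(any(grepl("inconclusive", call3$notes)))

  # an SMN1-null pattern is noted but not called
  call4 <- classify_sample(cc, theta = 0.5, pi = c(0, 0, 0),
                           raw_ratios = c(0, 0, 0))
  expect_true(call4$likely_carrier)
  expect_true(any(grepl("absence of SMN1", call4$notes)))
})

test_that("configuration round-trips through a key-value file", {
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("carrier_pi_threshold: 0.30",
               "theta_tolerance: 0.10",
               "variant_min_support: 5"), cfg_file)
  cfg <- read_sma_config(cfg_file)
  expect_equal(cfg$carrier_pi_threshold, 0.30)
  expect_equal(cfg$theta_tolerance, 0.10)
  expect_identical(cfg$variant_min_support, 5L)
  expect_equal(cfg$ratio_tolerance, 0.15)   # untouched default
  expect_false(call_carrier(c(0.31, 0.5, 0.5), cfg))
  expect_true(call_carrier(c(0.31, 0.5, 0.5), sma_config()))
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_key: 1", bad)
  expect_error(read_sma_config(bad), "unknown configuration key")
})
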