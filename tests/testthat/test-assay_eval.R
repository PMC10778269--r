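test_that("genome-equivalent arithmetic matches the 3.3 pg haploid mass", {
  expect_equal(genome_equivalents(20), 3030L)
  expect_equal(genome_equivalents(0.0066), 1L)
  expect_equal(genome_equivalents(40), 6061L)
  expect_error(genome_equivalents(0), "positive")
})

test_that("theoretical and coverage-based thresholds are reciprocals", {
  t1 <- theoretical_lod_percent(3030)
  expect_equal(t1$reported, 0.03)
  expect_equal(t1$value, 100 / 3030)
  expect_equal(theoretical_lod_percent(1)$value, 100)
  expect_equal(theoretical_lod_percent(1000)$value, 0.1)
  expect_error(theoretical_lod_percent(0), ">= 1")

  expect_equal(round(coverage_threshold_percent(837), 2), 0.12)
  expect_equal(coverage_threshold_percent(100), 1)
  expect_equal(coverage_threshold_percent(407), 100 / 407)
  expect_error(coverage_threshold_percent(0.5), ">= 1")
})

test_that("LoD rule returns the lowest uninterruptedly detected level", {
  ladder <- c(0.03, 0.1, 0.2, 0.3, 1, 1.2, 5, 25, 50)
  tb <- data.frame(expected_vaf_percent = ladder,
                   detected = ladder >= 0.1)
  expect_equal(estimate_lod(tb), 0.1)

  tb$detected <- ladder >= 0.3
  expect_equal(estimate_lod(tb), 0.3)

  tb$detected <- TRUE
  expect_equal(estimate_lod(tb), 0.03)

  tb$detected <- FALSE
  expect_warning(expect_true(is.na(estimate_lod(tb))), "no level detected")

  # isolated detection below an undetected level triggers the warning path
  tb$detected <- ladder %in% c(0.1, 1, 1.2, 5, 25, 50)
  expect_warning(lod <- estimate_lod(tb), "interrupted")
  expect_equal(lod, 1)
  expect_error(estimate_lod(data.frame(expected_vaf_percent = 0,
                                       detected = FALSE)), "nonzero")
})

test_that("linearity matches closed-form OLS and is affine-invariant", {
  tb <- data.frame(expected_vaf_percent = c(0, 1, 2),
                   observed_vaf_percent = c(0.1, 0.8, 2.1))
  fit <- linearity(tb)
  oracle <- bf_ols(tb$expected_vaf_percent, tb$observed_vaf_percent)
  expect_equal(fit$slope, oracle$slope)
  expect_equal(fit$intercept, oracle$intercept)
  expect_equal(fit$r_squared, oracle$r_squared)
  expect_equal(fit$slope, 1.0)
  expect_equal(fit$r_squared, 1 - 0.06 / 2.06)

  ident <- data.frame(expected_vaf_percent = c(0.1, 1, 5, 25),
                      observed_vaf_percent = c(0.1, 1, 5, 25))
  # exact collinear input trips lm's perfect-fit note; the fit is the point
  fit_id <- suppressWarnings(linearity(ident))
  expect_equal(fit_id$r_squared, 1)
  expect_equal(fit_id$slope, 1)
  doubled <- transform(ident, observed_vaf_percent = 2 * observed_vaf_percent)
  fit_2x <- suppressWarnings(linearity(doubled))
  expect_equal(fit_2x$r_squared, 1)
  expect_equal(fit_2x$slope, 2)
  # affine rescaling of both axes leaves R^2 unchanged
  scaled <- data.frame(expected_vaf_percent = 3 * tb$expected_vaf_percent + 1,
                       observed_vaf_percent = 5 * tb$observed_vaf_percent - 2)
  expect_equal(linearity(scaled)$r_squared, fit$r_squared)
  expect_error(linearity(ident[1:2, ]), "at least 3")
})

test_that("sensitivity and specificity handle empty margins as undefined", {
  ss <- sensitivity_specificity(list(tp = 10, fn = 7, tn = 6, fp = 0))
  expect_equal(round(ss$sensitivity, 3), 0.588)
  expect_equal(ss$specificity, 1)
  und <- sensitivity_specificity(list(tp = 0, fn = 0, tn = 3, fp = 1))
  expect_true(is.na(und$sensitivity))
  expect_equal(und$specificity, 0.75)
  cmp <- method_comparison(reference = c(TRUE, TRUE, FALSE, FALSE),
                           alternative = c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(unlist(cmp[c("tp", "fn", "tn", "fp")]),
               c(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
})

test_that("dilution points aggregate replicates with any-replicate detection", {
  fx <- default_locus_spec(seed = 61L)
  cfg <- library_config(target_umi_depth = 60, seed = 61)
  tb <- run_dilution_series(c(0, 50), replicates = 2, fx$locus, fx$spec,
                            fx$panel, cfg, seed = 61)
  expect_equal(nrow(tb), 2L)
  zero <- tb[tb$expected_vaf_percent == 0, ]
  expect_false(zero$detected)
  expect_equal(zero$supporting_families, 0L)
  hi <- tb[tb$expected_vaf_percent == 50, ]
  expect_true(hi$detected)
  # observed VAF within 3 binomial SD of 50% at the realized depth
  expect_lt(abs(hi$observed_vaf_percent - 50), 3 * sqrt(2500 / 120))
  detail <- attr(tb, "replicates")
  expect_equal(nrow(detail), 4L)
})

test_that("induced chimeras surface as nonzero blank counts", {
  fx <- default_locus_spec(seed = 71L)
  cfg <- library_config(target_umi_depth = 150, seed = 71)
  lob0 <- estimate_lob(2, fx$locus, fx$spec, fx$panel, cfg, seed = 71)
  expect_equal(lob0$max_supporting, 0L)
  expect_equal(lob0$percent_vaf, 0)

  cfg$chimera_rate <- 0.05
  lob <- estimate_lob(2, fx$locus, fx$spec, fx$panel, cfg, seed = 71)
  expect_gt(lob$max_supporting, 0L)
  fams <- 150 * 2
  # injected chimera count scale: about rate * families per run
  expect_lt(lob$max_supporting, 0.05 * fams * 4)
})
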