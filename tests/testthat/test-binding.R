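test_that("pIC50 / IC50 conversion is exact and invertible", {
  expect_equal(pic50_to_ic50(9), 1)
  expect_equal(ic50_to_pic50(1), 9)
  # the strong-binder boundary pIC50 = 6.3 corresponds to ~501 nM,
  # conventionally rounded to 500 nM
  expect_equal(pic50_to_ic50(6.3), 10^2.7)
  expect_lt(abs(pic50_to_ic50(6.3) - 500) / 500, 0.01)
  set.seed(3)
  p <- runif(100, 3, 9)
  expect_equal(ic50_to_pic50(pic50_to_ic50(p)), p, tolerance = 1e-12)
  expect_error(ic50_to_pic50(c(10, -1)), "strictly positive")
})

test_that("binder classes follow the pIC50 thresholds with open boundaries", {
  calls <- classify_affinity(c(6.658, 6.315, 6.31, 6.3, 5.31, 5.3, 4.0),
                             scale = "pic50")
  expect_equal(calls$binder_class,
               c("strong", "strong", "strong", "weak", "weak", "none", "none"))
  # spurious leading minus signs read as positive, with a message
  expect_message(out <- classify_affinity(-6.658, scale = "pic50"),
                 "read as positive")
  expect_equal(out$binder_class, "strong")
})

test_that("IC50 tiers use half-open nM bins and censoring yields none", {
  calls <- classify_affinity(c(16.96, 49.99, 50, 499, 500, 4999, 5000, 9000),
                             scale = "ic50_nM")
  expect_equal(calls$affinity_tier,
               c("high", "high", "intermediate", "intermediate",
                 "low", "low", "none", "none"))
  cens <- classify_affinity(5000, scale = "ic50_nM", censored = TRUE)
  expect_equal(cens$affinity_tier, "none")
  expect_equal(cens$binder_class, "none")
})

test_that("per-locus counting conserves the number of measured alleles", {
  meas <- data.frame(allele = c("a1", "a2", "a3", "b1", "b2"),
                     locus = c("DRB1", "DRB1", "DRB1", "DQ", "DQ"),
                     scale = "pic50",
                     value = c(6.5, 5.5, 4.0, 7.1, 5.9),
                     stringsAsFactors = FALSE)
  out <- locus_binder_counts(meas)
  drb1 <- out$counts[out$counts$locus == "DRB1", ]
  expect_equal(drb1$n_strong, 1L)
  expect_equal(drb1$n_weak, 1L)
  expect_equal(drb1$n_none, 1L)
  expect_equal(out$total_binders, 4L)
  expect_equal(sum(out$counts[, c("n_strong", "n_weak", "n_none")]),
               nrow(meas))

  empty <- locus_binder_counts(meas[0, ])
  expect_equal(empty$total_binders, 0L)

  dup <- rbind(meas, meas[1, ])
  expect_error(locus_binder_counts(dup), "duplicate")
})

test_that("panel summaries count tiers and report the best affinity", {
  panels <- allele_panels()
  meas <- data.frame(allele = c("DRB1*01:01", "DQ7", "DQ8"),
                     scale = "ic50_nM",
                     value = c(40, 400, 4000),
                     stringsAsFactors = FALSE)
  ps <- panel_summary(meas, panels)
  sus <- ps[ps$role == "susceptibility", ]
  expect_equal(sus$n_high, 1L)
  expect_equal(sus$n_intermediate, 1L)
  expect_equal(sus$n_low, 1L)
  expect_equal(sus$best_ic50_nM, 40)
  expect_equal(sus$best_tier, "high")
  # protection alleles were not measured: reported missing, not imputed
  pro <- ps[ps$role == "protection", ]
  expect_equal(pro$n_strong + pro$n_weak, 0L)
  expect_match(pro$missing_alleles, "DRB1\\*03:01")
})

test_that("the reference affinity row yields the published best binder", {
  fx <- load_reference_data()
  sig <- fx$affinities[fx$affinities$peptide_id == "SIGSSSEESAEVATEEVK", ]
  ps <- panel_summary(sig)
  sus <- ps[ps$role == "susceptibility", ]
  expect_equal(sus$best_ic50_nM, 0.53)
  expect_equal(sus$best_tier, "high")
  expect_equal(sus$missing_alleles, "")
})
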