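test_that("feature assembly maps evidence onto the 16 canonical factors", {
  # no evidence anywhere: all-zero raw vector
  f0 <- build_features()
  expect_length(f0, 16L)
  expect_true(all(f0 == 0))

  fx <- load_reference_data()
  bc <- fx$binder_counts
  row <- bc[bc$peptide_id == "DTQAIVQNNDSTE", ]
  f <- build_features(binder_counts = row)
  expect_equal(unname(f[1:6]), c(7, 1, 5, 1, 4, 2))

  # cytokine max score feeds the SVM factor; bioactivity tags are binary
  cyt <- data.frame(cytokine = "IL10", n_inducing = 2L, score_max = 0.9)
  tags <- data.frame("function" = "anti_inflammatory", check.names = FALSE)
  f <- build_features(cytokines = cyt, tags = tags)
  expect_equal(unname(f[13]), 0.9)
  expect_equal(unname(f[16]), 1)
  # an il10_inducer tag substitutes for a missing IL-10 record
  f <- build_features(tags = data.frame("function" = "il10_inducer",
                                        check.names = FALSE))
  expect_equal(unname(f[13]), 1)
})

test_that("panel-max normalization scales counts by fixed panel sizes", {
  raw <- matrix(0, 2, 16)
  raw[1, 4] <- 6    # DRB1-strong count
  raw[1, 9] <- 0.8  # IL-4 score
  raw[2, 9] <- 1.6
  raw[1, 7] <- 3    # full susceptibility panel
  norm <- normalize_features(raw, "panel-max")
  expect_equal(unname(norm[1, 4]), 0.5)       # 6 of 12 DRB1 alleles
  expect_equal(unname(norm[1, 7]), 1)         # 3 of 3 panel alleles
  expect_equal(unname(norm[1, 9]), 0.5)       # batch max 1.6
  expect_equal(unname(norm[2, 9]), 1)
  expect_true(all(norm >= 0 & norm <= 1))
})

test_that("batch-max normalization has fixed points and keeps zeros", {
  raw <- matrix(c(2, 4, 0, 0), 2, 2)
  raw <- cbind(raw, matrix(0, 2, 14))
  norm <- normalize_features(raw, "batch-max")
  expect_equal(norm[, 1], c(0.5, 1))  # the batch max maps to 1
  expect_true(all(norm[, 2] == 0))    # all-zero column stays zero
  expect_true(all(norm >= 0 & norm <= 1))
  # negative SVM scores are floored at zero under panel-max
  raw2 <- matrix(0, 1, 16); raw2[1, 10] <- -0.5
  expect_equal(unname(normalize_features(raw2, "panel-max")[1, 10]), 0)
})

test_that("radar areas match closed forms and the shoelace oracle", {
  expect_equal(radar_area(rep(0, 16)), 0)
  expect_equal(radar_area(rep(1, 16)), 8 * sin(pi / 8))
  # a single nonzero axis spans no area
  r <- rep(0, 16); r[5] <- 1
  expect_equal(radar_area(r), 0)
  expect_equal(radar_area(r, 4:9), 0)
  expect_error(radar_area(rep(1, 15)), "length 16")
  expect_error(radar_area(rep(1, 16), c(4, 6)), "contiguous")

  set.seed(9)
  for (i in seq_len(500)) {
    r <- runif(16)
    expect_equal(radar_area(r), shoelace_radar_area(r), tolerance = 1e-9)
  }
})

test_that("areas scale quadratically and sectors partition the cycle", {
  set.seed(13)
  for (i in seq_len(50)) {
    r <- runif(16)
    c_ <- runif(1, 0.1, 2)
    expect_equal(radar_area(c_ * r), c_^2 * radar_area(r), tolerance = 1e-12)
    expect_equal(radar_area(c_ * r, 4:9), c_^2 * radar_area(r, 4:9),
                 tolerance = 1e-12)
  }
  # the cyclic total decomposes into the chains 1..16 plus the closing edge
  r <- runif(16)
  chain <- radar_area(r, 1:16)
  closing <- 0.5 * sin(2 * pi / 16) * r[16] * r[1]
  expect_equal(radar_area(r), chain + closing, tolerance = 1e-12)
})

test_that("verdicts follow the margin and floor rules", {
  expect_equal(score_verdict(0.5, 0.1), "allergenic_dominant")
  expect_equal(score_verdict(0.1, 0.5), "tolerogenic_dominant")
  expect_equal(score_verdict(0, 0), "inert")
  expect_equal(score_verdict(0.005, 0.009), "inert")
  expect_equal(score_verdict(0.2, 0.21), "dual")
  expect_equal(score_verdict(c(0.5, 0), c(0.1, 0)),
               c("allergenic_dominant", "inert"))
})

test_that("integrated screening of the reference tables is coherent", {
  fx <- load_reference_data()
  cols <- c("protein_id", "start", "end", "sequence", "source")
  peps <- rbind(fx$is_peptides[cols], fx$iv_peptides[cols])
  sc <- screen_peptides(peps,
                        binder_counts = fx$binder_counts,
                        affinities = fx$affinities,
                        cytokines = fx$cytokines,
                        bioactivity = fx$bioactivity)
  expect_equal(nrow(sc), 31L)
  norm <- as.matrix(sc[, paste0("norm_", allerscreen:::FACTOR_NAMES)])
  expect_true(all(norm >= 0 & norm <= 1))
  expect_true(all(sc$allergenic_area >= 0))
  expect_true(all(sc$total_area <= 8 * sin(pi / 8) + 1e-12))
  # a peptide with evidence only in its strong-binder factors scores
  # allergenic-dominant
  ssn <- sc[sc$peptide_id == "SSNICNISCDK" & sc$source == "IS", ]
  expect_equal(ssn$verdict, "allergenic_dominant")
})
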