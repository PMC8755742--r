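make_raw <- function(m) {
  dimnames(m) <- list(sprintf("s%d", seq_len(nrow(m))),
                      sprintf("a%d", seq_len(ncol(m))))
  af_abundance(m, "raw")
}

test_that("hybridization factors are the median control ratio", {
  ## controls uniformly 2x their reference -> factor 0.5
  ref <- c(a1 = 10, a2 = 20)
  m <- make_raw(cbind(c(20, 10), c(40, 20)))
  h <- hybridization_normalize(m, c("a1", "a2"), ref)
  expect_equal(unname(h$factors), c(0.5, 1))
  expect_equal(unclass(h$abundance)["s2", ], unclass(m)["s2", ])
  ## post-condition: per-sample median control ratio is 1
  ratios <- sweep(unclass(h$abundance)[, c("a1", "a2")], 2, ref, "/")
  expect_equal(unname(apply(ratios, 1, median)), c(1, 1))
  expect_error(hybridization_normalize(m, character(0)), "no control")
})

test_that("planted hybridization factors are recovered exactly", {
  sim <- simulate_cohort(small_config(seed = 8))
  ctl <- sim$annotation$analyte_id[sim$annotation$is_control]
  h <- hybridization_normalize(sim$abundance, ctl,
                               sim$truth$control_reference)
  expect_lt(max(abs(h$factors * sim$truth$samples$hyb_factor - 1)), 1e-6)
})

test_that("median normalization matches a hand-worked toy and inverts constants", {
  ## 3 samples x 5 analytes, one bin; sample 2 is uniformly 3x the others
  base <- matrix(rep(c(10, 20, 30, 40, 50), each = 3), 3, 5)
  base[2, ] <- base[2, ] * 3
  m <- make_raw(base)
  mn <- median_normalize(m, rep(1, 5))
  ## analyte medians are the unscaled values, so sample 2's factor is 1/3
  expect_equal(unname(mn$factors[, 1]), c(1, 1 / 3, 1))
  expect_equal(unclass(mn$abundance)[2, ], unclass(m)[1, ],
               ignore_attr = TRUE)

  ## two bins perturbed by different constants are corrected independently
  b2 <- matrix(rep(c(8, 16, 24, 32), each = 4), 4, 4)
  b2[3, 1:2] <- b2[3, 1:2] * 5   # bin 1 perturbation
  b2[3, 3:4] <- b2[3, 3:4] * 0.2 # bin 2 perturbation
  m2 <- make_raw(b2)
  mn2 <- median_normalize(m2, c(1, 1, 2, 2))
  expect_equal(unname(mn2$factors[3, ]), c(1 / 5, 5))
  expect_equal(unclass(mn2$abundance)[3, ], unclass(m2)[1, ],
               ignore_attr = TRUE)

  ## single sample equals its own median -> all factors 1
  single <- make_raw(matrix(c(3, 7, 11), 1, 3))
  expect_equal(unname(median_normalize(single, rep(1, 3))$factors[1, 1]), 1)
  expect_error(median_normalize(m, c(1, 1, NA, 1, 1)), "dilution bin")
})

test_that("plate calibration returns unit factors on a matched plate", {
  m <- make_raw(matrix(c(10, 10, 20, 20), 2, 2))
  p <- plate_calibrate(m, c("P1", "P1"))
  expect_true(all(p$factors == 1))
  expect_identical(unclass(p$abundance), unclass(m))
  ## plate medians at 2x the reference -> factors 0.5
  p2 <- plate_calibrate(m, c("P1", "P1"),
                        reference = c(a1 = 5, a2 = 10))
  expect_true(all(p2$factors == 0.5))
  expect_true(all(unclass(p2$abundance) == unclass(m) / 2))
})

test_that("planted plate factors are inverted against the true reference", {
  sim <- simulate_cohort(small_config(seed = 9))
  tr <- sim$truth
  ## remove hybridization scaling exactly, then calibrate against the
  ## plate-free signal medians
  h <- hybridization_normalize(sim$abundance,
                               sim$annotation$analyte_id[sim$annotation$is_control],
                               tr$control_reference)
  plate_of <- setNames(sim$metadata$plate_id, sim$metadata$sample_id)
  recovered <- lapply(rownames(tr$plate_factors), function(p) {
    idx <- sim$metadata$plate_id == p
    ref <- apply(2^tr$log2_signal[idx, , drop = FALSE], 2, median)
    pc <- plate_calibrate(h$abundance, plate_of, reference = ref)
    pc$factors[p, ] * tr$plate_factors[p, ]
  })
  expect_lt(max(abs(unlist(recovered) - 1)), 1e-6)
})

test_that("log2 transform is exact and guarded", {
  m <- make_raw(matrix(c(1024, 1, 2, 8), 2, 2))
  lg <- log2_transform(m)
  expect_equal(abundance_scale(lg), "log2")
  expect_equal(unclass(lg)[1, 1], 10)
  expect_lt(max(abs(2^unclass(lg) - unclass(m))), 1e-12)
  expect_error(log2_transform(lg), "raw-scale")
})

test_that("the exact chain (hyb + plate) preserves group contrasts to 1e-9", {
  sim <- simulate_cohort(small_config(seed = 10))
  tr <- sim$truth
  ctl <- sim$annotation$analyte_id[sim$annotation$is_control]
  h <- hybridization_normalize(sim$abundance, ctl, tr$control_reference)
  plate_of <- setNames(sim$metadata$plate_id, sim$metadata$sample_id)
  ## calibrator-derived per-plate reference levels (expected plate medians)
  ref <- t(sapply(rownames(tr$plate_factors), function(p) {
    idx <- sim$metadata$plate_id == p
    apply(2^tr$log2_signal[idx, , drop = FALSE], 2, median)
  }))
  pc <- plate_calibrate(h$abundance, plate_of, reference = ref)
  lg <- log2_transform(pc$abundance)
  ## per-plate-and-sample scale corrections shift each analyte by a
  ## constant on the log2 scale, so group differences are untouched
  grp <- sim$metadata$group == "term"
  diff_norm <- colMeans(unclass(lg)[grp, ]) - colMeans(unclass(lg)[!grp, ])
  diff_true <- colMeans(tr$log2_signal[grp, ]) -
    colMeans(tr$log2_signal[!grp, ])
  expect_lt(max(abs(diff_norm - diff_true)), 1e-9)
  ## the data-driven median step perturbs contrasts only slightly
  full <- normalize_chain(sim$abundance, sim$annotation, sim$metadata,
                          control_reference = tr$control_reference,
                          plate_reference = ref)
  diff_full <- colMeans(unclass(full$abundance)[grp, ]) -
    colMeans(unclass(full$abundance)[!grp, ])
  expect_lt(max(abs(diff_full - diff_true)), 0.2)
  expect_gt(cor(diff_full, diff_true), 0.999)
})

test_that("normalization never changes shape, ids, or factor positivity", {
  sim <- simulate_cohort(small_config(seed = 12))
  out <- normalize_chain(sim$abundance, sim$annotation, sim$metadata)
  expect_identical(dim(out$abundance), dim(sim$abundance))
  expect_identical(sample_ids(out$abundance), sample_ids(sim$abundance))
  expect_identical(analyte_ids(out$abundance), analyte_ids(sim$abundance))
  expect_true(all(unlist(out$factors) > 0))
})
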