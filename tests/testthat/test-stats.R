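test_that("neighborhood presets select the published bin counts", {
  amps <- abs(rnorm(100, 1, 0.2))
  expect_length(neighborhood(50, neighborhood_preset("scalp_baseline"), amps), 20)
  expect_length(neighborhood(50, neighborhood_preset("scalp_z"), amps), 22)
  expect_length(neighborhood(50, neighborhood_preset("seeg_baseline"), amps), 22)
  expect_length(neighborhood(50, neighborhood_preset("seeg_z"), amps), 22)
  expect_error(neighborhood(5, neighborhood_preset("scalp_z"), amps), "edge")
  expect_error(neighborhood_spec(3, 3), "exceed")
  expect_error(neighborhood_spec(2, 0, TRUE), "4 neighborhood bins")
})

test_that("baseline correction matches the brute-force oracle bin-exactly", {
  for (seed in 1:50) {
    sp <- random_spectrum(seed, n_bins = 120)
    bc <- baseline_correct(sp, neighborhood_preset("scalp_baseline"))
    b <- sample(20:100, 1)
    expect_identical(unname(bc$values[1, b]),
                     unname(oracle_bc(sp$amps[1, ], b, 12, 1, TRUE)))
  }
  # flat spectrum corrects to zero everywhere defined
  flat <- random_spectrum(1, n_bins = 60)
  flat$amps[] <- 3
  bcf <- baseline_correct(flat, neighborhood_preset("scalp_baseline"))
  expect_true(all(bcf$values[1, 13:48] == 0))
  expect_true(all(is.na(bcf$values[1, 1:12])))
  # isolated peak on a constant background recovers its height
  pk <- flat; pk$amps[1, 30] <- 3 + 2
  bcp <- baseline_correct(pk, neighborhood_preset("seeg_baseline"))
  expect_equal(unname(bcp$values[1, 30]), 2)
})

test_that("local Z matches direct arithmetic and the brute-force oracle", {
  # neighborhood of exactly eleven 0.9s and eleven 1.1s, center 2.0
  amps <- rep(1, 61)
  nb_idx <- c(20:30, 32:42)
  amps[nb_idx] <- rep(c(0.9, 1.1), 11)
  amps[31] <- 2.0
  z <- local_z(amps, 31, neighborhood_spec(11, 0, FALSE))
  expect_equal(z, 1 / (0.1 * sqrt(22 / 21)), tolerance = 1e-12)
  expect_equal(noise_sd(amps, 31, neighborhood_spec(11, 0, FALSE)),
               0.1 * sqrt(22 / 21), tolerance = 1e-12)
  # center equal to the neighborhood mean
  amps2 <- amps; amps2[31] <- 1.0
  expect_equal(local_z(amps2, 31, neighborhood_spec(11, 0, FALSE)), 0)
  # oracle equivalence on random spectra
  for (seed in 1:50) {
    sp <- random_spectrum(seed + 100, n_bins = 120)
    b <- sample(20:100, 1)
    expect_identical(unname(local_z(sp, b, neighborhood_preset("seeg_z"))[[1]]),
                     oracle_z(sp$amps[1, ], b, 12, 1))
  }
})

test_that("Z is affine invariant; baseline and noise SD are homogeneous", {
  sp <- random_spectrum(7, n_bins = 200)
  b <- 77
  nb <- neighborhood_preset("scalp_z")
  z0 <- local_z(sp, b, nb)
  sc <- sp; sc$amps <- sp$amps * 10
  sh <- sp; sh$amps <- sp$amps + 5
  expect_equal(local_z(sc, b, nb), z0, tolerance = 1e-12)
  expect_equal(local_z(sh, b, nb), z0, tolerance = 1e-9)
  expect_equal(noise_sd(sc, b, nb), 10 * noise_sd(sp, b, nb),
               tolerance = 1e-12)
  bc0 <- baseline_correct(sp, neighborhood_preset("seeg_baseline"))
  bcs <- baseline_correct(sc, neighborhood_preset("seeg_baseline"))
  expect_equal(bcs$values, 10 * bc0$values, tolerance = 1e-12)
  # degenerate flat neighborhood errors
  flat <- sp; flat$amps[] <- 1
  expect_error(local_z(flat, b, nb), "zero neighborhood")
})

test_that("chunk summation pools harmonic bins and matches its oracle", {
  sp <- random_spectrum(3, n_bins = 300, df = 1 / 59.5)
  odd_bin <- 35L  # 0-based 34
  sp$amps[1, ] <- 0
  harm_bins <- 1L + (1:6) * 34L
  sp$amps[1, harm_bins] <- 0.7
  ck <- chunk_sum(sp, 4 / 7, 1:6, half_width_bins = 15, base_freq = 4)
  expect_equal(dim(ck$values), c(1, 31))
  expect_equal(ck$center, 16)
  expect_equal(unname(ck$values[1, 16]), 6 * 0.7)
  expect_true(all(ck$values[1, -16] == 0))
  # oracle equivalence on random spectra
  for (seed in 1:50) {
    spr <- random_spectrum(seed + 200, n_bins = 300, df = 1 / 59.5)
    ckr <- chunk_sum(spr, 4 / 7, 1:6, 15, base_freq = 4)
    expect_identical(unname(ckr$values[1, ]),
                     oracle_chunk_sum(spr$amps[1, ], harm_bins, 15))
  }
  # the 7th multiple collides with the 4 Hz base rate
  expect_error(chunk_sum(sp, 4 / 7, 1:7, 15, base_freq = 4), "coincide")
  expect_error(chunk_sum(sp, 4 / 7, 1:6, 40, base_freq = 4), "margin")
})

test_that("both baseline-correction orders agree without extrema exclusion", {
  sp <- random_spectrum(11, n_bins = 400, df = 1 / 59.5)
  seeg_order <- oddball_bc_sum(sp, 4 / 7, 1:6, "seeg", half_width_bins = 24)
  # manual sum-then-correct with the same (no-extrema) neighborhood
  ck <- chunk_sum(sp, 4 / 7, 1:6, 24, base_freq = 4)
  nb <- neighborhood_preset("seeg_baseline")
  manual <- unname(ck$values[1, ck$center] -
    mean(ck$values[1, neighborhood(ck$center, nb, ck$values[1, ])]))
  expect_equal(unname(seeg_order), manual, tolerance = 1e-12)
})

test_that("detection recovers noiseless amplitudes and calibrated power", {
  # noiseless: bc_sum equals the injected total; z errors on zero SD
  sess <- simulate_seeg_contact("pure_FN", amp = 0.5 / 6,
                                noise = noise_spec(pink_scale = 0,
                                                   white_scale = 0),
                                seed = 1)
  sp <- seeg_spectra(sess$recording)$FN
  expect_equal(unname(oddball_bc_sum(sp, 4 / 7, 1:6, "seeg")), 0.5,
               tolerance = 1e-3)
  # a degenerate flat spectrum has zero neighborhood SD and must error
  flat <- sp; flat$amps[] <- 1
  expect_error(detect_response(flat, 4 / 7, 1:6, "seeg"), "zero neighborhood")
  # power: amplitude 10 x noise SD per harmonic is detected at z > 3.1
  ns <- noise_spec()
  sd0 <- estimate_contact_noise_sd(ns, seeds = 1:3)
  hits <- vapply(1:40, function(s) {
    x <- synth_noise(1, 59.5, 512, ns, seed = 6000 + s) / sqrt(2)
    tt <- (seq_len(ncol(x)) - 1) / 512
    for (m in 1:6) x <- x + 10 * sd0 * sin(2 * pi * m * 4 / 7 * tt)
    spn <- amplitude_spectrum(epoch(x, 512, 0, "A"))
    detect_response(spn, 4 / 7, 1:6, "seeg")$significant[1]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("spectra algebra is element-wise and supports the subtraction contrast", {
  a <- random_spectrum(21, n_bins = 300, df = 1 / 59.5)
  b <- random_spectrum(22, n_bins = 300, df = 1 / 59.5)
  expect_equal(spectra_subtract(spectra_add(a, b), b)$amps, a$amps,
               tolerance = 1e-12)
  short <- random_spectrum(23, n_bins = 200, df = 1 / 59.5)
  expect_error(spectra_add(a, short), "grid")
  # additive simulation: FN - (FO + NO) vanishes at the oddball harmonics
  quiet <- noise_spec(pink_scale = 0, white_scale = 0)
  sessA <- simulate_seeg_contact("mixed", amp = 0.2, noise = quiet, seed = 2)
  spA <- seeg_spectra(sessA$recording)
  diffA <- spectra_subtract(spA$FN, spectra_add(spA$FO, spA$NO))
  harm_bins <- vapply(1:6, function(m) freq_to_bin(diffA, m * 4 / 7, TRUE),
                      integer(1))
  expect_lt(max(abs(diffA$amps[1, harm_bins])), 1e-6)
  # super-additive simulation: the subtraction carries the crossmodal part
  sessP <- simulate_seeg_contact("pure_FN", amp = 0.1, noise = quiet, seed = 2)
  spP <- seeg_spectra(sessP$recording)
  diffP <- spectra_subtract(spP$FN, spectra_add(spP$FO, spP$NO))
  expect_equal(unname(diffP$amps[1, harm_bins]), rep(0.1, 6),
               tolerance = 1e-6)
})

test_that("contact classification follows the significance decision table", {
  mk_cls <- function(profile, amp, seed) {
    sess <- simulate_seeg_contact(profile, amp = amp, seed = seed)
    sp <- seeg_spectra(sess$recording)
    classify_contact(sp$FN, sp$FO, sp$NO)
  }
  sd0 <- estimate_contact_noise_sd(seeds = 1:3)
  cls <- mk_cls("pure_FN", 10 * sd0, 31)
  expect_equal(cls$label, "pure_FN")
  expect_gt(cls$detections$FN$z, 3.1)
  expect_lte(cls$detections$FO$z, 3.1)
  expect_gt(cls$subtraction$z, 1.65)
  expect_equal(mk_cls("unimodal_face", 10 * sd0, 32)$label, "FN_and_face")
  expect_equal(mk_cls("unimodal_name", 10 * sd0, 33)$label, "FN_and_name")
  expect_equal(mk_cls("mixed", 10 * sd0, 34)$label, "mixed_all")
  expect_equal(mk_cls("null", 0, 35)$label, "none")
})

test_that("harmonic range selection returns a contiguous range and skips collisions", {
  sp <- random_spectrum(41, n_bins = 600, df = 1 / 59.5)
  harm_bins <- 1L + (1:6) * 34L
  sp$amps[1, harm_bins] <- sp$amps[1, harm_bins] + 3
  got <- select_harmonic_range(sp, 4 / 7, max_multiple = 6, variant = "scalp",
                               base_freq = 4)
  expect_equal(got, 1:6)
  # signal out to the 8th multiple: the base-coincident 7th is skipped
  sp8 <- random_spectrum(44, n_bins = 600, df = 1 / 59.5)
  sp8$amps[1, 1L + (1:8) * 34L] <- sp8$amps[1, 1L + (1:8) * 34L] + 3
  expect_equal(select_harmonic_range(sp8, 4 / 7, 8, "scalp", base_freq = 4),
               c(1:6, 8))
  # base-rate series: nine consecutive significant base harmonics
  spb <- random_spectrum(42, n_bins = 3000, df = 1 / 59.5)
  base_bins <- 1L + (1:9) * 238L
  spb$amps[1, base_bins] <- spb$amps[1, base_bins] + 3
  expect_equal(select_harmonic_range(spb, 4, max_multiple = 9,
                                     variant = "scalp"), 1:9)
  # pure noise: empty
  expect_length(select_harmonic_range(random_spectrum(43, n_bins = 600,
                                                      df = 1 / 59.5),
                                      4 / 7, 6, "scalp", base_freq = 4), 0)
})

test_that("ROI pooling averages channels and the integration fraction is exact", {
  sp <- random_spectrum(51, n_bins = 300, n_ch = 3, df = 1 / 59.5)
  sp$labels <- c("P9", "PO9", "PO11")
  rownames(sp$amps) <- sp$labels
  bc <- baseline_correct(sp, neighborhood_preset("seeg_baseline"))
  harm_bins <- 1L + (1:6) * 34L
  per_ch <- rowSums(bc$values[, harm_bins])
  expect_equal(roi_quantify(bc, c("P9", "PO9", "PO11")), mean(per_ch))
  # identical channels collapse to the single-channel value
  sp2 <- sp; sp2$amps[2, ] <- sp2$amps[1, ]; sp2$amps[3, ] <- sp2$amps[1, ]
  bc2 <- baseline_correct(sp2, neighborhood_preset("seeg_baseline"))
  expect_equal(roi_quantify(bc2, sp$labels),
               sum(bc2$values[1, harm_bins]))
  expect_error(roi_quantify(bc, c("P9", "NOPE")), "unknown ROI")
  expect_equal(integration_fraction(1, 0.4, 0.6), 0)
  expect_equal(integration_fraction(1, 0.4, 0.28), 32)
  expect_equal(integration_fraction(1, 0.5, 0.30), 20)
  expect_error(integration_fraction(0, 0.1, 0.1), "fn_amp")
  expect_lt(integration_fraction(1, 0.8, 0.4), 0)
  # exp-2 ROI presets expose the published electrode sets
  rois <- scalp_rois("exp2")
  expect_setequal(rois$LOT, c("I1", "POI1", "PO11", "PO9", "P9"))
  expect_setequal(rois$ROT, c("I2", "POI2", "PO12", "PO10", "P10"))
})
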