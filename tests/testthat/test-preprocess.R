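fs <- 512
tt <- seq(0, 70 - 1 / fs, by = 1 / fs)
mk_rec <- function(x, fs. = fs) recording(rbind(x), fs., "A")
win_amp <- function(rec, lo = 5000, hi = 30000) max(rec$data[1, lo:hi])

test_that("block alignment removes constructed DC jumps", {
  set.seed(1)
  base <- matrix(rnorm(2 * 300), 2, 300)
  jumped <- base
  jumped[, 101:200] <- jumped[, 101:200] + 50
  jumped[, 201:300] <- jumped[, 201:300] + c(50 + 10, 50 - 20)
  rec <- align_blocks(recording(jumped, 100), c(101, 201))
  # brute-force sequential oracle
  y <- jumped
  for (b in c(101, 201)) {
    off <- y[, b] - y[, b - 1]
    y[, b:300] <- y[, b:300] - off
  }
  expect_equal(rec$data, y, ignore_attr = TRUE)
  # continuity at the boundaries
  expect_equal(rec$data[, 101], rec$data[, 100])
  # no boundaries: identity
  rec0 <- recording(jumped, 100)
  expect_identical(align_blocks(rec0, integer(0))$data, rec0$data)
})

test_that("band-pass keeps the 4 Hz response and removes slow drift", {
  r <- bandpass_filter(mk_rec(sin(2 * pi * 4 * tt)))
  expect_gt(win_amp(r), 0.99)
  expect_lt(win_amp(r), 1.01)
  rd <- bandpass_filter(mk_rec(sin(2 * pi * 0.01 * tt)))
  expect_lt(max(abs(rd$data[1, 5000:30000])), 0.1)
  # zero phase: symmetric pulse peak does not move
  pulse <- exp(-((tt - 35) / 0.05)^2)
  rp <- bandpass_filter(mk_rec(pulse))
  expect_equal(which.max(rp$data[1, ]), which.max(pulse))
  expect_error(bandpass_filter(mk_rec(tt), low = 0.1, high = 300), "band")
})

test_that("multi-notch suppresses mains harmonics and spares the tagged bands", {
  for (f0 in c(50, 100, 150, 200)) {
    rn <- notch_filter(mk_rec(sin(2 * pi * f0 * tt)))
    expect_lt(max(abs(rn$data[1, 5000:30000])), 0.05)
  }
  r4 <- notch_filter(mk_rec(sin(2 * pi * 4 * tt)))
  expect_gt(win_amp(r4), 0.99)
  # mixture resolved on the amplitude spectrum
  mix <- notch_filter(mk_rec(sin(2 * pi * 4 * tt) + sin(2 * pi * 50 * tt)))
  sp <- amplitude_spectrum(epoch(mix$data[, 1:(59.5 * fs), drop = FALSE],
                                 fs, 0, "A"))
  expect_equal(unname(sp$amps[1, freq_to_bin(sp, 4, TRUE)]), 1, tolerance = 0.01)
  expect_lt(sp$amps[1, freq_to_bin(sp, 50, TRUE)], 0.05)
  expect_error(notch_filter(mk_rec(tt), line = 100, n_freqs = 4), "Nyquist")
})

test_that("downsampling preserves the passband and rescales events", {
  rec <- recording(rbind(sin(2 * pi * 4 * tt)), fs, "A",
                   events = data.frame(sample = c(1025L, 2049L),
                                       code = c("a", "b")))
  rr <- resample_recording(rec, 256)
  expect_equal(rr$fs, 256)
  expect_equal(rr$events$sample, c(513L, 1025L))
  sp <- amplitude_spectrum(epoch(rr$data[, 1:(59.5 * 256), drop = FALSE],
                                 256, 0, "A"))
  expect_equal(unname(sp$amps[1, freq_to_bin(sp, 4, TRUE)]), 1, tolerance = 0.01)
  expect_error(resample_recording(rec, 1024), "upsampling")
  # white noise: band-limited variance is preserved
  set.seed(2)
  rn <- recording(rbind(rnorm(fs * 100)), fs, "A")
  rlow <- bandpass_filter(rn, 0.5, 100, 4)
  rres <- resample_recording(rlow, 256)
  expect_equal(stats::var(rres$data[1, ]), stats::var(rlow$data[1, ]),
               tolerance = 0.1)
})

test_that("epoch segmentation is sample-exact and skips edge triggers", {
  set.seed(3)
  n <- 256 * 500
  rec <- recording(rbind(rnorm(n), rnorm(n)), 256, c("A", "B"),
                   events = data.frame(sample = c(100L, as.integer(256 * c(70, 140, 210, 280, 350, 420))),
                                       code = rep("FN", 7)))
  expect_warning(eps <- segment_epochs(rec, t_min = -2, t_max = 66), "skipped")
  expect_length(eps, 6)
  expect_equal(ncol(eps[[1]]$data), 68 * 256)
  expect_equal(ncol(eps[[1]]$data), 17408)
  start <- rec$events$sample[2] - 2 * 256
  expect_identical(eps[[1]]$data,
                   rec$data[, start:(start + 17408 - 1)])
  expect_equal(eps[[1]]$t0, -2)
})

test_that("blink counting applies the amplitude threshold and refractory period", {
  fs2 <- 256
  n <- 68 * fs2
  dat <- matrix(0, 3, n, dimnames = list(c("A", "VEOGU", "VEOGL"), NULL))
  tmpl_len <- round(0.3 * fs2)
  tmpl <- 150 * sin(pi * seq_len(tmpl_len) / tmpl_len)
  inject <- function(k) {
    pos <- round(seq(2, 66, length.out = k) * fs2)
    d <- dat
    for (p in pos) {
      idx <- p:(p + tmpl_len - 1)
      d["VEOGU", idx] <- d["VEOGU", idx] + tmpl
      d["VEOGL", idx] <- d["VEOGL", idx] - tmpl
    }
    epoch(d, fs2, t0 = -2)
  }
  b12 <- blink_rate(inject(12), c("VEOGU", "VEOGL"))
  expect_equal(b12$n_blinks, 12)
  expect_equal(b12$rate, 12 / 68, tolerance = 1e-6)
  expect_true(b12$flagged)
  b10 <- blink_rate(inject(10), c("VEOGU", "VEOGL"))
  expect_equal(b10$rate, 10 / 68, tolerance = 1e-6)
  expect_false(b10$flagged)
  b0 <- blink_rate(epoch(dat, fs2, -2), c("VEOGU", "VEOGL"))
  expect_equal(b0$n_blinks, 0)
  expect_false(b0$flagged)
  expect_error(blink_rate(epoch(dat, fs2, -2), c("VEOGU", "MISSING")),
               "missing EOG")
})

test_that("EOG regression removes shared activity and preserves the signal", {
  set.seed(4)
  n <- 256 * 60
  eog <- rnorm(n)
  sine <- sin(2 * pi * 4 * (0:(n - 1)) / 256)
  # exactly orthogonal to intercept + EOG
  X <- cbind(1, eog)
  b_orth <- as.vector(sine - X %*% solve(crossprod(X), crossprod(X, sine)))
  dat <- rbind(A = 0.3 * eog + sine, B = b_orth, VEOG = eog)
  ep <- epoch(dat, 256, 0)
  out <- regress_out_eog(ep, "VEOG")
  expect_lt(abs(stats::cor(out$data["A", ], eog)), 0.01)
  sp <- amplitude_spectrum(epoch(out$data["A", , drop = FALSE], 256, 0, "A"))
  expect_equal(unname(sp$amps[1, freq_to_bin(sp, 4, TRUE)]), 1, tolerance = 0.02)
  # orthogonal channel unchanged; EOG untouched; idempotent
  expect_equal(out$data["B", ], dat["B", ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(out$data["VEOG", ], ep$data["VEOG", ])
  again <- regress_out_eog(out, "VEOG")
  expect_equal(again$data, out$data, tolerance = 1e-9)
})

test_that("bad-channel interpolation pools neighbors and enforces the 5% cap", {
  labels <- sprintf("C%03d", 1:128)
  dat <- matrix(rnorm(128 * 100), 128, 100, dimnames = list(labels, NULL))
  nb <- list(C001 = c("C002", "C003", "C004"))
  out <- interpolate_channels(epoch(dat, 256, 0), "C001", nb)
  expect_equal(out$data["C001", ], colMeans(dat[c("C002", "C003", "C004"), ]))
  # constant neighbors give a constant channel
  dat2 <- dat
  dat2[c("C002", "C003", "C004"), ] <- 2
  out2 <- interpolate_channels(epoch(dat2, 256, 0), "C001", nb)
  expect_true(all(out2$data["C001", ] == 2))
  # 6 of 128 = 4.7% proceeds; 7 of 128 = 5.5% refuses
  bad6 <- sprintf("C%03d", 1:6)
  nb6 <- stats::setNames(lapply(1:6, function(i) sprintf("C%03d", 100:102 + i)),
                         bad6)
  expect_silent(interpolate_channels(epoch(dat, 256, 0), bad6, nb6))
  bad7 <- sprintf("C%03d", 1:7)
  nb7 <- stats::setNames(lapply(1:7, function(i) sprintf("C%03d", 100:102 + i)),
                         bad7)
  expect_error(interpolate_channels(epoch(dat, 256, 0), bad7, nb7), "5%")
  expect_error(interpolate_channels(epoch(dat, 256, 0), "C001",
                                    list(C001 = c("C002", "C003"))),
               "3 to 6")
})

test_that("common-average reference zeroes the mean and is idempotent", {
  set.seed(5)
  dat <- matrix(rnorm(5 * 200), 5, 200,
                dimnames = list(c("A", "B", "C", "D", "VEOG"), NULL))
  ep <- epoch(dat, 256, 0)
  out <- rereference_common_average(ep, exclude = "VEOG")
  expect_lt(max(abs(colMeans(out$data[1:4, ]))), 1e-10)
  expect_identical(out$data["VEOG", ], dat["VEOG", ])
  out2 <- rereference_common_average(out, exclude = "VEOG")
  expect_equal(out2$data, out$data, tolerance = 1e-12)
  # single-channel SEEG path: identity
  seeg <- epoch(dat[1, , drop = FALSE], 512, 0)
  expect_identical(rereference_common_average(seeg)$data, seeg$data)
})

test_that("the scalp chain leaves oddball-harmonic amplitudes nearly unchanged", {
  sess <- simulate_session(spec = response_spec(),
                           noise = noise_spec(pink_scale = 0, white_scale = 0),
                           n_sequences_per_condition = 1, seed = 1,
                           channels = c("P9", "P10"),
                           gains = c(P9 = 1, P10 = -1),
                           eog_channels = character(0))
  sp <- scalp_spectra(sess$recording, conditions = "FN")$FN
  bins <- vapply(1:6, function(m) freq_to_bin(sp, m * 4 / 7, TRUE),
                 integer(1))
  truth <- with(response_spec(), face_amps + name_amps + cross_amps)
  expect_equal(unname(sp$amps["P9", bins]), truth, tolerance = 0.02)
})
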