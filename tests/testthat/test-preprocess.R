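test_that("segmentation arithmetic and degenerate inputs", {
  r10 <- segment_signal(numeric(10 * 60 * 128) + 1, 300, fs = 128)
  expect_equal(nrow(r10), 2L)
  expect_equal(r10$end - r10$start + 1L, c(38400L, 38400L))
  expect_false(any(r10$partial))

  r75 <- segment_signal(numeric(7.5 * 60 * 128) + 1, 300, fs = 128)
  expect_equal(r75$end - r75$start + 1L, c(38400L, 19200L))
  expect_equal(r75$partial, c(FALSE, TRUE))

  r1 <- segment_signal(0.5, 300, fs = 128)
  expect_equal(nrow(r1), 1L)
  expect_true(r1$partial)

  expect_equal(nrow(segment_signal(numeric(0), 300, fs = 128)), 0L)
  expect_error_class(segment_signal(1:10, -1, fs = 128),
                     "strisk_parameter_error")
})

test_that("segmentation is idempotent on reconcatenated segments", {
  for (n in c(1000L, 38400L, 54321L)) {
    x <- rnorm(n)
    r <- segment_signal(x, 100, fs = 128)
    x2 <- unlist(lapply(seq_len(nrow(r)), function(i) x[r$start[i]:r$end[i]]))
    expect_identical(segment_signal(x2, 100, fs = 128), r)
  }
})

test_that("baseline removal: constants, zeros, and wander tracking", {
  expect_equal(remove_baseline(rep(0.5, 2000), 128), rep(0, 2000))
  expect_equal(remove_baseline(numeric(1500), 128), numeric(1500))

  wander <- make_ecg_record(beat_template_params(st_level = 0.1,
                                                 baseline_amp = 0.2),
                            80, seed = 3)
  nowander <- make_ecg_record(beat_template_params(st_level = 0.1),
                              80, seed = 3)
  outw <- remove_baseline(wander$signal$samples, 128)
  out0 <- remove_baseline(nowander$signal$samples, 128)
  # residual wander = what the wander leaves behind after cleaning, i.e. the
  # difference between the cleaned record and the cleaned wander-free record
  # (the beat-shape DC offset removed by the filter is identical in both).
  # The first/last filter window are documented transients and excluded.
  skip_n <- 2L * 141L
  n <- length(outw)
  resid <- (outw - out0)[skip_n:(n - skip_n)]
  expect_lt(max(abs(resid)), 0.02)
})

test_that("wavelet denoising preserves signal and removes noise", {
  x0 <- clean_record$signal$samples
  dn <- denoise_wavelet(x0)
  expect_equal(length(dn), length(x0))
  expect_lt(sqrt(mean((dn - x0)^2)) / sqrt(mean(x0^2)), 0.05)
  # QRS peak amplitude preserved within 10%
  r1 <- clean_record$truth$r_idx[2]
  expect_equal(dn[r1], x0[r1], tolerance = 0.1)

  set.seed(5)
  xn <- x0 + rnorm(length(x0), 0, 0.05)
  dnn <- denoise_wavelet(xn)
  expect_lt(sqrt(mean((dnn - x0)^2)), sqrt(mean((xn - x0)^2)))

  expect_equal(denoise_wavelet(numeric(512)), numeric(512))
})

test_that("quality index separates clean, flat and noisy segments", {
  x0 <- remove_baseline(clean_record$signal$samples, 128)
  expect_gte(sqi_score(x0, 128), 0.8)
  expect_equal(sqi_score(numeric(2000), 128), 0)
  set.seed(1)
  expect_lt(sqi_score(rnorm(38400, 0, 1), 128), 0.8)

  q <- quality_filter(list(x0, numeric(2000)), fs = 128)
  expect_equal(q$keep, c(TRUE, FALSE))
  expect_error_class(quality_filter(list(), fs = 128),
                     "strisk_parameter_error")
})

test_that("delineation hits ground truth on clean signal", {
  x <- remove_baseline(clean_record$signal$samples, 128)
  ann <- delineate_beats(x, 128)
  tr <- clean_record$truth
  expect_equal(nrow(ann), nrow(tr))
  expect_lte(max(abs(ann$r_idx - tr$r_idx)), 2)
  expect_lte(max(abs(ann$s_idx - tr$s_idx), na.rm = TRUE), 3)
  expect_lte(max(abs(ann$t_idx - tr$t_idx), na.rm = TRUE), 3)

  expect_equal(nrow(delineate_beats(numeric(2000), 128)), 0L)
})

test_that("delineation fiducials strictly increase on random records", {
  set.seed(99)
  for (i in 1:20) {
    p <- beat_template_params(st_level = runif(1, -0.1, 0.2),
                              st_jitter_sd = runif(1, 0, 0.05),
                              noise_sd = runif(1, 0, 0.1))
    rec <- make_ecg_record(p, 15, seed = 1000 + i)
    x <- remove_baseline(rec$signal$samples, 128)
    ann <- delineate_beats(x, 128)
    if (!nrow(ann)) next
    fid <- as.matrix(ann[, c("p_idx", "qrs_on_idx", "r_idx", "s_idx",
                             "t_idx")])
    for (r in seq_len(nrow(fid))) {
      v <- fid[r, !is.na(fid[r, ])]
      if (length(v) > 1) expect_true(all(diff(v) > 0))
    }
  }
})

test_that("amplitude normalization scales by mean R amplitude", {
  x <- remove_baseline(clean_record$signal$samples, 128)
  ann <- delineate_beats(x, 128)
  xn <- normalize_amplitude(x, ann)
  expect_equal(mean(xn[ann$r_idx]), 1, tolerance = 1e-12)
  # two different R amplitudes average to their mean
  y <- numeric(600)
  y[c(100, 400)] <- c(0.8, 1.2)
  yn <- normalize_amplitude(y, data.frame(r_idx = c(100, 400)))
  expect_equal(yn[c(100, 400)], c(0.8, 1.2))
  expect_error_class(normalize_amplitude(y, data.frame(r_idx = integer())),
                     "strisk_quality_error")
  expect_error_class(normalize_amplitude(-y, data.frame(r_idx = c(100, 400))),
                     "strisk_quality_error")
})

test_that("kept-segment fraction is non-increasing in noise", {
  kept <- vapply(c(0, 0.05, 0.2), function(ns) {
    rec <- make_ecg_record(beat_template_params(noise_sd = ns), 60,
                           seed = 17)
    pp <- preprocess_record(rec$signal, seg_len_s = 15)
    mean(pp$quality$keep)
  }, 0)
  expect_true(all(diff(kept) <= 0))
})

test_that("full preprocessing pipeline yields usable annotations", {
  pp <- preprocess_record(jitter_record$signal)
  expect_true(all(pp$quality$keep))
  expect_equal(nrow(pp$annotations), nrow(jitter_record$truth))
  expect_true(all(diff(pp$annotations$r_idx) > 0))
})
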