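test_that("ST extraction applies the span retention rule", {
  x <- rep(0.1, 400)
  ann <- data.frame(beat = 1:4,
                    s_idx = c(50, 120, 200, 300),
                    t_idx = c(50 + 14, 120 + 15, 200 + 32, 300 + 19))
  st <- extract_st_segments(x, ann)  # spans 15, 16, 33, 20
  expect_equal(nrow(st$segments), 2L)
  expect_equal(unname(st$discards["too_short"]), 1L)
  expect_equal(unname(st$discards["too_long"]), 1L)
  expect_equal(st$beat_index, c(2L, 4L))

  ann$t_idx[2] <- NA
  st2 <- extract_st_segments(x, ann)
  expect_equal(unname(st2$discards["missing_label"]), 1L)
  # discard accounting partitions the input
  expect_equal(nrow(st2$segments) + sum(st2$discards), nrow(ann))

  bad <- data.frame(beat = 1, s_idx = 390, t_idx = 410)
  expect_error_class(extract_st_segments(x, bad), "strisk_data_error")
})

test_that("extraction recovers the planted window exactly", {
  st <- extract_st_segments(clean_record$signal$samples, clean_record$truth)
  expect_equal(nrow(st$segments), nrow(clean_record$truth))
  expect_equal(unname(st$segments[3, ]), rep(0.1, 16), tolerance = 1e-12)
})

test_that("orthonormal basis has the documented exact columns", {
  B <- build_orthonormal_basis(16)
  expect_equal(B[, 1], rep(1 / 4, 16))
  expect_equal(B[, 2], ((0:15) - 7.5) / sqrt(340), tolerance = 1e-12)
  for (n in c(8L, 16L, 20L)) {
    Bn <- build_orthonormal_basis(n)
    expect_lt(max(abs(crossprod(Bn) - diag(n))), 1e-10)
  }
  expect_error_class(build_orthonormal_basis(1), "strisk_parameter_error")
})

test_that("projection matches hand values and conserves energy", {
  B <- build_orthonormal_basis(16)
  seg <- function(v) {
    s <- structure(list(segments = matrix(v, 1), beat_index = 1L,
                        segment_id = NA_integer_,
                        discards = c(missing_label = 0L, too_short = 0L,
                                     too_long = 0L)),
                   class = "st_segment_matrix")
    project_coefficients(s, B)$intermediate[1, ]
  }
  cs <- seg(rep(0.1, 16))
  expect_equal(unname(cs[1]), 0.4, tolerance = 1e-12)
  expect_lt(max(abs(cs[-1])), 1e-12)

  ramp <- seg(0:15)
  expect_equal(unname(ramp[1]), 30, tolerance = 1e-10)
  expect_equal(unname(ramp[2]), sqrt(340), tolerance = 1e-10)
  expect_lt(max(abs(ramp[-(1:2)])), 1e-9)

  quad <- seg(((0:15) - 7.5)^2)
  expect_lt(abs(quad[2]), 1e-9)

  # energy conservation and reconstruction on random segments
  set.seed(2)
  M <- matrix(rnorm(50 * 16), 50)
  stm <- structure(list(segments = M, beat_index = 1:50,
                        segment_id = rep(NA_integer_, 50),
                        discards = c(missing_label = 0L, too_short = 0L,
                                     too_long = 0L)),
                   class = "st_segment_matrix")
  co <- project_coefficients(stm, B)$intermediate
  expect_equal(rowSums(co^2), rowSums(M^2), tolerance = 1e-10)
  expect_lt(max(abs(co %*% t(B) - M)), 1e-10)

  expect_error_class(
    project_coefficients(stm, build_orthonormal_basis(8)),
    "strisk_parameter_error")
})

test_that("c1 is exactly four times the window mean", {
  B <- build_orthonormal_basis(16)
  set.seed(3)
  M <- matrix(rnorm(20 * 16), 20)
  co <- M %*% B
  expect_equal(co[, 1], 4 * rowMeans(M), tolerance = 1e-13)
})

test_that("SD normalization follows the sample-SD convention", {
  s <- coefficient_series(cbind(c1 = c(1, 2, 3), c2 = c(0, 1, 2)))
  n <- normalize_by_sd(s)
  expect_equal(unname(n$normalized[, 1]), c(1, 2, 3))
  s2 <- normalize_by_sd(coefficient_series(cbind(c1 = c(2, 4, 6),
                                                 c2 = c(1, 2, 3))))
  expect_equal(unname(s2$normalized[, 1]), c(1, 2, 3))
  # zero-SD component: divisor 1, flagged, values unchanged
  s3 <- normalize_by_sd(coefficient_series(cbind(c1 = c(5, 5, 5),
                                                 c2 = c(1, 2, 3))))
  expect_true(s3$flagged)
  expect_equal(unname(s3$normalized[, 1]), c(5, 5, 5))
  expect_error_class(normalize_by_sd(coefficient_series(cbind(c1 = 1))),
                     "strisk_parameter_error")
})

test_that("first_window truncates, signals exclusion, and is exact at 50", {
  set.seed(8)
  mk <- function(n) normalize_by_sd(coefficient_series(
    cbind(c1 = rnorm(n) + seq_len(n), c2 = rnorm(n))))
  s60 <- mk(60)
  expect_identical(first_window(s60), s60$normalized[1:50, ])
  s50 <- mk(50)
  expect_identical(first_window(s50), s50$normalized)
  expect_error_class(first_window(mk(49)), "strisk_exclusion")
  expect_error_class(first_window(coefficient_series(cbind(c1 = 1:60))),
                     "strisk_parameter_error")  # not normalized yet
})

test_that("window summary uses sample SDs", {
  w <- cbind(c1 = rep(0.4, 10), c2 = rep(0, 10))
  expect_equal(unname(st_summary(w)), c(0.4, 0, 0, 0))
  w2 <- cbind(c1 = c(1, 3), c2 = c(0, 0))
  expect_equal(unname(st_summary(w2)), c(2, sqrt(2), 0, 0))
})

test_that("planted slope and level are recovered through projection", {
  st <- extract_st_segments(jitter_record$signal$samples,
                            jitter_record$truth)
  co <- project_coefficients(st)
  tr <- jitter_record$truth[st$beat_index, ]
  expect_gt(cor(co$intermediate[, 1], tr$st_level), 0.9999)
  expect_gt(cor(co$intermediate[, 2], tr$st_slope), 0.9999)
  # mean c2 over the window ~ sqrt(340) * mean planted slope
  expect_lt(abs(mean(co$intermediate[1:50, 2]) -
                  sqrt(340) * mean(tr$st_slope[1:50])), 0.02)
})

test_that("cohort window assembly excludes short series", {
  co <- make_cohort(cohort_spec(20, seed = 6, n_series_beats = 60))
  co$series[[3]]$intermediate <- co$series[[3]]$intermediate[1:30, ]
  cw <- cohort_windows(co)
  expect_equal(nrow(cw$patients), 19L)
  expect_equal(cw$excluded$reason, "insufficient_beats")
  expect_equal(dim(cw$windows), c(19L, 50L, 2L))
  expect_equal(colnames(cw$features),
               c("mean_c1", "sd_c1", "mean_c2", "sd_c2"))
})
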