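# ST-segment isolation and orthonormal-polynomial morphology coefficients.
#
# Each retained beat contributes a 16-sample ST window centred on the
# midpoint of the S and T labels. Projection onto an orthonormal polynomial
# basis (Gram-Schmidt on monomials at 16 equispaced points) yields
# Legendre-style coefficients: c1 is the ST level (c1 = 4 * window mean on
# 16 points), c2 the slope. Coefficients are normalized per patient by the
# component SD over the full first-day series; models consume the first
# 50-beat window of the normalized series.

#' Extract 16-sample ST windows from annotated beats
#'
#' For each beat with both S and T labels whose inclusive span
#' `t_idx - s_idx + 1` lies in \[16, 32\], emits the 16 samples centred on
#' `floor((s_idx + t_idx) / 2)` (window: midpoint - 8 ... midpoint + 7).
#' All other beats are counted under a discard reason.
#'
#' @param sig_clean numeric vector (cleaned record) or [ecg_signal].
#' @param ann beat table with `s_idx`, `t_idx` (and optionally `beat`,
#'   `segment`) columns; indices must lie within the signal.
#' @return an `st_segment_matrix`: list with `segments` (rows = retained
#'   beats, 16 columns), `beat_index`, `segment_id`, and `discards`
#'   (named counts: missing_label, too_short, too_long).
#' @export
extract_st_segments <- function(sig_clean, ann) {
  x <- if (inherits(sig_clean, "ecg_signal")) sig_clean$samples else sig_clean
  n <- length(x)
  nb <- nrow(ann)
  beat_id <- if ("beat" %in% names(ann)) ann$beat else seq_len(nb)
  seg_id <- if ("segment" %in% names(ann)) ann$segment else rep(NA_integer_, nb)
  discards <- c(missing_label = 0L, too_short = 0L, too_long = 0L)
  keep_rows <- list()
  keep_beat <- integer()
  keep_seg <- integer()
  for (i in seq_len(nb)) {
    s <- ann$s_idx[i]
    t <- ann$t_idx[i]
    if (is.na(s) || is.na(t)) {
      discards["missing_label"] <- discards["missing_label"] + 1L
      next
    }
    if (s < 1L || t > n || s > t)
      stop_strisk(sprintf("beat %s: annotation index out of signal bounds",
                          beat_id[i]), "strisk_data_error")
    span <- t - s + 1L
    if (span < 16L) {
      discards["too_short"] <- discards["too_short"] + 1L
      next
    }
    if (span > 32L) {
      discards["too_long"] <- discards["too_long"] + 1L
      next
    }
    mid <- (s + t) %/% 2L
    idx <- (mid - 8L):(mid + 7L)
    if (idx[1] < 1L || idx[16] > n || anyNA(x[idx])) {
      # window clipped by a record/segment edge: too few usable samples
      discards["too_short"] <- discards["too_short"] + 1L
      next
    }
    keep_rows[[length(keep_rows) + 1L]] <- x[idx]
    keep_beat <- c(keep_beat, beat_id[i])
    keep_seg <- c(keep_seg, seg_id[i])
  }
  segments <- if (length(keep_rows))
    do.call(rbind, keep_rows) else matrix(numeric(), 0L, 16L)
  structure(list(segments = segments, beat_index = keep_beat,
                 segment_id = keep_seg, discards = discards),
            class = "st_segment_matrix")
}

#' Orthonormal polynomial basis on equispaced points
#'
#' Gram-Schmidt orthonormalisation of the monomials `1, x, x^2, ...`
#' evaluated at `n_samples` equispaced points (computed via Householder QR,
#' which yields the same nested orthonormal basis with better numerical
#' behaviour; signs fixed so each column correlates positively with its
#' monomial). Column 1 is the exact constant `1/sqrt(n)`; for n = 16,
#' column 2 is `(k - 7.5)/sqrt(340)`, k = 0..15.
#'
#' @param n_samples number of points (>= 2; default 16).
#' @return an `n_samples x n_samples` matrix with orthonormal columns.
#' @export
build_orthonormal_basis <- function(n_samples = 16L) {
  n <- as.integer(n_samples)
  if (n < 2L) stop_strisk("n_samples must be >= 2", "strisk_parameter_error")
  k <- 0:(n - 1L)
  xs <- (k - (n - 1) / 2) / ((n - 1) / 2)  # scaled abscissa for conditioning
  V <- outer(xs, 0:(n - 1L), `^`)
  qrd <- qr(V)
  B <- qr.Q(qrd)
  B <- sweep(B, 2, sign(diag(qr.R(qrd))), `*`)
  B[, 1] <- 1 / sqrt(n)  # snap the constant column to its exact value
  B
}

#' Per-beat morphology coefficient series
#'
#' @param intermediate numeric matrix: rows = beats, columns = coefficient
#'   components (16 from [project_coefficients()], or fewer for emulated
#'   series).
#' @return a `coefficient_series` object with fields `intermediate`,
#'   `normalized` (NULL until [normalize_by_sd()]), `sds`, `retained_k`,
#'   `flagged`.
#' @export
coefficient_series <- function(intermediate) {
  intermediate <- as.matrix(intermediate)
  if (is.null(colnames(intermediate)))
    colnames(intermediate) <- paste0("c", seq_len(ncol(intermediate)))
  structure(list(intermediate = intermediate, normalized = NULL,
                 sds = NULL, retained_k = min(2L, ncol(intermediate)),
                 flagged = FALSE),
            class = "coefficient_series")
}

#' @export
print.coefficient_series <- function(x, ...) {
  cat(sprintf("<coefficient_series> %d beats x %d components (%s)\n",
              nrow(x$intermediate), ncol(x$intermediate),
              if (is.null(x$normalized)) "raw" else "normalized"))
  invisible(x)
}

#' Project ST windows onto the orthonormal basis
#'
#' Coefficient vector = `t(basis) %*% segment` for every beat; because the
#' basis is orthonormal, `basis %*% coefficients` reconstructs the segment
#' and coefficient energy equals sample energy.
#'
#' @param st an `st_segment_matrix` from [extract_st_segments()].
#' @param basis matrix from [build_orthonormal_basis()]; its dimension must
#'   match the window width.
#' @return a [coefficient_series] (intermediate, un-normalized).
#' @export
project_coefficients <- function(st, basis = build_orthonormal_basis(16L)) {
  stopifnot(inherits(st, "st_segment_matrix"))
  if (ncol(st$segments) != nrow(basis))
    stop_strisk("segment width does not match basis dimension",
                "strisk_parameter_error")
  co <- st$segments %*% basis
  colnames(co) <- paste0("c", seq_len(ncol(co)))
  out <- coefficient_series(co)
  out$beat_index <- st$beat_index
  out
}

#' Normalize coefficient components by their standard deviation
#'
#' Each retained component is divided by that component's sample SD computed
#' over the full series (the patient's first-day record). A zero-SD
#' component gets divisor 1 and the series is flagged.
#'
#' @param series a [coefficient_series] with >= 2 beats.
#' @param retain number of leading components retained (default 2: level and
#'   slope).
#' @return the series with `normalized`, `sds`, `retained_k` and `flagged`
#'   filled in.
#' @export
normalize_by_sd <- function(series, retain = 2L) {
  stopifnot(inherits(series, "coefficient_series"))
  if (nrow(series$intermediate) < 2L)
    stop_strisk("need >= 2 beats to normalize", "strisk_parameter_error")
  retain <- min(as.integer(retain), ncol(series$intermediate))
  sub <- series$intermediate[, seq_len(retain), drop = FALSE]
  sds <- apply(sub, 2, sd)
  flagged <- sds == 0
  sds_use <- ifelse(flagged, 1, sds)
  series$normalized <- sweep(sub, 2, sds_use, `/`)
  series$sds <- sds
  series$retained_k <- retain
  series$flagged <- any(flagged)
  series
}

#' First-n-beats analysis window
#'
#' @param series a normalized [coefficient_series].
#' @param n_beats window length (default 50). Fewer available beats raises
#'   an exclusion condition of class `strisk_exclusion` (catch it during
#'   cohort assembly), never a silent truncation.
#' @return matrix of the first `n_beats` rows of the normalized series.
#' @export
first_window <- function(series, n_beats = 50L) {
  stopifnot(inherits(series, "coefficient_series"))
  if (is.null(series$normalized))
    stop_strisk("series must be normalized first (see normalize_by_sd)",
                "strisk_parameter_error")
  if (nrow(series$normalized) < n_beats)
    stop_strisk(sprintf("patient has %d clean beats, fewer than %d",
                        nrow(series$normalized), n_beats),
                "strisk_exclusion")
  series$normalized[seq_len(n_beats), , drop = FALSE]
}

#' Summary features of a coefficient window
#'
#' @param window matrix from [first_window()] with components c1, c2.
#' @return named numeric vector `(mean_c1, sd_c1, mean_c2, sd_c2)` (sample
#'   SD).
#' @export
st_summary <- function(window) {
  if (!nrow(window)) stop_strisk("empty window", "strisk_parameter_error")
  sdv <- function(v) if (length(v) > 1L) sd(v) else 0
  c(mean_c1 = mean(window[, 1]), sd_c1 = sdv(window[, 1]),
    mean_c2 = mean(window[, 2]), sd_c2 = sdv(window[, 2]))
}

#' Assemble model inputs (windows and summary features) for a cohort
#'
#' Normalizes every patient's coefficient series, takes the first-50-beat
#' window and its summary features, and reports patients excluded for
#' having fewer than `n_beats` clean beats.
#'
#' @param cohort an `st_cohort` from [make_cohort()], or a list of
#'   [coefficient_series] plus a `patients` data frame.
#' @param n_beats window length (default 50).
#' @return list with `patients` (included rows), `windows` (array
#'   n x n_beats x 2), `features` (matrix n x 4 of [st_summary()] values)
#'   and `excluded` (data frame patient_id, reason).
#' @export
cohort_windows <- function(cohort, n_beats = 50L) {
  stopifnot(inherits(cohort, "st_cohort"))
  if (is.null(cohort$series))
    stop_strisk("cohort has no coefficient series", "strisk_parameter_error")
  pats <- cohort$patients
  ids <- pats$patient_id
  wins <- vector("list", length(ids))
  feats <- matrix(NA_real_, length(ids), 4)
  ok <- logical(length(ids))
  excl <- list()
  for (i in seq_along(ids)) {
    res <- tryCatch({
      s <- normalize_by_sd(cohort$series[[i]])
      w <- first_window(s, n_beats)
      list(w = w, f = st_summary(w))
    }, strisk_exclusion = function(e) e)
    if (inherits(res, "condition")) {
      excl[[length(excl) + 1L]] <- data.frame(patient_id = ids[i],
                                              reason = "insufficient_beats")
      next
    }
    wins[[i]] <- res$w
    feats[i, ] <- res$f
    ok[i] <- TRUE
  }
  windows <- array(NA_real_, c(sum(ok), n_beats, 2L))
  j <- 0L
  for (i in which(ok)) {
    j <- j + 1L
    windows[j, , ] <- wins[[i]][, 1:2]
  }
  feats <- feats[ok, , drop = FALSE]
  colnames(feats) <- c("mean_c1", "sd_c1", "mean_c2", "sd_c2")
  list(patients = pats[ok, , drop = FALSE], windows = windows,
       features = feats,
       excluded = if (length(excl)) do.call(rbind, excl) else
         data.frame(patient_id = character(), reason = character()))
}
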