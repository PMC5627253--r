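# Statistical evaluation harness: stratified 80/20 bootstrap, AUC with
# Hanley-McNeil confidence intervals, quartile-dichotomized Cox hazard
# ratios at multiple horizons, net reclassification indices, Kaplan-Meier
# curves and paired model comparisons. Summary metrics are means over
# non-eliminated bootstrap rounds, and confidence-interval bounds are means
# of the per-round bounds.

#' Bootstrap evaluation plan
#'
#' @param n_rounds number of resampling rounds (default 1000).
#' @param test_fraction held-out fraction per round (default 0.2).
#' @param stratify_on_event keep the event fraction equal (up to rounding)
#'   in train and test each round (default TRUE).
#' @param seed master seed; per-round seeds are derived by a counter.
#' @param horizons evaluation horizons in days (default 365, 60, 30, 14).
#' @return a `bootstrap_plan` object.
#' @export
bootstrap_plan <- function(n_rounds = 1000L, test_fraction = 0.2,
                           stratify_on_event = TRUE, seed = 1L,
                           horizons = c(365, 60, 30, 14)) {
  stopifnot(n_rounds >= 0, test_fraction > 0, test_fraction < 1)
  structure(list(n_rounds = as.integer(n_rounds),
                 test_fraction = test_fraction,
                 stratify_on_event = isTRUE(stratify_on_event),
                 seed = as.integer(seed), horizons = horizons),
            class = "bootstrap_plan")
}

.round_seed <- function(master, round) {
  as.integer((as.double(master) * 48271 + round * 16807) %% 2147483647)
}

#' Stratified train/test partitions for every bootstrap round
#'
#' Events and non-events are sampled without replacement into the train set
#' with per-stratum size `round((1 - test_fraction) * n_stratum)`, so the
#' train/test event counts are fixed across rounds. For a 4395-patient
#' cohort with 149 events and an 80/20 split, every train set has 3516
#' patients.
#'
#' @param event 0/1 event indicator for the cohort.
#' @param plan a [bootstrap_plan()].
#' @return list of `plan$n_rounds` lists with integer `train` and `test`
#'   index vectors.
#' @export
stratified_splits <- function(event, plan) {
  y <- as.integer(event)
  if (sum(y == 1L) < 1L || sum(y == 0L) < 1L)
    stop_strisk("need at least one event and one non-event",
                "strisk_config_error")
  n_test_ev <- sum(y == 1L) - round((1 - plan$test_fraction) * sum(y == 1L))
  if (plan$stratify_on_event && n_test_ev < 1L)
    stop_strisk("cohort too small for one event in every test set",
                "strisk_config_error")
  lapply(seq_len(plan$n_rounds), function(r) {
    with_seed(.round_seed(plan$seed, r), {
      if (plan$stratify_on_event) {
        tr <- integer()
        for (cls in c(0L, 1L)) {
          idx <- which(y == cls)
          k <- round((1 - plan$test_fraction) * length(idx))
          tr <- c(tr, sample(idx, k))
        }
      } else {
        tr <- sample(length(y), round((1 - plan$test_fraction) * length(y)))
      }
      tr <- sort(tr)
      list(train = tr, test = setdiff(seq_along(y), tr))
    })
  })
}

#' Area under the ROC curve (rank-based)
#'
#' Concordance probability between a random event/non-event pair; ties
#' count one half (mid-rank formulation).
#'
#' @param scores numeric predictions.
#' @param labels 0/1 outcomes; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_strisk("AUC undefined with a single class", "strisk_parameter_error")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' SE^2 = (A(1-A) + (n_pos - 1)(Q1 - A^2) + (n_neg - 1)(Q2 - A^2)) /
#' (n_pos n_neg) with Q1 = A/(2-A), Q2 = 2A^2/(1+A);
#' CI = A +/- 1.96 SE, clipped to \[0, 1\].
#'
#' @param auc AUC estimate in \[0, 1\].
#' @param n_pos,n_neg class counts (>= 1).
#' @return list with `se`, `lower`, `upper`.
#' @export
hanley_mcneil_ci <- function(auc, n_pos, n_neg) {
  stopifnot(n_pos >= 1, n_neg >= 1, auc >= 0, auc <= 1)
  a <- auc
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) +
                (n_neg - 1) * (q2 - a^2)) / (n_pos * n_neg))
  list(se = se, lower = max(0, a - 1.96 * se), upper = min(1, a + 1.96 * se))
}

#' Truncate toward zero at the first significant digit
#'
#' 0.2736 -> 0.2; 0.0734 -> 0.07 (truncation, not rounding).
#'
#' @param x positive numeric.
#' @param digits significant digits kept (default 1).
#' @return truncated value.
#' @export
truncate_sig <- function(x, digits = 1L) {
  vapply(x, function(v) {
    if (!is.finite(v) || v == 0) return(v)
    m <- 10^(floor(log10(abs(v))) - digits + 1L)
    trunc(v / m) * m * sign(1)
  }, 0)
}

#' Dichotomize scores at the upper quartile
#'
#' Without an external cutoff, high risk means score strictly above the
#' 75th percentile (linear-interpolation quantile) of these scores. With an
#' external cutoff (e.g. one carried from a derivation cohort), the cutoff
#' is first truncated to one significant digit.
#'
#' @param scores numeric predictions (>= 4 values when deriving a cutoff).
#' @param external_cutoff optional cutoff from another dataset.
#' @return list with `high_risk` (0/1 integer vector) and `cutoff` (the
#'   threshold actually applied).
#' @export
dichotomize_upper_quartile <- function(scores, external_cutoff = NULL) {
  if (is.null(external_cutoff)) {
    if (length(scores) < 4L)
      stop_strisk("need >= 4 scores to derive a quartile cutoff",
                  "strisk_parameter_error")
    cut <- unname(quantile(scores, 0.75, type = 7))
  } else {
    cut <- truncate_sig(external_cutoff, 1L)
  }
  list(high_risk = as.integer(scores > cut), cutoff = cut)
}

#' Cox proportional-hazards hazard ratio at a horizon
#'
#' Outcomes are administratively censored at `horizon_days` (events after
#' the horizon count as censored at the horizon). The HR is for
#' `high_risk = 1` vs 0, with optional binary covariate adjustment;
#' CI = exp(beta +/- 1.96 se). Fit failures and degenerate groups are
#' reported through `ok`/`reason` rather than raised, so bootstrap rounds
#' can be eliminated.
#'
#' @param high_risk 0/1 group indicator.
#' @param time_days follow-up times.
#' @param event 0/1 event indicator.
#' @param horizon_days censoring horizon.
#' @param covariates optional data frame of binary adjustment indicators.
#' @return list with `hr`, `lower`, `upper`, `ok`, `reason`.
#' @export
cox_hr <- function(high_risk, time_days, event, horizon_days,
                   covariates = NULL) {
  ev <- as.integer(event == 1 & time_days <= horizon_days)
  tt <- pmin(time_days, horizon_days)
  bad <- function(reason) list(hr = NA_real_, lower = NA_real_,
                               upper = NA_real_, ok = FALSE, reason = reason)
  if (length(unique(high_risk)) < 2L) return(bad("single_risk_group"))
  if (sum(ev) < 1L) return(bad("no_events_before_horizon"))
  df <- data.frame(tt = tt, ev = ev, hr_grp = as.numeric(high_risk))
  form <- tt ~ hr_grp
  if (!is.null(covariates)) {
    df <- cbind(df, covariates)
    form <- stats::as.formula(paste("survival::Surv(tt, ev) ~ hr_grp +",
                                    paste(names(covariates), collapse = "+")))
  } else {
    form <- survival::Surv(tt, ev) ~ hr_grp
  }
  fit <- tryCatch(
    suppressWarnings(survival::coxph(form, data = df)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad("fit_failed"))
  b <- coef(fit)["hr_grp"]
  se <- sqrt(diag(fit$var))[1]
  if (!is.finite(b) || !is.finite(se) || abs(b) > 15)
    return(bad("non_convergence"))
  list(hr = unname(exp(b)), lower = unname(exp(b - 1.96 * se)),
       upper = unname(exp(b + 1.96 * se)), ok = TRUE, reason = NA_character_)
}

#' Net reclassification index
#'
#' `NRI = P(up|event) - P(up|nonevent) + P(down|nonevent) - P(down|event)`.
#'
#' @param counts a list like `list(events = list(n =, up =, down =),
#'   nonevents = list(n =, up =, down =))`; see also [nri_from_classes()]
#'   and [nri_from_scores()].
#' @return NRI value in \[-2, 2\].
#' @export
nri <- function(counts) {
  ev <- counts$events
  ne <- counts$nonevents
  if (ev$n < 1 || ne$n < 1)
    stop_strisk("need at least one event and one non-event",
                "strisk_parameter_error")
  stopifnot(ev$up + ev$down <= ev$n, ne$up + ne$down <= ne$n)
  ev$up / ev$n - ne$up / ne$n + ne$down / ne$n - ev$down / ev$n
}

#' Two-category NRI from old/new class assignments
#'
#' @param old_class,new_class 0/1 risk-class assignments (1 = high risk);
#'   "up" is a move from 0 to 1, "down" from 1 to 0.
#' @param event 0/1 outcome.
#' @return NRI value.
#' @export
nri_from_classes <- function(old_class, new_class, event) {
  up <- old_class == 0 & new_class == 1
  down <- old_class == 1 & new_class == 0
  e <- event == 1
  nri(list(events = list(n = sum(e), up = sum(up & e), down = sum(down & e)),
           nonevents = list(n = sum(!e), up = sum(up & !e),
                            down = sum(down & !e))))
}

#' Kaplan-Meier curves with at-risk counts
#'
#' @param time_days,event survival outcome.
#' @param group group labels.
#' @param horizon_days truncation horizon (default 60).
#' @param ticks times at which to report the number at risk (default
#'   `seq(0, horizon_days, length.out = 5)`).
#' @return list with `curve` (data frame group, time, survival) and
#'   `at_risk` (data frame group, time, at_risk).
#' @export
km_curve <- function(time_days, event, group, horizon_days = 60,
                     ticks = NULL) {
  if (is.null(ticks)) ticks <- seq(0, horizon_days, length.out = 5)
  ev <- as.integer(event == 1 & time_days <= horizon_days)
  tt <- pmin(time_days, horizon_days)
  g <- factor(group)
  fit <- survival::survfit(survival::Surv(tt, ev) ~ g)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(levels(g)[1], length(sm$time)) else
    sub("^g=", "", as.character(sm$strata))
  curve <- data.frame(group = strata, time = sm$time, survival = sm$surv)
  ar <- do.call(rbind, lapply(levels(g), function(lv) {
    data.frame(group = lv, time = ticks,
               at_risk = vapply(ticks, function(tk)
                 sum(g == lv & tt >= tk), 0L))
  }))
  list(curve = curve, at_risk = ar)
}

#' Paired model comparison over bootstrap rounds
#'
#' Two-sided paired t-test on the per-round metric differences.
#'
#' @param metric_a,metric_b equal-length per-round metric vectors (n >= 2).
#' @return two-sided p-value.
#' @export
paired_compare <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 2)
  d <- metric_b - metric_a
  if (sd(d) <= 1e-12 * max(abs(mean(d)), 1)) {
    if (mean(d) == 0) return(1)
    warning("zero-variance non-zero differences; p-value degenerate at 0")
    return(0)
  }
  t.test(metric_a, metric_b, paired = TRUE)$p.value
}

# Fit the requested model on the train split and score the test split.
# `inputs` carries precomputed design pieces shared across models.
.fit_score_model <- function(model, inputs, tr, te, seed) {
  p <- inputs$patients
  y <- p$event
  scale_tr <- function(M) {
    sc <- lapply(seq_len(ncol(M)), function(j) range(M[tr, j]))
    list(tr = .apply_scaler(M[tr, , drop = FALSE], sc),
         te = .apply_scaler(M[te, , drop = FALSE], sc))
  }
  switch(model,
    lr_hx = {
      d <- scale_tr(inputs$hx)
      fit <- fit_lr(d$tr, y[tr], seed = seed)
      predict(fit, d$te)
    },
    lr_st = {
      d <- scale_tr(inputs$st)
      fit <- fit_lr(d$tr, y[tr], seed = seed)
      predict(fit, d$te)
    },
    lr_hx_st = {
      d <- scale_tr(cbind(inputs$hx, inputs$st))
      fit <- fit_lr(d$tr, y[tr], seed = seed)
      predict(fit, d$te)
    },
    rnn = {
      fit <- fit_rnn(inputs$windows[tr, , , drop = FALSE], y[tr],
                     seed = seed)
      rnn_forward(fit, inputs$windows[te, , , drop = FALSE])
    },
    ann = {
      fit <- fit_ann(p[tr, , drop = FALSE],
                     inputs$windows[tr, , , drop = FALSE], seed = seed)
      pr <- predict(fit, p[te, , drop = FALSE],
                    inputs$windows[te, , , drop = FALSE])
      pr$score[pr$model == "ann"]
    },
    trs = as.numeric(trs_ordinal(p$trs[te])),
    stop_strisk(paste("unknown model:", model), "strisk_parameter_error"))
}

#' Run the bootstrap benchmark over a cohort
#'
#' For each stratified 80/20 round, fits the requested models on the train
#' split, scores the test split, and computes the test AUC with its
#' Hanley-McNeil CI, upper-quartile Cox hazard ratios at every plan
#' horizon, the category-free NRI of `ann` vs `lr_hx_st`, and the
#' two-category NRI of `ann` vs the TIMI risk classes. A round is
#' eliminated for a horizon when its test set has fewer than 2 events
#' observed by that horizon or the Cox fit fails.
#'
#' @param cohort an `st_cohort` (with series) or the output of
#'   [cohort_windows()].
#' @param models character subset of `c("lr_hx", "lr_st", "lr_hx_st",
#'   "rnn", "ann", "trs")`.
#' @param plan a [bootstrap_plan()].
#' @return a `bootstrap_result`: list with per-round tables (`auc`, `hr`,
#'   `nri`) and a `summary` list of means over retained rounds.
#' @export
run_benchmark <- function(cohort,
                          models = c("lr_hx", "lr_st", "lr_hx_st", "rnn",
                                     "ann", "trs"),
                          plan = bootstrap_plan()) {
  inputs <- if (inherits(cohort, "st_cohort")) cohort_windows(cohort)
            else cohort
  p <- inputs$patients
  inputs$hx <- history_matrix(p)
  inputs$st <- inputs$features
  if (plan$n_rounds == 0L)
    return(structure(list(auc = data.frame(), hr = data.frame(),
                          nri = data.frame(), summary = list(),
                          plan = plan),
                     class = "bootstrap_result"))
  splits <- stratified_splits(p$event, plan)
  auc_rows <- list()
  hr_rows <- list()
  nri_rows <- list()
  for (r in seq_len(plan$n_rounds)) {
    tr <- splits[[r]]$train
    te <- splits[[r]]$test
    seed_r <- .round_seed(plan$seed, r + plan$n_rounds)
    scores <- list()
    if ("ann" %in% models) {
      # one ensemble fit also yields the lr_hx and rnn sub-model scores
      bundle <- fit_ann(p[tr, , drop = FALSE],
                        inputs$windows[tr, , , drop = FALSE], seed = seed_r)
      pr <- predict(bundle, p[te, , drop = FALSE],
                    inputs$windows[te, , , drop = FALSE])
      for (m in intersect(models, c("ann", "lr_hx", "rnn")))
        scores[[m]] <- pr$score[pr$model == m]
    }
    for (m in setdiff(models, names(scores)))
      scores[[m]] <- .fit_score_model(m, inputs, tr, te, seed_r)
    scores <- scores[models]
    yte <- p$event[te]
    for (m in models) {
      a <- auc(scores[[m]], yte)
      ci <- hanley_mcneil_ci(a, sum(yte == 1), sum(yte == 0))
      auc_rows[[length(auc_rows) + 1L]] <-
        data.frame(round = r, model = m, auc = a, se = ci$se,
                   lower = ci$lower, upper = ci$upper)
      for (h in plan$horizons) {
        n_ev_h <- sum(yte == 1 & p$time_days[te] <= h)
        if (n_ev_h < 2L) {
          hr_rows[[length(hr_rows) + 1L]] <-
            data.frame(round = r, model = m, horizon = h, hr = NA_real_,
                       lower = NA_real_, upper = NA_real_, ok = FALSE,
                       reason = "too_few_events")
          next
        }
        grp <- if (m == "trs") as.integer(p$trs[te] > 4) else
          dichotomize_upper_quartile(scores[[m]])$high_risk
        cx <- cox_hr(grp, p$time_days[te], yte, h)
        hr_rows[[length(hr_rows) + 1L]] <-
          data.frame(round = r, model = m, horizon = h, hr = cx$hr,
                     lower = cx$lower, upper = cx$upper, ok = cx$ok,
                     reason = ifelse(cx$ok, NA_character_, cx$reason))
      }
    }
    if (all(c("ann", "lr_hx_st") %in% models)) {
      nri_rows[[length(nri_rows) + 1L]] <-
        data.frame(round = r, comparison = "ann_vs_lr_hx_st",
                   type = "category_free",
                   nri = nri_category_free(scores[["lr_hx_st"]],
                                           scores[["ann"]], yte))
    }
    if (all(c("ann", "trs") %in% models)) {
      old_cls <- as.integer(p$trs[te] > 4)
      new_cls <- dichotomize_upper_quartile(scores[["ann"]])$high_risk
      nri_rows[[length(nri_rows) + 1L]] <-
        data.frame(round = r, comparison = "ann_vs_trs",
                   type = "two_category",
                   nri = nri_from_classes(old_cls, new_cls, yte))
    }
  }
  auc_df <- do.call(rbind, auc_rows)
  hr_df <- if (length(hr_rows)) do.call(rbind, hr_rows) else data.frame()
  nri_df <- if (length(nri_rows)) do.call(rbind, nri_rows) else data.frame()
  elim_frac <- if (nrow(hr_df))
    max(tapply(!hr_df$ok, paste(hr_df$model, hr_df$horizon), mean)) else 0
  if (elim_frac > 0.05)
    warning(sprintf(
      "%.1f%% of bootstrap rounds eliminated for some model/horizon (> 5%%)",
      100 * elim_frac))
  auc_sum <- stats::aggregate(cbind(auc, lower, upper) ~ model,
                              data = auc_df, FUN = mean)
  hr_ok <- if (nrow(hr_df)) hr_df[hr_df$ok, , drop = FALSE] else hr_df
  hr_sum <- if (NROW(hr_ok))
    stats::aggregate(cbind(hr, lower, upper) ~ model + horizon,
                     data = hr_ok, FUN = mean)
    else data.frame()
  nri_sum <- if (nrow(nri_df))
    stats::aggregate(nri ~ comparison + type, data = nri_df, FUN = mean)
    else data.frame()
  structure(list(auc = auc_df, hr = hr_df, nri = nri_df,
                 summary = list(auc = auc_sum, hr = hr_sum, nri = nri_sum,
                                eliminated_fraction = elim_frac),
                 plan = plan),
            class = "bootstrap_result")
}

#' Category-free NRI from raw score pairs
#'
#' @param old_score,new_score raw model outputs for the same patients.
#' @param event 0/1 outcome.
#' @return NRI value.
#' @export
nri_category_free <- function(old_score, new_score, event) {
  up <- new_score > old_score
  down <- new_score < old_score
  e <- event == 1
  nri(list(events = list(n = sum(e), up = sum(up & e), down = sum(down & e)),
           nonevents = list(n = sum(!e), up = sum(up & !e),
                            down = sum(down & !e))))
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d rounds\n", x$plan$n_rounds))
  if (length(x$summary)) {
    cat("Mean test AUC (mean CI):\n")
    print(x$summary$auc, row.names = FALSE)
  }
  invisible(x)
}
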