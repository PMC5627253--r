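# Risk models: L2-regularised logistic regressions on history and ST summary
# features, a 2-13-1 bias-free Elman recurrent network over the 50-beat
# coefficient windows, and the two-level ensemble combining the history LR
# with the RNN through weights w1, w2.
#
# No model carries an intercept/bias term: 26 (W_in) + 169 (W_rec) +
# 13 (W_out) + 7 (history LR) + 2 (combiner) = 217 trainable scalars.

#' Min-max scaling to [0, 1]
#'
#' @param x numeric vector.
#' @param from length-2 `c(min, max)` learned on training data; defaults to
#'   `range(x)`. Test values outside the training range are not clipped.
#' @return scaled vector with attribute `"from"`. A constant column maps to
#'   all zeros with a warning.
#' @export
minmax_scale <- function(x, from = range(x)) {
  if (diff(from) == 0) {
    warning("constant column in min-max scaling; returning zeros")
    return(structure(rep(0, length(x)), from = from))
  }
  structure((x - from[1]) / (from[2] - from[1]), from = from)
}

# IRLS ridge logistic regression, no intercept.
.ridge_logit <- function(X, y, lambda, max_iter = 100L, tol = 1e-10) {
  X <- as.matrix(X)
  p <- ncol(X)
  w <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% w)
    mu <- plogis(eta)
    s <- pmax(mu * (1 - mu), 1e-10)
    # Newton step on penalized log-likelihood (penalty lambda/2 * ||w||^2)
    g <- drop(crossprod(X, y - mu)) - lambda * w
    H <- crossprod(X * s, X) + diag(lambda, p)
    step <- solve(H, g)
    w <- w + step
    if (max(abs(step)) < tol) break
  }
  w
}

.fold_assign <- function(y, nfolds, seed) {
  with_seed(seed, {
    f <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      f[idx] <- rep_len(seq_len(nfolds), length(idx))
    }
    f
  })
}

#' Fit an L2-regularised logistic regression (no intercept)
#'
#' The ridge penalty is selected by stratified 3-fold cross-validation over
#' a log-spaced grid, maximizing validation AUC, then the model is refit on
#' all data at the chosen penalty. The design is centered on the training
#' column means before fitting (a data statistic, like the min-max scaling
#' constants, not a model parameter): without an intercept and with a rare
#' outcome, an uncentered all-positive design forces every weight negative
#' just to match the base rate, destroying the risk ranking.
#'
#' @param features numeric matrix (rows = patients).
#' @param labels 0/1 vector; both classes must be present.
#' @param seed integer seed controlling the fold assignment.
#' @param lambda_grid candidate penalties (default `10^seq(-3, 3)`).
#' @param nfolds number of CV folds (default 3).
#' @return an `lr_model`: list with `weights`, `centers`, `lambda`,
#'   `cv_auc`.
#' @export
fit_lr <- function(features, labels, seed = 1,
                   lambda_grid = 10^seq(-3, 3, length.out = 7),
                   nfolds = 3L) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L)
    stop_strisk("labels contain a single class", "strisk_fit_error")
  folds <- .fold_assign(y, nfolds, seed)
  cv <- vapply(lambda_grid, function(lam) {
    aucs <- vapply(seq_len(nfolds), function(k) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
        return(NA_real_)
      Xtr <- X[tr, , drop = FALSE]
      ctr <- colMeans(Xtr)
      w <- .ridge_logit(sweep(Xtr, 2, ctr), y[tr], lam)
      auc(drop(sweep(X[!tr, , drop = FALSE], 2, ctr) %*% w), y[!tr])
    }, 0)
    mean(aucs, na.rm = TRUE)
  }, 0)
  # with very few events every fold can be single-class; fall back to a
  # mid-grid penalty rather than failing
  lam <- if (all(is.na(cv))) lambda_grid[ceiling(length(lambda_grid) / 2)]
         else lambda_grid[which.max(cv)]
  centers <- colMeans(X)
  structure(list(weights = .ridge_logit(sweep(X, 2, centers), y, lam),
                 centers = centers, lambda = lam,
                 cv_auc = cv, lambda_grid = lambda_grid),
            class = "lr_model")
}

#' @export
predict.lr_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$centers)) X <- sweep(X, 2, object$centers)
  plogis(drop(X %*% object$weights))
}

# Convert a list/array of n x (T x 2) windows to the (n_in, N, T) cube
# layout the C++ backend expects.
.windows_cube <- function(windows) {
  if (is.list(windows)) {
    Tn <- nrow(windows[[1]])
    arr <- array(NA_real_, c(length(windows), Tn, ncol(windows[[1]])))
    for (i in seq_along(windows)) arr[i, , ] <- windows[[i]]
    windows <- arr
  }
  d <- dim(windows)
  aperm(windows, c(3L, 1L, 2L))  # (n_in, N, T)
}

#' Fit the recurrent network on 50-beat coefficient windows
#'
#' Architecture: 2 input units, 13 tanh hidden units with full Elman
#' recurrence, 1 sigmoid output unit, no bias terms (208 weights):
#' `h_t = tanh(W_in x_t + W_rec h_(t-1))`, `h_0 = 0`,
#' `Y = sigmoid(W_out h_T)`. Trained by full-batch gradient descent (with
#' classical momentum) on class-weighted binary cross-entropy using
#' backpropagation through time; optionally with early stopping on a
#' stratified validation split.
#'
#' @param windows array n x T x 2 (or list of T x 2 matrices); every
#'   sequence must have the same length.
#' @param labels 0/1 vector.
#' @param seed integer seed (weight initialization and validation split).
#' @param hidden hidden units (default 13).
#' @param lr learning rate (default 0.15, with classical momentum 0.9).
#' @param max_epochs epoch budget (default 100).
#' @param patience early-stopping patience in epochs; only used when
#'   `val_fraction > 0`.
#' @param val_fraction inner validation fraction (default 0: at ~3% event
#'   rates a 10% split holds too few events to give a usable stopping
#'   signal, so the fixed epoch budget acts as the regularizer).
#' @param momentum classical momentum coefficient.
#' @param weight_decay L2 penalty added to the gradient (default 0).
#' @param rank_loss optimize the pairwise logistic ranking loss over
#'   event/non-event pairs instead of cross-entropy; with rare events this
#'   uses every discordant pair and is far more sample-efficient.
#' @param class_weight logical; weight positives by n_neg/n_pos (default
#'   TRUE; with ~3% events an unweighted full-batch fit collapses to the
#'   base rate).
#' @return an `rnn_model` with `W_in` (13 x 2), `W_rec` (13 x 13), `W_out`
#'   (1 x 13) and training diagnostics.
#' @export
fit_rnn <- function(windows, labels, seed = 1, hidden = 13L, lr = 0.15,
                    max_epochs = 100L, patience = 25L, val_fraction = 0,
                    momentum = 0.9, weight_decay = 0, class_weight = TRUE,
                    rank_loss = FALSE) {
  Xc <- .windows_cube(windows)
  if (dim(Xc)[1] != 2L)
    stop_strisk("windows must have 2 components per beat",
                "strisk_parameter_error")
  y <- as.numeric(labels)
  N <- dim(Xc)[2]
  if (length(y) != N)
    stop_strisk("labels length does not match windows",
                "strisk_parameter_error")
  if (length(unique(y)) < 2L)
    stop_strisk("labels contain a single class", "strisk_fit_error")
  with_seed(seed, {
    # leaky-integrator initialization: near-identity recurrence makes each
    # hidden unit a slow accumulator, so the final state exposes
    # window-level statistics before any training
    W_in <- matrix(runif(hidden * 2, -0.3, 0.3), hidden, 2)
    W_rec <- diag(0.6, hidden) +
      matrix(runif(hidden * hidden, -0.05, 0.05), hidden, hidden)
    W_out <- matrix(runif(hidden, -0.1, 0.1), 1, hidden)
    val <- integer()
    for (cls in c(0, 1)) {
      idx <- sample(which(y == cls))
      nv <- floor(length(idx) * val_fraction)
      if (nv >= 1 && length(idx) - nv >= 1) val <- c(val, idx[seq_len(nv)])
    }
    train <- setdiff(seq_len(N), val)
    pw <- if (class_weight) sum(y[train] == 0) / max(1, sum(y[train] == 1))
          else 1
    fit <- rnn_train_cpp(Xc, y, train - 1L, val - 1L, W_in, W_rec, W_out,
                         lr, as.integer(max_epochs), as.integer(patience),
                         pw, 5.0, momentum, weight_decay, isTRUE(rank_loss))
    structure(list(W_in = fit$W_in, W_rec = fit$W_rec,
                   W_out = matrix(fit$W_out, 1),
                   hidden = hidden, epochs = fit$epochs,
                   best_epoch = fit$best_epoch, val_loss = fit$val_loss,
                   seed = seed),
              class = "rnn_model")
  })
}

#' Forward pass of the recurrent network
#'
#' @param model an `rnn_model` (or list with `W_in`, `W_rec`, `W_out`).
#' @param windows array n x T x 2 or list of T x 2 matrices.
#' @return vector of predictions in (0, 1).
#' @export
rnn_forward <- function(model, windows) {
  Xc <- .windows_cube(windows)
  drop(rnn_forward_cpp(Xc, model$W_in, model$W_rec,
                       matrix(model$W_out, 1)))
}

#' @export
predict.rnn_model <- function(object, newdata, ...) rnn_forward(object, newdata)

#' Fit the two-level ensemble (history LR + RNN + combiner)
#'
#' The history logistic regression and the RNN are trained independently on
#' the full training set; their outputs feed a second-level L2 logistic
#' regression whose two weights are `w1` (on the RNN output) and `w2` (on
#' the LR output). The combiner weights are estimated from *cross-fitted*
#' sub-model predictions (two stratified folds, each scored by sub-models
#' trained on the other) rather than in-sample outputs: an in-sample RNN
#' separates the training classes almost perfectly, so naive same-data
#' stacking grossly over-weights it. History features are min-max scaled
#' with constants learned on the training set.
#'
#' @param patients data frame with the seven history columns `age`,
#'   `female`, `smoker`, `hypertension`, `diabetes`, `prior_mi`,
#'   `prior_angiography` and the 0/1 outcome column `event`.
#' @param windows array n x 50 x 2 of normalized coefficient windows,
#'   aligned with `patients` rows.
#' @param seed integer seed; sub-fits use seeds derived from it.
#' @param ... passed to [fit_rnn()].
#' @return an `ann_bundle` with elements `lr_hx`, `rnn`, `combiner`
#'   (`w1`, `w2`), `scaler`, `seed`.
#' @export
fit_ann <- function(patients, windows, seed = 1, ...) {
  hx <- history_matrix(patients)
  y <- patients$event
  sc <- lapply(seq_len(ncol(hx)), function(j) range(hx[, j]))
  Xs <- .apply_scaler(hx, sc)
  folds <- .fold_assign(y, 2L, (seed %% 99999989L) * 13 + 7)
  oof <- matrix(NA_real_, length(y), 2,
                dimnames = list(NULL, c("rnn", "lr")))
  dots <- list(...)
  # fold models only calibrate the two combiner weights; a reduced epoch
  # budget keeps them representative at half the cost
  fold_args <- utils::modifyList(
    list(max_epochs = min(60L, dots$max_epochs %||% 60L)), dots)
  fold_args$max_epochs <- min(60L, fold_args$max_epochs)
  for (k in 1:2) {
    tr <- folds != k
    lrk <- fit_lr(Xs[tr, , drop = FALSE], y[tr], seed = seed)
    rnk <- do.call(fit_rnn, c(list(windows[tr, , , drop = FALSE], y[tr],
                                   seed = seed + k), fold_args))
    oof[!tr, "rnn"] <- rnn_forward(rnk, windows[!tr, , , drop = FALSE])
    oof[!tr, "lr"] <- predict(lrk, Xs[!tr, , drop = FALSE])
  }
  comb <- fit_lr(oof, y, seed = seed + 97L)
  lr_hx <- fit_lr(Xs, y, seed = seed)
  rnn <- fit_rnn(windows, y, seed = seed + 1L, ...)
  structure(list(lr_hx = lr_hx, rnn = rnn,
                 combiner = c(w1 = unname(comb$weights[1]),
                              w2 = unname(comb$weights[2])),
                 combiner_centers = comb$centers,
                 combiner_lambda = comb$lambda,
                 scaler = sc, seed = seed),
            class = "ann_bundle")
}

#' Seven-feature history design matrix
#' @param patients cohort data frame.
#' @return numeric matrix with the seven history columns, in canonical
#'   order. Missing values raise an exclusion error.
#' @export
history_matrix <- function(patients) {
  cols <- c("age", "female", "smoker", "hypertension", "diabetes",
            "prior_mi", "prior_angiography")
  miss <- setdiff(cols, names(patients))
  if (length(miss))
    stop_strisk(paste("missing history columns:",
                      paste(miss, collapse = ", ")), "strisk_data_error")
  X <- as.matrix(patients[, cols])
  if (anyNA(X))
    stop_strisk("history features contain missing values; such patients must be excluded",
                "strisk_exclusion")
  storage.mode(X) <- "double"
  X
}

.apply_scaler <- function(X, sc) {
  out <- X
  for (j in seq_len(ncol(X)))
    out[, j] <- suppressWarnings(minmax_scale(X[, j], from = sc[[j]]))
  out
}

#' Predict risk scores from a trained ensemble
#'
#' @param object an `ann_bundle` from [fit_ann()].
#' @param patients data frame of history features (see [fit_ann()]).
#' @param windows coefficient windows aligned with `patients`.
#' @param ... unused.
#' @return data frame (patient_id, model, score) with rows for models
#'   `lr_hx`, `rnn` and `ann`; the ensemble score is
#'   `sigmoid(w1 * Y_rnn + w2 * Y_lr)`.
#' @export
predict.ann_bundle <- function(object, patients, windows, ...) {
  Xs <- .apply_scaler(history_matrix(patients), object$scaler)
  y_lr <- predict(object$lr_hx, Xs)
  y_rnn <- rnn_forward(object$rnn, windows)
  y_ann <- sigmoid(object$combiner["w1"] * y_rnn +
                     object$combiner["w2"] * y_lr)
  ids <- if ("patient_id" %in% names(patients)) patients$patient_id
         else as.character(seq_len(nrow(patients)))
  data.frame(patient_id = rep(ids, 3),
             model = rep(c("lr_hx", "rnn", "ann"), each = length(ids)),
             score = c(y_lr, y_rnn, unname(y_ann)),
             stringsAsFactors = FALSE)
}

#' Count trainable parameters of the ensemble
#'
#' `n_h * (n_h + n_in + 1) + 7 + 2`: for the default 2-13-1 architecture,
#' 26 (W_in) + 169 (W_rec) + 13 (W_out) + 7 (history LR) + 2 (combiner)
#' = 217.
#'
#' @param bundle an `ann_bundle`, an `rnn_model`, or NULL to count the
#'   default architecture.
#' @param hidden,n_in architecture dimensions used when `bundle` is NULL.
#' @return integer parameter count.
#' @export
count_parameters <- function(bundle = NULL, hidden = 13L, n_in = 2L) {
  if (inherits(bundle, "rnn_model"))
    return(length(bundle$W_in) + length(bundle$W_rec) + length(bundle$W_out))
  if (inherits(bundle, "ann_bundle")) {
    r <- bundle$rnn
    return(length(r$W_in) + length(r$W_rec) + length(r$W_out) +
             length(bundle$lr_hx$weights) + length(bundle$combiner))
  }
  as.integer(hidden * (hidden + n_in + 1L) + 7L + 2L)
}

#' Ordinal encoding of the TIMI risk score
#'
#' @param trs integer vector with values in 1..7.
#' @return integer vector: 1-2 -> 1 (low), 3-4 -> 2 (moderate),
#'   >4 -> 3 (high).
#' @export
trs_ordinal <- function(trs) {
  if (any(is.na(trs)) || any(trs < 1 | trs > 7))
    stop_strisk("TRS values must be in 1..7", "strisk_data_error")
  ifelse(trs <= 2, 1L, ifelse(trs <= 4, 2L, 3L))
}
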