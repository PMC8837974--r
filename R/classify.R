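#' Cross-validation configuration
#'
#' @param n_folds Number of CV folds (default 10).
#' @param threshold Classification threshold on the positive-class
#'   probability (default 0.5).
#' @param upsample Balance the training folds by resampling the minority
#'   class with replacement (default TRUE); never applied to test folds.
#' @param seed Integer seed controlling fold assignment, upsampling and
#'   model fitting.
#' @param group_by_subject Assign whole subjects to folds (default FALSE,
#'   mirroring per-sample CV; note that with 5 vowels per subject,
#'   per-sample folds share speakers between training and test).
#' @param models Model families to fit, subset of RF, LR, LDA, NN, SVM.
#' @param rf_ntree,nn_size,nn_decay,svm_cost,lr_lambda Hyperparameters.
#' @return A list of class `bv_cv_config`.
#' @export
cv_config <- function(n_folds = 10L, threshold = 0.5, upsample = TRUE,
                      seed = 1L, group_by_subject = FALSE,
                      models = c("RF", "LR", "LDA", "NN", "SVM"),
                      rf_ntree = 500L, nn_size = 10L, nn_decay = 0.01,
                      svm_cost = 1, lr_lambda = 0.01) {
  stopifnot(n_folds >= 2, threshold > 0, threshold < 1)
  structure(list(n_folds = as.integer(n_folds), threshold = threshold,
                 upsample = upsample, seed = as.integer(seed),
                 group_by_subject = group_by_subject, models = models,
                 rf_ntree = rf_ntree, nn_size = nn_size, nn_decay = nn_decay,
                 svm_cost = svm_cost, lr_lambda = lr_lambda),
            class = "bv_cv_config")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' @param tp,fn,tn,fp Non-negative confusion counts (positives = affected
#'   class).
#' @return Named vector `accuracy`, `sensitivity`, `specificity` in percent.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  if (tp + fn == 0 || tn + fp == 0)
    stop("undefined metric: a class has no observations")
  c(accuracy = (tp + tn) / (tp + fn + tn + fp) * 100,
    sensitivity = tp / (tp + fn) * 100,
    specificity = tn / (tn + fp) * 100)
}

#' Upsample the minority class with replacement
#'
#' Resamples minority-class rows (with replacement) until the class counts
#' are equal; majority rows are untouched. Intended for training folds only.
#'
#' @param X Feature matrix.
#' @param y Two-level factor.
#' @param seed Integer seed.
#' @return List `X`, `y` with equal class counts.
#' @export
upsample_training <- function(X, y, seed = 1L) {
  stopifnot(nlevels(y) == 2L)
  cnt <- base::table(y)
  if (any(cnt == 0)) stop("both classes must be present to upsample")
  if (cnt[1] == cnt[2]) return(list(X = X, y = y))
  minority <- names(cnt)[which.min(cnt)]
  idx_min <- which(y == minority)
  extra <- with_local_seed(seed,
    idx_min[sample.int(length(idx_min), max(cnt) - length(idx_min),
                       replace = TRUE)])
  keep <- c(seq_along(y), extra)
  list(X = X[keep, , drop = FALSE], y = y[keep])
}

# Stratified fold assignment; optionally by subject so no speaker straddles
# folds. Returns an integer fold id per row.
make_folds <- function(y, k, seed, subjects = NULL, group_by_subject = FALSE) {
  with_local_seed(seed, {
    fold <- integer(length(y))
    if (group_by_subject && !is.null(subjects)) {
      us <- unique(subjects)
      sy <- y[match(us, subjects)]
      sf <- integer(length(us))
      for (lv in levels(y)) {
        i <- which(sy == lv)
        sf[i[sample.int(length(i))]] <-
          rep_len(sample.int(k), length(i))
      }
      fold <- sf[match(subjects, us)]
    } else {
      for (lv in levels(y)) {
        i <- which(y == lv)
        fold[i[sample.int(length(i))]] <- rep_len(sample.int(k), length(i))
      }
    }
    fold
  })
}

# ---- model families ------------------------------------------------------

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

fit_one_model <- function(name, X, y, cfg, seed) {
  switch(name,
    RF = fit_random_forest(X, y, ntree = cfg$rf_ntree, seed = seed),
    LDA = structure(list(fit = MASS::lda(X, grouping = y)), class = "bv_lda"),
    LR = {
      fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                            lambda = cfg$lr_lambda, standardize = FALSE)
      structure(list(fit = fit, lambda = cfg$lr_lambda), class = "bv_lr")
    },
    NN = fit_nnet1(X, y, size = cfg$nn_size, decay = cfg$nn_decay,
                   seed = seed),
    SVM = fit_lssvm(X, y, cost = cfg$svm_cost, seed = seed),
    stop("unknown model: ", name))
}

predict_prob <- function(fit, X) {
  if (inherits(fit, "bv_rf")) return(predict(fit, X))
  if (inherits(fit, "bv_lda"))
    return(stats::predict(fit$fit, X)$posterior[, 2])
  if (inherits(fit, "bv_lr"))
    return(as.numeric(stats::predict(fit$fit, X, type = "response")))
  if (inherits(fit, "bv_nnet1")) return(predict_nnet1(fit, X))
  if (inherits(fit, "bv_lssvm")) return(predict_lssvm(fit, X))
  stop("unknown fit class")
}

# Single-hidden-layer neural network (logistic activations), cross-entropy
# loss with weight decay, trained by BFGS from a small seeded random start.
fit_nnet1 <- function(X, y, size = 10L, decay = 0.01, seed = 1L,
                      maxit = 200L) {
  y01 <- as.integer(y) - 1L
  p <- ncol(X)
  n_par <- (p + 1L) * size + size + 1L
  unpack <- function(w) {
    W1 <- matrix(w[seq_len((p + 1L) * size)], nrow = p + 1L)
    w2 <- w[(p + 1L) * size + seq_len(size + 1L)]
    list(W1 = W1, w2 = w2)
  }
  sig <- function(z) 1 / (1 + exp(-z))
  Xb <- cbind(1, X)
  obj <- function(w) {
    pr <- unpack(w)
    H <- sig(Xb %*% pr$W1)
    ph <- sig(cbind(1, H) %*% pr$w2)
    ph <- pmin(pmax(ph, 1e-12), 1 - 1e-12)
    -sum(y01 * log(ph) + (1 - y01) * log(1 - ph)) +
      decay * (sum(pr$W1^2) + sum(pr$w2^2))
  }
  w0 <- with_local_seed(seed, stats::runif(n_par, -0.5, 0.5))
  opt <- stats::optim(w0, obj, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-9))
  structure(c(unpack(opt$par), list(levels = levels(y))),
            class = "bv_nnet1")
}

predict_nnet1 <- function(fit, X) {
  sig <- function(z) 1 / (1 + exp(-z))
  H <- sig(cbind(1, X) %*% fit$W1)
  as.numeric(sig(cbind(1, H) %*% fit$w2))
}

# Least-squares SVM with RBF kernel: solve the LS-SVM linear system for
# (bias, alphas), then Platt-calibrate the decision values into
# probabilities on the training data.
fit_lssvm <- function(X, y, cost = 1, gamma = NULL, seed = 1L) {
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  yy <- ifelse(as.integer(y) == 2L, 1, -1)
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / cost))
  sol <- solve(A, c(0, yy))
  b <- sol[1]; alpha <- sol[-1]
  d <- as.numeric(K %*% alpha + b)
  platt <- suppressWarnings(
    stats::glm(I(yy > 0) ~ d, family = stats::binomial()))
  structure(list(X = X, alpha = alpha, b = b, gamma = gamma,
                 platt = stats::coef(platt), levels = levels(y)),
            class = "bv_lssvm")
}

predict_lssvm <- function(fit, X) {
  d <- as.numeric(rbf_kernel(X, fit$X, fit$gamma) %*% fit$alpha + fit$b)
  z <- fit$platt[1] + fit$platt[2] * d
  1 / (1 + exp(-z))
}

# ---- the CV harness ------------------------------------------------------

#' Cross-validated evaluation of the five classification models
#'
#' For one comparison: stratified `n_folds`-fold cross-validation. In every
#' fold the feature scaler (center/scale) is fitted on the training rows
#' only, the minority class of the training rows is upsampled with
#' replacement to balance, the models are trained, and the held-out rows are
#' scored at the probability threshold. Metrics are computed from the
#' confusion counts pooled over folds.
#'
#' @param table Feature table (data.frame with `group`, optionally `sex` and
#'   `subject_id`, plus feature columns).
#' @param selected Character vector of feature columns to use (e.g. the
#'   output of [screen_features()]).
#' @param cmp A [comparison()].
#' @param cfg A [cv_config()].
#' @return A list of class `bv_cv_report`: `metrics` (data.frame model x
#'   accuracy/sensitivity/specificity in %), `confusion` (pooled counts per
#'   model), `folds` (per-fold detail incl. scaler parameters), `config`,
#'   `comparison`.
#' @export
run_cv <- function(table, selected, cmp, cfg = cv_config()) {
  sub <- comparison_subset(table, cmp, selected)
  X <- sub$X; y <- sub$y
  cnt <- base::table(y)
  if (min(cnt) < cfg$n_folds)
    warning("fewer observations (", min(cnt), ") in a class than folds (",
            cfg$n_folds, "); some folds will lack that class in test")
  subjects <- if ("subject_id" %in% names(sub$meta)) sub$meta$subject_id
  fold <- make_folds(y, cfg$n_folds, cfg$seed, subjects,
                     cfg$group_by_subject)

  models <- cfg$models
  conf <- matrix(0L, nrow = length(models), ncol = 4,
                 dimnames = list(models, c("tp", "fn", "tn", "fp")))
  fold_detail <- vector("list", cfg$n_folds)
  for (k in seq_len(cfg$n_folds)) {
    tr <- fold != k; te <- !tr
    if (!any(te)) next
    if (length(unique(y[tr])) < 2L)
      stop("stratification error: a class is absent from training fold ", k)
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/")
    ytr <- y[tr]
    if (cfg$upsample) {
      up <- upsample_training(Xtr, ytr, seed = cfg$seed + 1000L + k)
      Xtr <- up$X; ytr <- up$y
    }
    for (mi in seq_along(models)) {
      fit <- fit_one_model(models[mi], Xtr, ytr, cfg,
                           seed = cfg$seed + 100L * k + mi)
      pr <- predict_prob(fit, Xte)
      pred_pos <- pr >= cfg$threshold
      is_pos <- y[te] == "pos"
      conf[mi, ] <- conf[mi, ] + c(sum(pred_pos & is_pos),
                                   sum(!pred_pos & is_pos),
                                   sum(!pred_pos & !is_pos),
                                   sum(pred_pos & !is_pos))
    }
    fold_detail[[k]] <- list(fold = k, n_test = sum(te),
                             scaler = list(center = mu, scale = sdv),
                             train_counts = base::table(ytr))
  }
  metrics <- t(apply(conf, 1, function(cc)
    confusion_metrics(cc[["tp"]], cc[["fn"]], cc[["tn"]], cc[["fp"]])))
  structure(list(metrics = as.data.frame(metrics), confusion = conf,
                 folds = fold_detail, fold_id = fold, y = y,
                 config = cfg, comparison = cmp),
            class = "bv_cv_report")
}

#' @export
print.bv_cv_report <- function(x, ...) {
  cat(sprintf("<bv_cv_report> %s (%s), %d-fold CV\n", x$comparison$name,
              x$comparison$sex, x$config$n_folds))
  print(round(x$metrics, 1))
  invisible(x)
}
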