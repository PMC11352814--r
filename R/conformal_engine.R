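#' Model configuration for the conformal random-forest engine
#'
#' Bundles every tunable of the predictive machinery: forest size, conformal
#' confidence, number of aggregated conformal sub-models, neighborhood size
#' of the residual normalization for regression, feature-selection width, and
#' the master seed from which all internal randomness is derived.
#'
#' @param n_trees Trees per random forest, default 200.
#' @param confidence Conformal confidence level, default 0.8 (prediction sets
#'   target at most 20\% error under exchangeability).
#' @param n_acp_models Number of bootstrap-calibrated conformal sub-models
#'   aggregated by median, default 10.
#' @param knn_norm_k Neighbors used for residual normalization of the
#'   regression nonconformity, default 15.
#' @param seed Master seed, default 46.
#' @param k_best Features kept by univariate selection ("auto" resolves to
#'   10), default 10.
#' @param min_samples_split Minimum samples required to split a node,
#'   default 2 (trees grown to purity).
#' @param rebalance \code{"instance-hardness-threshold"} (categorical
#'   outcome), \code{"all-knn"} (continuous outcome) or \code{"none"}.
#' @param aggregation p-value / bound aggregation across sub-models; only
#'   \code{"median"} is implemented.
#' @param mondrian Use class-conditional (Mondrian) calibration instead of
#'   pooled calibration for classification. Default \code{FALSE}: with a few
#'   dozen patients the per-class calibration sets are so small that the
#'   minimum attainable class p-value exceeds 1 - confidence and every
#'   prediction set keeps both classes; pooled calibration preserves
#'   marginal validity while allowing conclusive predictions.
#' @return An object of class \code{model_config}.
#' @export
model_config <- function(n_trees = 200L, confidence = 0.8,
                         n_acp_models = 10L, knn_norm_k = 15L, seed = 46L,
                         k_best = 10L, min_samples_split = 2L,
                         rebalance = c("instance-hardness-threshold",
                                       "all-knn", "none"),
                         aggregation = "median", mondrian = FALSE) {
  rebalance <- match.arg(rebalance)
  stopifnot(confidence > 0, confidence < 1, n_acp_models >= 1,
            n_trees >= 1, knn_norm_k >= 1, k_best >= 1,
            aggregation == "median")
  structure(list(
    n_trees = as.integer(n_trees), confidence = confidence,
    n_acp_models = as.integer(n_acp_models),
    knn_norm_k = as.integer(knn_norm_k), seed = as.integer(seed),
    k_best = as.integer(k_best),
    min_samples_split = as.integer(min_samples_split),
    rebalance = rebalance, aggregation = aggregation,
    mondrian = isTRUE(mondrian)
  ), class = "model_config")
}

# deterministic child seeds: keep everything below 2^31
child_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset)) %% 2000000011L
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- rebalancing -----------------------------------------------------------

#' Correct class imbalance by instance removal
#'
#' \code{"all-knn"} applies repeated edited-nearest-neighbor cleaning with
#' k = 1, 2, 3: a majority-class sample is removed when any of its k nearest
#' neighbors (among the remaining samples, Euclidean distance on standardized
#' features) carries a different label. \code{"instance-hardness-threshold"}
#' estimates each sample's hardness as one minus the cross-validated random
#' forest probability of its own class, then drops the hardest majority
#' samples until the classes balance. In both methods the minority class is
#' never reduced and the majority class never drops below the minority count.
#'
#' @param X Numeric feature matrix.
#' @param y Two-level factor (or coercible) of class labels.
#' @param method \code{"all-knn"} or \code{"instance-hardness-threshold"}.
#' @param seed Seed for the cross-validated hardness estimate.
#' @return A list with the retained \code{X}, \code{y} and the integer
#'   indices \code{kept} into the original rows.
#' @export
rebalance <- function(X, y, method = c("all-knn",
                                       "instance-hardness-threshold"),
                      seed = 46L) {
  method <- match.arg(method)
  y <- factor(y)
  X <- as.matrix(X)
  tab <- table(y)
  if (length(tab) < 2 || any(tab < 2)) {
    warning("a class has fewer than 2 samples; skipping rebalancing")
    return(list(X = X, y = y, kept = seq_len(nrow(X))))
  }
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  if (tab[minority] == tab[majority]) majority <- names(tab)[2]
  n_min <- min(tab)

  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  kept <- seq_len(nrow(X))

  if (method == "all-knn") {
    for (k in 1:3) {
      repeat_removed <- FALSE
      d <- as.matrix(stats::dist(Z[kept, , drop = FALSE]))
      diag(d) <- Inf
      yk <- y[kept]
      n_maj_now <- sum(yk == majority)
      drop_local <- logical(length(kept))
      for (i in seq_along(kept)) {
        if (yk[i] != majority) next
        nb <- order(d[i, ])[seq_len(min(k, length(kept) - 1))]
        if (any(yk[nb] != yk[i])) drop_local[i] <- TRUE
      }
      # never shrink the majority below the minority count
      if (sum(drop_local) > n_maj_now - n_min) {
        cand <- which(drop_local)
        drop_local[] <- FALSE
        drop_local[cand[seq_len(n_maj_now - n_min)]] <- TRUE
      }
      if (any(drop_local)) {
        kept <- kept[!drop_local]
        repeat_removed <- TRUE
      }
      if (sum(y[kept] == majority) <= n_min) break
      if (!repeat_removed && k == 3) break
    }
  } else {
    probs <- cv_class_prob(Z, y, seed = seed)
    hardness <- 1 - probs
    excess <- sum(y == majority) - n_min
    if (excess > 0) {
      maj_idx <- which(y == majority)
      ord <- maj_idx[order(hardness[maj_idx], decreasing = TRUE)]
      kept <- sort(setdiff(seq_len(nrow(X)), ord[seq_len(excess)]))
    }
  }
  list(X = X[kept, , drop = FALSE], y = droplevels(y[kept]), kept = kept)
}

# 3-fold cross-validated probability of each sample's own class
cv_class_prob <- function(Z, y, seed, folds = 3L) {
  n <- length(y)
  fold <- with_seed(child_seed(seed, 7L), stratified_folds(y, folds))
  p_own <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(unique(y[tr])) < 2) { p_own[te] <- 0.5; next }
    fit <- ranger::ranger(
      x = Z[tr, , drop = FALSE], y = droplevels(y[tr]),
      num.trees = 100, probability = TRUE, num.threads = 1,
      seed = child_seed(seed, 11L + f))
    pr <- stats::predict(fit, data = Z[te, , drop = FALSE],
                         num.threads = 1)$predictions
    lev <- colnames(pr)
    p_own[te] <- pr[cbind(seq_along(te), match(as.character(y[te]), lev))]
    p_own[te][is.na(p_own[te])] <- 0
  }
  p_own
}

stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  start <- 0L
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- sample(idx)
    # running offset keeps fold sizes balanced across classes, so
    # folds = n yields a leave-one-out partition
    fold[idx] <- ((start + seq_along(idx) - 1L) %% folds) + 1L
    start <- start + length(idx)
  }
  fold
}

# conformal p-value of a nonconformity score against calibration scores,
# (rank + 1) / (n + 1) convention
conformal_pvalue <- function(alpha_new, calib) {
  (vapply(alpha_new, function(a) sum(calib >= a - 1e-12), 0L) + 1) /
    (length(calib) + 1)
}

# calibration quantile at the given confidence, (n + 1) rank convention,
# capped at the largest calibration score
calib_quantile <- function(scores, confidence) {
  k <- ceiling((length(scores) + 1) * confidence)
  if (k > length(scores)) max(scores) else sort(scores)[k]
}

# ---- univariate feature selection -----------------------------------------

#' Select the k best features by univariate F score
#'
#' Classification uses the one-way ANOVA F statistic, regression the
#' univariate regression F statistic. Constant features score zero and are
#' never chosen over varying ones; ties break by column order, keeping the
#' selection deterministic.
#'
#' @param X Feature matrix with column names.
#' @param y Outcome: factor for classification, numeric for regression.
#' @param k Number of features to keep (capped at \code{ncol(X)}).
#' @return Character vector of selected feature names, in score order.
#' @export
select_k_best <- function(X, y, k) {
  X <- as.matrix(X)
  k <- min(k, ncol(X))
  scores <- apply(X, 2, function(x) f_score(x, y))
  names(scores) <- colnames(X)
  ord <- order(-scores, seq_along(scores))
  colnames(X)[ord[seq_len(k)]]
}

f_score <- function(x, y) {
  if (stats::sd(x) == 0) return(0)
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    groups <- split(x, y)
    n <- length(x); g <- length(groups)
    gm <- mean(x)
    ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - gm)^2, 0))
    ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
    if (ssw == 0) return(Inf)
    (ssb / (g - 1)) / (ssw / (n - g))
  } else {
    if (stats::sd(y) == 0) return(0)
    r <- stats::cor(x, y)
    n <- length(x)
    r^2 * (n - 2) / max(1 - r^2, .Machine$double.eps)
  }
}

# ---- aggregated conformal classifier --------------------------------------

#' Fit an aggregated conformal random-forest classifier
#'
#' Fits \code{n_acp_models} conformal sub-models. Each sub-model draws a
#' bootstrap sample as its proper training set, fits a probability random
#' forest (balanced class weights, \code{mtry = floor(sqrt(p))}), and keeps
#' the out-of-bootstrap rows as its calibration set, scoring them with the
#' nonconformity 1 - predicted probability of the true class. Calibration is
#' pooled across classes by default (see the \code{mondrian} switch of
#' \code{\link{model_config}} for class-conditional calibration). Features
#' are standardized with statistics from the training data.
#'
#' @param X Feature matrix (rows = samples).
#' @param y Two-level factor of outcomes.
#' @param cfg A \code{\link{model_config}}.
#' @return An object of class \code{acp_classifier}.
#' @export
fit_acp_classifier <- function(X, y, cfg = model_config()) {
  X <- as.matrix(X); y <- factor(y)
  stopifnot(nlevels(y) == 2, all(table(y) >= 2))
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
  Z <- scale(X, center = ctr, scale = scl)
  n <- nrow(Z)
  lev <- levels(y)
  models <- vector("list", cfg$n_acp_models)
  for (m in seq_len(cfg$n_acp_models)) {
    sm <- child_seed(cfg$seed, 100L + m)
    for (try in 1:50) {
      boot <- with_seed(child_seed(sm, try), sample.int(n, n, replace = TRUE))
      calib <- setdiff(seq_len(n), unique(boot))
      if (length(unique(y[boot])) == 2 && length(calib) >= 2 &&
          (!cfg$mondrian || length(unique(y[calib])) == 2)) break
      if (try == 50) stop("could not draw a bootstrap split with both classes")
    }
    wt <- as.numeric(length(boot) / (2 * table(y[boot])[lev]))
    fit <- ranger::ranger(
      x = Z[boot, , drop = FALSE], y = y[boot],
      num.trees = cfg$n_trees, probability = TRUE,
      mtry = max(1L, floor(sqrt(ncol(Z)))),
      min.node.size = max(1L, cfg$min_samples_split - 1L),
      class.weights = wt, num.threads = 1, seed = sm)
    pr <- stats::predict(fit, data = Z[calib, , drop = FALSE],
                         num.threads = 1)$predictions
    pr <- pr[, lev, drop = FALSE]
    alpha <- 1 - pr[cbind(seq_along(calib), match(y[calib], lev))]
    models[[m]] <- list(
      forest = fit,
      calib_scores = if (cfg$mondrian) split(alpha, y[calib])[lev]
                     else alpha
    )
  }
  structure(list(models = models, levels = lev, center = ctr, scale = scl,
                 features = colnames(X), config = cfg),
            class = "acp_classifier")
}

#' Conformal prediction sets for new samples
#'
#' For each class, each sub-model converts the nonconformity of the new
#' sample into a p-value against its class-conditional calibration scores
#' with the usual (rank + 1) / (n + 1) formula; the aggregated p-value is the
#' median across sub-models. The prediction set contains every class whose
#' aggregated p-value exceeds 1 - confidence; a prediction is conclusive when
#' the set is a singleton.
#'
#' @param bundle An \code{acp_classifier}.
#' @param X_new Feature matrix of new samples (same columns as training).
#' @return A data.frame with one row per sample: per-class p-values
#'   (\code{p_<class>}), \code{set}, \code{conclusive}, and the point
#'   prediction \code{predicted} (class with the larger p-value).
#' @export
predict_set <- function(bundle, X_new) {
  stopifnot(inherits(bundle, "acp_classifier"))
  X_new <- as.matrix(X_new)[, bundle$features, drop = FALSE]
  Z <- scale(X_new, center = bundle$center, scale = bundle$scale)
  lev <- bundle$levels
  n_new <- nrow(Z)
  pvals <- array(NA_real_, dim = c(n_new, length(lev),
                                   length(bundle$models)))
  for (m in seq_along(bundle$models)) {
    mod <- bundle$models[[m]]
    pr <- stats::predict(mod$forest, data = Z, num.threads = 1)$predictions
    pr <- pr[, lev, drop = FALSE]
    for (ci in seq_along(lev)) {
      alpha_new <- 1 - pr[, ci]
      cal <- if (bundle$config$mondrian) mod$calib_scores[[ci]]
             else mod$calib_scores
      pvals[, ci, m] <- conformal_pvalue(alpha_new, cal)
    }
  }
  agg <- apply(pvals, c(1, 2), stats::median)
  thr <- 1 - bundle$config$confidence
  in_set <- agg > thr
  out <- as.data.frame(agg)
  names(out) <- paste0("p_", gsub("[^A-Za-z0-9]+", "_", lev))
  out$set <- apply(in_set, 1, function(r) paste(lev[r], collapse = "|"))
  out$conclusive <- rowSums(in_set) == 1
  out$predicted <- lev[max.col(agg, ties.method = "first")]
  rn <- rownames(X_new)
  if (!is.null(rn) && !anyDuplicated(rn)) rownames(out) <- rn
  attr(out, "submodel_pvalues") <- pvals
  out
}

# ---- aggregated conformal regressor ---------------------------------------

#' Fit an aggregated, residual-normalized conformal random-forest regressor
#'
#' As \code{\link{fit_acp_classifier}}, but for a continuous outcome (days of
#' survival). Nonconformity is the absolute residual divided by a local
#' difficulty estimate: the mean absolute training residual (out-of-bag)
#' among the \code{knn_norm_k} nearest training samples in standardized
#' feature space, floored at 0.01 standard deviations of the outcome. The
#' per-sub-model calibration quantile at the configured confidence uses the
#' (n + 1) rank convention, capped at the largest calibration score.
#'
#' @param X Feature matrix.
#' @param y_days Numeric outcome (days of survival).
#' @param cfg A \code{\link{model_config}}.
#' @return An object of class \code{acp_regressor}.
#' @export
fit_acp_regressor <- function(X, y_days, cfg = model_config()) {
  X <- as.matrix(X); y <- as.numeric(y_days)
  stopifnot(nrow(X) == length(y), all(y > 0))
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
  Z <- scale(X, center = ctr, scale = scl)
  n <- nrow(Z)
  beta <- 0.01 * stats::sd(y)
  if (!is.finite(beta) || beta == 0) beta <- .Machine$double.eps
  models <- vector("list", cfg$n_acp_models)
  for (m in seq_len(cfg$n_acp_models)) {
    sm <- child_seed(cfg$seed, 200L + m)
    for (try in 1:50) {
      boot <- with_seed(child_seed(sm, try), sample.int(n, n, replace = TRUE))
      calib <- setdiff(seq_len(n), unique(boot))
      if (length(calib) >= 2) break
      if (try == 50) stop("could not draw a bootstrap split with calibration rows")
    }
    fit <- ranger::ranger(
      x = Z[boot, , drop = FALSE], y = y[boot],
      num.trees = cfg$n_trees,
      mtry = max(1L, floor(sqrt(ncol(Z)))),
      min.node.size = max(1L, cfg$min_samples_split - 1L),
      num.threads = 1, seed = sm)
    res_oob <- abs(y[boot] - fit$predictions)
    res_oob[!is.finite(res_oob)] <- stats::median(res_oob[is.finite(res_oob)])
    train_Z <- Z[boot, , drop = FALSE]

    sigma_fun_env <- list(train_Z = train_Z, res = res_oob,
                          k = cfg$knn_norm_k, beta = beta)
    pred_cal <- stats::predict(fit, data = Z[calib, , drop = FALSE],
                               num.threads = 1)$predictions
    sig_cal <- knn_sigma(Z[calib, , drop = FALSE], sigma_fun_env)
    scores <- abs(y[calib] - pred_cal) / sig_cal
    q <- calib_quantile(scores, cfg$confidence)
    models[[m]] <- list(forest = fit, sigma_env = sigma_fun_env, q = q)
  }
  structure(list(models = models, center = ctr, scale = scl,
                 features = colnames(X), config = cfg, beta = beta),
            class = "acp_regressor")
}

knn_sigma <- function(Znew, env) {
  k <- min(env$k, nrow(env$train_Z))
  apply(Znew, 1, function(z) {
    d <- sqrt(colSums((t(env$train_Z) - z)^2))
    nb <- order(d)[seq_len(k)]
    mean(env$res[nb]) + env$beta
  })
}

#' Conformal prediction intervals for new samples
#'
#' Each sub-model emits the interval point prediction +/- calibration
#' quantile times local difficulty; the aggregated interval takes the median
#' of the lower and of the upper bounds across sub-models.
#'
#' @param bundle An \code{acp_regressor}.
#' @param X_new Feature matrix of new samples.
#' @return A data.frame with \code{predicted}, \code{lo}, \code{hi} (days)
#'   and \code{conclusive} (always \code{TRUE} for regression).
#' @export
predict_interval <- function(bundle, X_new) {
  stopifnot(inherits(bundle, "acp_regressor"))
  X_new <- as.matrix(X_new)[, bundle$features, drop = FALSE]
  Z <- scale(X_new, center = bundle$center, scale = bundle$scale)
  n_new <- nrow(Z)
  M <- length(bundle$models)
  lo <- hi <- ctr <- matrix(NA_real_, n_new, M)
  for (m in seq_len(M)) {
    mod <- bundle$models[[m]]
    pred <- stats::predict(mod$forest, data = Z, num.threads = 1)$predictions
    sig <- knn_sigma(Z, mod$sigma_env)
    ctr[, m] <- pred
    lo[, m] <- pred - mod$q * sig
    hi[, m] <- pred + mod$q * sig
  }
  rn <- rownames(X_new)
  if (is.null(rn) || anyDuplicated(rn)) rn <- NULL
  data.frame(
    predicted = apply(ctr, 1, stats::median),
    lo = apply(lo, 1, stats::median),
    hi = apply(hi, 1, stats::median),
    conclusive = TRUE,
    row.names = rn
  )
}

# ---- cross-validation ------------------------------------------------------

#' Cross-validated conformal pipeline with permutation importance
#'
#' Runs the full pipeline (rebalance, univariate feature selection, conformal
#' fit) inside each training fold of a stratified k-fold split, pools the
#' out-of-fold prediction sets or intervals, and measures permutation
#' importance: the mean degradation of out-of-fold point accuracy
#' (classification) or Q-squared (regression) when a feature's held-out
#' values are permuted, averaged over \code{n_perm} permutations per fold.
#' Nothing from a held-out fold influences rebalancing, selection or
#' fitting in that fold.
#'
#' @param X Feature matrix.
#' @param y Outcome: two-level factor (classification) or numeric days
#'   (regression).
#' @param cfg A \code{\link{model_config}}.
#' @param folds Number of folds, default 5.
#' @param strata Factor used for stratification and for rebalancing on the
#'   regression path (event status); defaults to \code{y} for
#'   classification.
#' @param n_perm Permutations per feature for importance, default 20.
#' @return A list: \code{predictions} (pooled out-of-fold data.frame, row
#'   order of \code{X}), \code{importance} (named numeric), \code{selected}
#'   (list of per-fold selected features), \code{fold} (fold assignment),
#'   \code{task}.
#' @export
cross_validate <- function(X, y, cfg = model_config(), folds = 5L,
                           strata = NULL, n_perm = 20L) {
  X <- as.matrix(X)
  task <- if (is.numeric(y)) "regression" else "classification"
  if (task == "classification") y <- factor(y)
  if (is.null(strata)) {
    if (task == "regression")
      stop("regression cross-validation needs 'strata' (event status)")
    strata <- y
  }
  strata <- factor(strata)
  n <- nrow(X)
  stopifnot(n >= folds, length(y) == n, length(strata) == n)
  fold <- with_seed(child_seed(cfg$seed, 1L), stratified_folds(strata, folds))

  preds <- vector("list", folds)
  selected <- vector("list", folds)
  imp_acc <- list()
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (!length(te)) next
    rb_method <- if (cfg$rebalance == "none") NULL else cfg$rebalance
    if (!is.null(rb_method)) {
      rb <- rebalance(X[tr, , drop = FALSE], strata[tr], method = rb_method,
                      seed = child_seed(cfg$seed, 10L + f))
      tr_keep <- tr[rb$kept]
    } else tr_keep <- tr
    y_tr <- y[tr_keep]
    feats <- select_k_best(X[tr_keep, , drop = FALSE], y_tr,
                           k = cfg$k_best)
    selected[[f]] <- feats
    Xtr <- X[tr_keep, feats, drop = FALSE]
    Xte <- X[te, feats, drop = FALSE]
    if (task == "classification") {
      bundle <- fit_acp_classifier(Xtr, y_tr, cfg)
      pr <- predict_set(bundle, Xte)
      base_metric <- mean(pr$predicted == as.character(y[te]))
    } else {
      bundle <- fit_acp_regressor(Xtr, as.numeric(y_tr), cfg)
      pr <- predict_interval(bundle, Xte)
      base_metric <- -sum((as.numeric(y[te]) - pr$predicted)^2)
    }
    pr$fold <- f
    pr$row <- te
    preds[[f]] <- pr

    # permutation importance on the held-out fold; all permutations of a
    # feature are stacked into one prediction call
    n_te <- length(te)
    for (feat in feats) {
      Xbig <- Xte[rep(seq_len(n_te), n_perm), , drop = FALSE]
      for (b in seq_len(n_perm)) {
        perm <- with_seed(child_seed(cfg$seed, 1000L + f * 37L +
                                       match(feat, feats) * 101L + b),
                          sample.int(n_te))
        Xbig[(b - 1L) * n_te + seq_len(n_te), feat] <- Xte[perm, feat]
      }
      block <- rep(seq_len(n_perm), each = n_te)
      if (task == "classification") {
        pred_big <- predict_set(bundle, Xbig)$predicted
        hits <- pred_big == rep(as.character(y[te]), n_perm)
        m_p <- tapply(hits, block, mean)
      } else {
        pred_big <- predict_interval(bundle, Xbig)$predicted
        sq <- (rep(as.numeric(y[te]), n_perm) - pred_big)^2
        m_p <- -tapply(sq, block, sum)
      }
      imp_acc[[feat]] <- c(imp_acc[[feat]], mean(base_metric - m_p))
    }
  }
  pooled <- do.call(rbind, preds)
  pooled <- pooled[order(pooled$row), , drop = FALSE]
  importance <- vapply(imp_acc, mean, 0)
  if (task == "regression") {
    # express regression importance as Q-squared degradation
    tss <- sum((as.numeric(y) - mean(as.numeric(y)))^2)
    importance <- importance / tss
  }
  list(predictions = pooled, importance = sort(importance, decreasing = TRUE),
       selected = selected, fold = fold, task = task)
}
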