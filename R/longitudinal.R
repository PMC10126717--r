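#' Linear trend test over sessions
#'
#' Ordinary least-squares regression of a session-level quantity (SNR,
#' decoding accuracy) on days post-implant; a non-zero slope is evaluated
#' with the regression F-test. If the slope is significant its sign gives
#' the verdict, otherwise the series is called trend-free. A perfectly
#' constant series is reported as `no-trend` with `F = 0` (the F statistic
#' is otherwise 0/0).
#'
#' @param days numeric session days (>= 3 distinct values).
#' @param values numeric session values, same length.
#' @param alpha significance level (default 0.05).
#' @return a `trend_result` list: `slope` (per day), `intercept`,
#'   `f_statistic`, `p_value`, `verdict` (`"increasing"`, `"decreasing"` or
#'   `"no-trend"`), `alpha`.
#' @export
fit_trend <- function(days, values, alpha = 0.05) {
  check_that(length(days) == length(values), "days and values must align")
  check_that(length(days) >= 3, "need at least 3 sessions")
  if (stats::var(days) == 0) stop("days are constant; no trend estimable", call. = FALSE)
  if (stats::var(values) == 0) {
    return(structure(list(slope = 0, intercept = values[1], f_statistic = 0,
                          p_value = 1, verdict = "no-trend", alpha = alpha),
                     class = "trend_result"))
  }
  fit <- stats::lm(values ~ days)
  sm <- summary(fit)
  f <- unname(sm$fstatistic[1])
  p <- stats::pf(f, sm$fstatistic[2], sm$fstatistic[3], lower.tail = FALSE)
  slope <- unname(stats::coef(fit)[2])
  verdict <- if (p >= alpha) "no-trend" else if (slope > 0) "increasing" else "decreasing"
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 f_statistic = f, p_value = unname(p), verdict = verdict,
                 alpha = alpha), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Linear trend: slope %.4g/day, F = %.3g, p = %.3g -> %s\n",
              x$slope, x$f_statistic, x$p_value, x$verdict))
  invisible(x)
}

#' Compare a trial-level metric across arm positions
#'
#' One-way ANOVA over groups (by default, transition errors per trial
#' grouped by arm position), followed by all pairwise comparisons with
#' Bonferroni correction; adjusted p-values are capped at 1.
#'
#' @param values numeric trial-level observations.
#' @param groups group labels (e.g. arm position), same length.
#' @param alpha significance level (default 0.05).
#' @return list with `anova_p` (overall one-way ANOVA p-value), `pairwise`
#'   data frame (`group1`, `group2`, `p_adjusted`, `significant`) with
#'   `k(k-1)/2` rows, and `alpha`.
#' @export
compare_positions <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  check_that(nlevels(groups) >= 2, "need at least 2 groups")
  check_that(all(table(groups) >= 2), "need >= 2 observations per group")
  fit <- stats::aov(values ~ groups)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  pt <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  p_adj <- apply(pairs, 2, function(pr) {
    v <- pt$p.value[pr[2], pr[1]]
    if (is.na(v)) v <- pt$p.value[pr[1], pr[2]]
    min(1, v)
  })
  list(anova_p = anova_p,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             p_adjusted = p_adj,
                             significant = p_adj < alpha,
                             row.names = NULL, stringsAsFactors = FALSE),
       alpha = alpha)
}

#' Two-sided Wilcoxon rank sum comparison
#'
#' Exact enumeration of the rank-sum distribution for small samples
#' (`m + n <= 12`, no ties); the normal approximation with tie correction
#' (and continuity correction) otherwise.
#'
#' @param a,b numeric samples (nonempty).
#' @return two-sided p-value.
#' @export
rank_sum_compare <- function(a, b) {
  check_that(length(a) > 0 && length(b) > 0, "both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  min(1, p)
}

# features + labels for one session recording (decimating raw recordings)
.session_features <- function(recording, bin_width = 50) {
  rec <- if (recording$sample_rate > 1000) preprocess(recording) else recording
  compute_mav(rec, bin_width = bin_width)
}

# per-trial accuracy of a static model trained on `train` and evaluated on
# `test` (recordings), restricted to a channel subset
.subset_session_accuracy <- function(train, test, channels, kind,
                                     bin_width = 50) {
  ftr <- .session_features(train, bin_width)
  keep <- match(channels, rownames(ftr$mav))
  check_that(!anyNA(keep), "unknown channel in subset")
  if (is.null(test)) {
    sub <- ftr
    sub$mav <- ftr$mav[keep, , drop = FALSE]
    cv <- loo_cross_validate(sub, train$trials, kind = kind)
    return(cv$predictions)
  }
  tr_bins <- lapply(seq_len(nrow(train$trials)), function(i) {
    bins_in_interval(ftr, train$trials$active_start[i], train$trials$active_end[i])
  })
  model <- if (kind == "hmm") {
    sub <- ftr; sub$mav <- ftr$mav[keep, , drop = FALSE]
    suppressWarnings(train_hmm_nb(sub))
  } else {
    train_static(ftr$mav[keep, unlist(tr_bins), drop = FALSE],
                 labels = rep(train$trials$movement, lengths(tr_bins)),
                 kind = kind)
  }
  fte <- .session_features(test, bin_width)
  preds <- vapply(seq_len(nrow(test$trials)), function(i) {
    bins <- bins_in_interval(fte, test$trials$active_start[i],
                             test$trials$active_end[i])
    predict_trial(model, fte$mav[keep, bins, drop = FALSE])
  }, character(1))
  data.frame(truth = test$trials$movement, predicted = preds,
             stringsAsFactors = FALSE)
}

#' Channel-ablation analysis across sessions
#'
#' Retrains a classifier per session on each channel subset and compares
#' per-trial accuracy, quantifying how much each electrode group (typically
#' the RPNIs) contributes to decoding each movement. Accuracy is evaluated
#' by leave-one-out cross-validation within each session, or on a held-out
#' test recording per session if `test_series` is given, then averaged
#' unweighted across sessions.
#'
#' @param train_series list of sessions as returned by
#'   [generate_longitudinal_series()] (each with `$recording`).
#' @param channel_subsets named list of channel-name vectors; conventionally
#'   the first is the full set and the second the reduced set.
#' @param test_series optional matching list of held-out sessions.
#' @param kind classifier: `"lda"` (default), `"nb"` or `"hmm"`.
#' @param bin_width feature bin width, ms.
#' @return an `ablation_result`: list with `per_subset` (data frame
#'   `subset`, `accuracy` in percent), `per_class` (`subset`, `class`,
#'   `accuracy`), `delta` (first minus second subset, percentage points),
#'   `confusion` (per-subset trial-level confusion matrices, row %).
#' @export
ablate_channels <- function(train_series, channel_subsets, test_series = NULL,
                            kind = c("lda", "nb", "hmm"), bin_width = 50) {
  kind <- match.arg(kind)
  check_that(length(channel_subsets) >= 1 && !is.null(names(channel_subsets)),
             "channel_subsets must be a named list")
  subset_names <- names(channel_subsets)
  per_subset <- per_class <- list()
  confusion <- list()
  for (sname in subset_names) {
    preds_all <- list()
    acc_sessions <- numeric(length(train_series))
    for (i in seq_along(train_series)) {
      test <- if (!is.null(test_series)) test_series[[i]]$recording
      pr <- .subset_session_accuracy(train_series[[i]]$recording, test,
                                     channel_subsets[[sname]], kind, bin_width)
      acc_sessions[i] <- mean(pr$predicted == pr$truth)
      preds_all[[i]] <- pr
    }
    preds <- do.call(rbind, preds_all)
    per_subset[[sname]] <- data.frame(subset = sname,
                                      accuracy = 100 * mean(acc_sessions),
                                      stringsAsFactors = FALSE)
    cls <- unique(preds$truth)
    per_class[[sname]] <- data.frame(
      subset = sname, class = cls,
      accuracy = vapply(cls, function(c) {
        100 * mean(preds$predicted[preds$truth == c] == c)
      }, numeric(1)), row.names = NULL, stringsAsFactors = FALSE)
    all_cls <- unique(c(preds$truth, preds$predicted))
    cm <- table(factor(preds$truth, all_cls), factor(preds$predicted, all_cls))
    cm <- 100 * cm / pmax(1, rowSums(cm))
    confusion[[sname]] <- cm
  }
  per_subset <- do.call(rbind, per_subset)
  delta <- if (length(subset_names) >= 2) {
    per_subset$accuracy[1] - per_subset$accuracy[2]
  } else NA_real_
  structure(list(per_subset = per_subset,
                 per_class = do.call(rbind, per_class),
                 delta = delta, confusion = confusion),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  for (i in seq_len(nrow(x$per_subset))) {
    cat(sprintf("  %-16s %6.1f%%\n", x$per_subset$subset[i],
                x$per_subset$accuracy[i]))
  }
  if (!is.na(x$delta)) cat(sprintf("  delta: %+.1f points\n", x$delta))
  invisible(x)
}

# extended infomax ICA on whitened 2D data: natural-gradient ascent with a
# kurtosis-sign-adaptive nonlinearity (handles sub-Gaussian sources such as
# bimodal movement clusters), deterministic identity initialization
.infomax_2d <- function(Z, lr = 0.02, max_iter = 5000, tol = 1e-9) {
  W <- diag(2)
  n <- nrow(Z)
  for (it in seq_len(max_iter)) {
    Y <- Z %*% t(W)
    k <- sign(colMeans(Y^4) - 3 * colMeans(Y^2)^2)
    k[k == 0] <- 1
    dW <- (diag(2) - sweep(crossprod(tanh(Y), Y), 1, k, "*") / n -
             crossprod(Y) / n) %*% W
    if (any(!is.finite(dW))) break
    W <- W + lr * dW
    if (sqrt(sum(dW^2)) < tol) break
  }
  W
}

#' 2D ICA-PCA decomposition of trial features
#'
#' Visualizes the multichannel MAV feature space: features are centered,
#' projected onto the top two principal components, whitened, and rotated
#' by infomax independent component analysis. Component sign follows a
#' fixed convention (the largest-magnitude channel loading of each
#' component is positive) and components are ordered by projected variance,
#' so the decomposition is deterministic.
#'
#' @param x trials x channels numeric matrix of per-trial feature vectors
#'   (>= 10 rows, >= 2 columns).
#' @return list with `coords` (trials x 2), `channel_vectors` (channels x 2
#'   back-projected loadings: the direction and relative magnitude each
#'   channel contributes in the 2D space), `var_explained` (fraction of
#'   total variance captured by the two components) and `transform`
#'   (channels x 2 projection matrix applied to centered features).
#' @export
icapca_2d <- function(x) {
  check_that(is.matrix(x) && nrow(x) >= 10 && ncol(x) >= 2,
             "need a trials x channels matrix with >= 10 trials, >= 2 channels")
  xc <- scale(x, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(xc, center = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-10 * pc$sdev[1]) {
    stop("feature matrix has rank < 2", call. = FALSE)
  }
  V2 <- pc$rotation[, 1:2, drop = FALSE]
  scores <- xc %*% V2
  sds <- apply(scores, 2, stats::sd)
  Z <- sweep(scores, 2, sds, "/")
  W <- .infomax_2d(Z)
  transform <- V2 %*% diag(1 / sds) %*% t(W)
  # project onto unit-norm independent directions so each component keeps
  # its scale in feature space (whitened scale would equalize signal and
  # noise components and hide cluster separation)
  transform <- sweep(transform, 2, sqrt(colSums(transform^2)), "/")
  coords <- xc %*% transform
  # order components by variance, fix signs by the dominant channel loading
  ord <- order(apply(coords, 2, stats::var), decreasing = TRUE)
  coords <- coords[, ord, drop = FALSE]
  transform <- transform[, ord, drop = FALSE]
  mixing <- pinv_svd(transform) # 2 x channels
  for (k in 1:2) {
    j <- which.max(abs(mixing[k, ]))
    if (mixing[k, j] < 0) {
      mixing[k, ] <- -mixing[k, ]
      coords[, k] <- -coords[, k]
      transform[, k] <- -transform[, k]
    }
  }
  channel_vectors <- t(mixing)
  rownames(channel_vectors) <- colnames(x)
  colnames(coords) <- colnames(channel_vectors) <- c("IC1", "IC2")
  var_explained <- sum(pc$sdev[1:2]^2) / sum(pc$sdev^2)
  list(coords = coords, channel_vectors = channel_vectors,
       var_explained = var_explained, transform = transform)
}

# Moore-Penrose pseudoinverse via SVD (for the 2D back-projection)
pinv_svd <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
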