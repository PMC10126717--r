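#' Train the HMM with Naive Bayes emissions
#'
#' Fits the streaming grasp classifier: latent states (by default one per
#' movement class) with diagonal-Gaussian emission distributions over the
#' per-channel MAV features (the Naive Bayes factorization: channels are
#' conditionally independent given the state). Emission means and variances
#' are per-state per-channel maximum-likelihood estimates with a variance
#' floor; the state-transition matrix is estimated from labelled bin-to-bin
#' transitions with add-one smoothing (which keeps the chain ergodic); the
#' initial distribution is uniform.
#'
#' With `states_per_class > 1`, each contiguous labelled run of a class is
#' split into that many equal temporal segments and states are assigned in
#' order, giving a left-to-right sub-chain per class without requiring EM.
#'
#' @param features a `feature_sequence` from [compute_mav()].
#' @param labels per-bin movement labels (default: the feature labels).
#' @param states_per_class latent states per movement class (>= 1).
#' @param var_floor emission variance floor, uV^2 (default 1e-4).
#' @param classes class set to model (default: the classes present in
#'   `labels`); a requested class with no labelled bins is an error.
#' @return an object of class `hmm_nb` with elements `classes`,
#'   `states_per_class`, `initial`, `transition`, `emission_mean`,
#'   `emission_var` (states x channels), `state_to_class`, `channels`.
#' @export
train_hmm_nb <- function(features, labels = features$labels,
                         states_per_class = 1, var_floor = 1e-4,
                         classes = NULL) {
  check_that(!is.null(labels), "per-bin labels are required")
  check_that(length(labels) == ncol(features$mav),
             "labels must match the number of feature bins")
  check_that(states_per_class >= 1, "states_per_class must be >= 1")
  if (is.null(classes)) classes <- unique(labels)
  if ("rest" %in% classes) classes <- c("rest", setdiff(classes, "rest"))
  counts <- table(factor(labels, classes))
  if (any(counts == 0)) {
    stop("no labelled bins for class '", names(counts)[counts == 0][1], "'",
         call. = FALSE)
  }
  if (any(counts < 10)) {
    warning("fewer than 10 labelled bins for: ",
            paste(names(counts)[counts < 10], collapse = ", "))
  }

  s <- states_per_class
  state_to_class <- rep(classes, each = s)
  n_states <- length(state_to_class)
  state_names <- if (s == 1) classes else
    paste(state_to_class, rep(seq_len(s), length(classes)), sep = ".")

  # assign a state index to every bin
  state_of <- integer(length(labels))
  r <- rle(labels)
  pos <- 0L
  for (k in seq_along(r$lengths)) {
    len <- r$lengths[k]
    base <- (match(r$values[k], classes) - 1L) * s
    seg <- if (s == 1) rep(1L, len) else pmin(s, ceiling(seq_len(len) / len * s))
    state_of[pos + seq_len(len)] <- base + seg
    pos <- pos + len
  }

  ch_names <- rownames(features$mav)
  emission_mean <- matrix(0, n_states, nrow(features$mav),
                          dimnames = list(state_names, ch_names))
  emission_var <- emission_mean
  for (st in seq_len(n_states)) {
    idx <- which(state_of == st)
    x <- features$mav[, idx, drop = FALSE]
    emission_mean[st, ] <- rowMeans(x)
    v <- rowMeans((x - emission_mean[st, ])^2)
    emission_var[st, ] <- pmax(v, var_floor)
  }

  trans_counts <- matrix(1, n_states, n_states,
                         dimnames = list(state_names, state_names)) # add-one
  if (length(state_of) > 1) {
    from <- state_of[-length(state_of)]; to <- state_of[-1]
    for (k in seq_along(from)) {
      trans_counts[from[k], to[k]] <- trans_counts[from[k], to[k]] + 1
    }
  }
  transition <- trans_counts / rowSums(trans_counts)

  structure(list(classes = classes, states_per_class = s,
                 initial = rep(1 / n_states, n_states),
                 transition = transition,
                 emission_mean = emission_mean, emission_var = emission_var,
                 state_to_class = state_to_class, channels = ch_names,
                 var_floor = var_floor),
            class = "hmm_nb")
}

#' @export
print.hmm_nb <- function(x, ...) {
  cat("HMM-NB decoder: ", length(x$classes), " classes (",
      paste(x$classes, collapse = ", "), "), ", length(x$state_to_class),
      " states, ", length(x$channels), " channels\n", sep = "")
  invisible(x)
}

# per-bin per-state Gaussian log-likelihoods (bins x states)
.emission_loglik <- function(model, mav) {
  n_states <- nrow(model$emission_mean)
  out <- matrix(0, ncol(mav), n_states)
  for (st in seq_len(n_states)) {
    mu <- model$emission_mean[st, ]; v <- model$emission_var[st, ]
    ll <- -0.5 * ((mav - mu)^2 / v + log(2 * pi * v))
    out[, st] <- colSums(ll)
  }
  out
}

#' Causal forward filtering of a feature stream
#'
#' Runs the HMM forward recursion in log space over the MAV stream, exactly
#' as the real-time decoder consumes 50 ms bins: at each bin the filtered
#' state posterior uses only past and present observations. Class posteriors
#' sum the state posteriors through the state-to-class map; the per-bin
#' prediction is the posterior argmax, ties broken by class-list order.
#'
#' @param model an `hmm_nb` model.
#' @param features a `feature_sequence` (channels must match the model).
#' @return a `decoded_stream`: list with `posterior` (bins x classes),
#'   `argmax` (character per bin) and `classes`.
#' @export
forward_filter <- function(model, features) {
  mav <- if (inherits(features, "feature_sequence")) features$mav else features
  check_that(nrow(mav) == length(model$channels),
             "feature channel count does not match the model")
  n_bins <- ncol(mav)
  n_states <- length(model$state_to_class)
  ll <- .emission_loglik(model, mav)
  log_trans <- log(model$transition)
  log_alpha <- log(model$initial) + ll[1, ]
  post_states <- matrix(0, n_bins, n_states)
  norm1 <- max(log_alpha) + log(sum(exp(log_alpha - max(log_alpha))))
  post_states[1, ] <- exp(log_alpha - norm1)
  log_alpha <- log_alpha - norm1
  if (n_bins > 1) {
    for (b in 2:n_bins) {
      # log-sum-exp over predecessor states
      m <- apply(log_alpha + log_trans, 2, function(col) {
        mx <- max(col); mx + log(sum(exp(col - mx)))
      })
      log_alpha <- m + ll[b, ]
      mx <- max(log_alpha)
      z <- mx + log(sum(exp(log_alpha - mx)))
      post_states[b, ] <- exp(log_alpha - z)
      log_alpha <- log_alpha - z
    }
  }
  cls_idx <- match(model$state_to_class, model$classes)
  posterior <- matrix(0, n_bins, length(model$classes),
                      dimnames = list(NULL, model$classes))
  for (st in seq_len(n_states)) {
    posterior[, cls_idx[st]] <- posterior[, cls_idx[st]] + post_states[, st]
  }
  argmax <- model$classes[apply(posterior, 1, which.max)]
  structure(list(posterior = posterior, argmax = argmax,
                 classes = model$classes), class = "decoded_stream")
}

#' Train a single-state Naive Bayes or LDA baseline
#'
#' The offline baselines: `nb` fits a per-class diagonal Gaussian by maximum
#' likelihood (with a variance floor); `lda` fits class means with a pooled
#' within-class covariance, ridge-regularized by `eps * trace(Sigma)/d * I`
#' so small calibration sets stay well-conditioned. Class priors are the
#' empirical bin frequencies.
#'
#' @param features a `feature_sequence` or channels x bins matrix.
#' @param labels per-bin movement labels.
#' @param kind `"nb"` or `"lda"`.
#' @param var_floor NB emission variance floor (uV^2).
#' @param ridge LDA ridge fraction of the average eigenvalue (default 1e-6).
#' @return an object of class `static_model`.
#' @export
train_static <- function(features, labels = NULL, kind = c("nb", "lda"),
                         var_floor = 1e-4, ridge = 1e-6) {
  kind <- match.arg(kind)
  mav <- if (inherits(features, "feature_sequence")) features$mav else features
  if (is.null(labels) && inherits(features, "feature_sequence")) labels <- features$labels
  check_that(!is.null(labels) && length(labels) == ncol(mav),
             "labels must match the number of feature bins")
  classes <- unique(labels)
  if ("rest" %in% classes) classes <- c("rest", setdiff(classes, "rest"))
  check_that(length(classes) >= 2, "need at least 2 classes")
  priors <- as.numeric(table(factor(labels, classes))) / length(labels)
  d <- nrow(mav)
  means <- matrix(0, length(classes), d, dimnames = list(classes, rownames(mav)))
  model <- list(kind = kind, classes = classes, priors = priors, means = means,
                channels = rownames(mav))
  if (kind == "nb") {
    vars <- means
    for (c in classes) {
      x <- mav[, labels == c, drop = FALSE]
      model$means[c, ] <- rowMeans(x)
      vars[c, ] <- pmax(rowMeans((x - model$means[c, ])^2), var_floor)
    }
    model$vars <- vars
  } else {
    S <- matrix(0, d, d)
    n_tot <- 0
    for (c in classes) {
      x <- mav[, labels == c, drop = FALSE]
      model$means[c, ] <- rowMeans(x)
      xc <- x - model$means[c, ]
      S <- S + tcrossprod(xc)
      n_tot <- n_tot + ncol(x)
    }
    S <- S / max(1, n_tot - length(classes))
    S <- S + diag(ridge * sum(diag(S)) / d + .Machine$double.eps, d)
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok) stop("pooled covariance singular after regularization", call. = FALSE)
    model$cov <- S
    model$cov_inv <- solve(S)
  }
  structure(model, class = "static_model")
}

#' @export
print.static_model <- function(x, ...) {
  cat(toupper(x$kind), " classifier: ", length(x$classes), " classes, ",
      length(x$channels), " channels\n", sep = "")
  invisible(x)
}

# class log-scores of a static model for feature column vectors (d x n)
.static_scores <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  scores <- matrix(0, ncol(x), length(model$classes),
                   dimnames = list(NULL, model$classes))
  for (ci in seq_along(model$classes)) {
    mu <- model$means[ci, ]
    if (model$kind == "nb") {
      v <- model$vars[ci, ]
      scores[, ci] <- colSums(-0.5 * ((x - mu)^2 / v + log(2 * pi * v))) +
        log(model$priors[ci])
    } else {
      xc <- x - mu
      scores[, ci] <- -0.5 * colSums(xc * (model$cov_inv %*% xc)) +
        log(model$priors[ci])
    }
  }
  scores
}

#' Per-bin class predictions of a static model
#'
#' @param model a `static_model`.
#' @param features a `feature_sequence` or channels x bins matrix.
#' @return character vector of predicted classes, one per bin.
#' @export
predict_bins <- function(model, features) {
  mav <- if (inherits(features, "feature_sequence")) features$mav else features
  scores <- .static_scores(model, mav)
  model$classes[apply(scores, 1, which.max)]
}

#' Predict the movement of one trial
#'
#' Open-loop per-trial decoding rule: NB and LDA classify the trial-averaged
#' per-channel MAV; the HMM-NB prediction is the most frequent per-bin class
#' of the causal forward filter over the trial (ties broken by the class
#' achieved earliest in the trial). Both rules deliberately ignore transient
#' errors.
#'
#' @param model an `hmm_nb` or `static_model`.
#' @param trial_features a `feature_sequence` or channels x bins matrix for
#'   the trial (>= 1 bin).
#' @return the predicted movement label.
#' @export
predict_trial <- function(model, trial_features) {
  mav <- if (inherits(trial_features, "feature_sequence")) trial_features$mav
         else trial_features
  if (!is.matrix(mav)) mav <- matrix(mav, ncol = 1)
  check_that(ncol(mav) >= 1, "trial must have at least one bin")
  if (inherits(model, "hmm_nb")) {
    out <- forward_filter(model, mav)$argmax
    tab <- table(out)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      first_seen <- vapply(top, function(cl) which(out == cl)[1], numeric(1))
      top <- top[which.min(first_seen)]
    }
    return(top)
  }
  avg <- rowMeans(mav)
  model$classes[which.max(.static_scores(model, avg)[1, ])]
}

#' Leave-one-out cross-validated trial accuracy
#'
#' One trial is held out per fold; the decoder is retrained on the remaining
#' trials and the held-out trial is predicted with [predict_trial()].
#'
#' @param features a `feature_sequence` for the whole calibration recording.
#' @param trials trial annotation data frame (as in [emg_recording]):
#'   `movement` plus sample intervals `start`/`end` and
#'   `active_start`/`active_end`.
#' @param kind `"hmm"`, `"nb"` or `"lda"`.
#' @param ... passed to the trainer.
#' @return list with `accuracy` (fraction correct), `predictions` data frame
#'   (`truth`, `predicted`) and `n_folds`.
#' @export
loo_cross_validate <- function(features, trials, kind = c("hmm", "nb", "lda"),
                               ...) {
  kind <- match.arg(kind)
  n <- nrow(trials)
  check_that(n >= 2, "need at least 2 trials")
  counts <- table(trials$movement)
  check_that(all(counts >= 2), "need >= 2 trials per class")
  trial_bins <- lapply(seq_len(n), function(i) {
    bins_in_interval(features, trials$active_start[i], trials$active_end[i])
  })
  full_bins <- lapply(seq_len(n), function(i) {
    bins_in_interval(features, trials$start[i], trials$end[i])
  })
  preds <- character(n)
  for (i in seq_len(n)) {
    held <- trial_bins[[i]]
    if (kind == "hmm") {
      keep <- setdiff(seq_len(ncol(features$mav)), full_bins[[i]])
      sub <- features
      sub$mav <- features$mav[, keep, drop = FALSE]
      sub$labels <- features$labels[keep]
      model <- suppressWarnings(train_hmm_nb(sub, ...))
    } else {
      train_idx <- unlist(trial_bins[-i])
      model <- train_static(features$mav[, train_idx, drop = FALSE],
                            labels = rep(trials$movement[-i],
                                         lengths(trial_bins)[-i]),
                            kind = kind, ...)
    }
    preds[i] <- predict_trial(model, features$mav[, held, drop = FALSE])
  }
  list(accuracy = mean(preds == trials$movement),
       predictions = data.frame(truth = trials$movement, predicted = preds,
                                stringsAsFactors = FALSE),
       n_folds = n)
}
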