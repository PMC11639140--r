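# Leave-one-state-out (TTO) / leave-one-pair-out (DCE) cross-validation.
# Each TTO fold refits on the remaining 31 states (plus all DCE data for
# hybrid scope), predicts the held-out state's disutility and compares it to
# that state's censored mean; each DCE fold refits without one pair and
# scores the held-out choices by out-of-sample log-likelihood only.

#' Censored mean disutility of one state's observations
#'
#' Intercept-only censored-normal (Tobit-type) MLE of the mean and s.d. of a
#' state's disutilities, right-censored at 2 (the cTTO floor of -1 on the
#' value scale). With no censored observations this is the arithmetic mean.
#'
#' @param values numeric TTO values in `[-1, 1]`, or a data frame with a
#'   `value` (and optionally `censored`) column.
#' @param censored optional logical vector; defaults to `value <= -1`.
#' @return List of class `"censored_state_mean"`: `mean` (disutility scale),
#'   `sigma`, `n`, `n_censored`, `all_censored`.
#' @examples
#' censored_state_mean(c(0.5, 0.7))$mean  # 0.4
#' @export
censored_state_mean <- function(values, censored = NULL) {
  if (is.data.frame(values)) {
    censored <- if ("censored" %in% names(values)) values$censored
    values <- values$value
  }
  if (length(values) < 2) stop("need at least 2 observations of the state")
  if (is.null(censored)) censored <- values <= -1
  y <- 1 - values
  y[censored] <- 2
  n <- length(y)
  out <- list(n = n, n_censored = sum(censored), all_censored = all(censored))
  if (!any(censored)) {
    out$mean <- mean(y)
    out$sigma <- stats::sd(y)
  } else if (all(censored)) {
    out$mean <- 2       # only a lower bound is identified
    out$sigma <- NA_real_
  } else {
    yu <- y[!censored]
    nc <- sum(censored)
    nll <- function(p) {
      mu <- p[1]
      sig <- p[2]
      -(sum(stats::dnorm(yu, mu, sig, log = TRUE)) +
          nc * stats::pnorm((mu - 2) / sig, log.p = TRUE))
    }
    start <- c(mean(c(yu, rep(2, nc))), max(stats::sd(yu), 0.1, na.rm = TRUE))
    res <- stats::optim(start, nll, method = "L-BFGS-B",
                        lower = c(-Inf, 1e-4), upper = c(Inf, Inf))
    out$mean <- res$par[1]
    out$sigma <- res$par[2]
  }
  class(out) <- "censored_state_mean"
  out
}

#' @export
print.censored_state_mean <- function(x, ...) {
  cat(sprintf("censored state mean: %.4f (sigma %.4f, n = %d, censored = %d%s)\n",
              x$mean, x$sigma, x$n, x$n_censored,
              if (x$all_censored) ", all censored: lower bound" else ""))
  invisible(x)
}

#' Out-of-sample agreement metrics
#'
#' Computes the six comparison metrics between predicted and target state
#' values: RMSE, MAE, Pearson's R, the one-way agreement intraclass
#' correlation (treating each (prediction, target) pair as two ratings of one
#' state), and Lin's concordance correlation coefficient
#' `2 cov / (var1 + var2 + (mean1 - mean2)^2)`.
#'
#' @param predictions,targets aligned numeric vectors.
#' @return Named list `rmse`, `mae`, `pearson_r`, `icc`, `ccc`. Correlations
#'   are `NA` when either vector has zero variance.
#' @examples
#' cv_metrics(1:5, 1:5 + 0.5)
#' @export
cv_metrics <- function(predictions, targets) {
  stopifnot(length(predictions) == length(targets))
  if (length(predictions) < 2) {
    return(list(rmse = NA_real_, mae = NA_real_, pearson_r = NA_real_,
                icc = NA_real_, ccc = NA_real_))
  }
  d <- predictions - targets
  out <- list(rmse = sqrt(mean(d^2)), mae = mean(abs(d)))
  if (stats::var(predictions) == 0 || stats::var(targets) == 0) {
    out$pearson_r <- out$icc <- out$ccc <- NA_real_
    return(out)
  }
  out$pearson_r <- stats::cor(predictions, targets)
  # one-way random ICC on the n x 2 rating matrix
  n <- length(predictions)
  rowm <- (predictions + targets) / 2
  grand <- mean(rowm)
  msb <- 2 * sum((rowm - grand)^2) / (n - 1)
  msw <- sum((predictions - targets)^2) / (2 * n)
  out$icc <- (msb - msw) / (msb + msw)
  out$ccc <- 2 * stats::cov(predictions, targets) /
    (stats::var(predictions) + stats::var(targets) +
       (mean(predictions) - mean(targets))^2)
  out
}

#' Cross-validate a candidate model
#'
#' Runs the leave-one-state-out (TTO) and/or leave-one-pair-out (DCE)
#' cross-validation for one model specification and assembles the
#' out-of-sample log-likelihoods and, for TTO, the agreement metrics between
#' the 32 held-out predictions and the censored state means.
#'
#' @inheritParams fit_value_model
#' @param control a [fit_control()]; fold refits are warm-started at the
#'   full-data fit with a single start.
#' @return Object of class `"cv_result"`: `spec`, `tto_folds` (data frame of
#'   per-state predictions, targets and held-out log-likelihoods),
#'   `dce_folds`, `metrics` (including `ll_tto`, `ll_dce`, `ll_combined`),
#'   `n_failed` folds.
#' @export
crossvalidate <- function(spec, tto = NULL, dce = NULL, tto_design = NULL,
                          dce_pairs = NULL, control = fit_control()) {
  stopifnot(inherits(spec, "value_model_spec"))
  full <- fit_value_model(spec, tto, dce, tto_design, dce_pairs, control)
  warm <- full$coefficients[full$free_names]
  fold_ctl <- fit_control(restarts = 1, maxit = control$maxit,
                          factr = control$factr, start = warm)
  tstats <- if (spec$scope != "dce") .tto_stats(tto, tto_design)
  dstats <- if (spec$scope != "tto") .dce_stats(dce, dce_pairs)
  tto_folds <- dce_folds <- NULL
  n_failed <- 0L

  if (spec$scope != "dce") {
    ids <- tstats$state_id
    rows <- vector("list", length(ids))
    for (k in seq_along(ids)) {
      drop <- tstats$state_id == ids[k]
      tr <- lapply(tstats, function(v)
        if (is.matrix(v)) v[!drop, , drop = FALSE] else v[!drop])
      obj <- .make_objective(spec, tr, dstats)
      res <- .optimize(obj, fold_ctl)
      conv <- res$convergence == 0
      if (!conv) n_failed <- n_failed + 1L
      cf <- .full_coefs(spec, res$par, obj$free$name)
      state <- tstats$L[drop, , drop = FALSE]
      pred <- predict_disutility(spec, cf, state)
      sig <- .tto_sigma(spec, cf, pred)
      obs <- tto[tto$state_id == ids[k], , drop = FALSE]
      tgt <- censored_state_mean(obs)
      cens <- if ("censored" %in% names(obs)) obs$censored else obs$value <= -1
      yu <- 1 - obs$value[!cens]
      ll <- sum(stats::dnorm(yu, pred, sig, log = TRUE)) +
        sum(cens) * stats::pnorm((pred - 2) / sig, log.p = TRUE)
      rows[[k]] <- data.frame(state_id = ids[k], prediction = pred,
                              target = tgt$mean, n = tgt$n,
                              n_censored = tgt$n_censored, oos_ll = ll,
                              converged = conv)
    }
    tto_folds <- do.call(rbind, rows)
  }

  if (spec$scope != "tto") {
    ids <- dstats$pair_id
    rows <- vector("list", length(ids))
    for (k in seq_along(ids)) {
      drop <- dstats$pair_id == ids[k]
      dr <- lapply(dstats, function(v)
        if (is.matrix(v)) v[!drop, , drop = FALSE] else v[!drop])
      obj <- .make_objective(spec, tstats, dr)
      res <- .optimize(obj, fold_ctl)
      conv <- res$convergence == 0
      if (!conv) n_failed <- n_failed + 1L
      cf <- .full_coefs(spec, res$par, obj$free$name)
      # held-out pair's choices scored at the fold coefficients
      hold <- lapply(dstats, function(v)
        if (is.matrix(v)) v[drop, , drop = FALSE] else v[drop])
      ll <- -.make_objective(spec, NULL, hold)$fn(res$par)
      rows[[k]] <- data.frame(pair_id = ids[k], n_a = hold$n_a, n_b = hold$n_b,
                              oos_ll = ll, converged = conv)
    }
    dce_folds <- do.call(rbind, rows)
  }

  metrics <- list(ll_tto = NA_real_, ll_dce = NA_real_)
  if (!is.null(tto_folds)) {
    ok <- tto_folds$converged
    metrics$ll_tto <- sum(tto_folds$oos_ll[ok])
    metrics <- c(metrics, cv_metrics(tto_folds$prediction[ok],
                                     tto_folds$target[ok]))
  }
  if (!is.null(dce_folds))
    metrics$ll_dce <- sum(dce_folds$oos_ll[dce_folds$converged])
  metrics$ll_combined <- sum(c(metrics$ll_tto, metrics$ll_dce), na.rm = TRUE)
  structure(list(spec = spec, full_fit = full, tto_folds = tto_folds,
                 dce_folds = dce_folds, metrics = metrics,
                 n_failed = n_failed, icc_variant = "one-way agreement"),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  print(x$spec)
  m <- x$metrics
  cat(sprintf("  OOS LL: TTO %.2f  DCE %.2f  combined %.2f\n",
              m$ll_tto, m$ll_dce, m$ll_combined))
  if (!is.null(m$rmse))
    cat(sprintf("  R %.4f  ICC %.4f  CCC %.4f  MAE %.4f  RMSE %.4f\n",
                m$pearson_r, m$icc, m$ccc, m$mae, m$rmse))
  if (x$n_failed > 0) cat("  ", x$n_failed, "fold refits did not converge\n")
  invisible(x)
}

#' Rank cross-validated models and pick a winner
#'
#' Ranks by combined out-of-sample log-likelihood (descending); ties are
#' broken by RMSE (ascending) and then by primary parameter count
#' (ascending, preferring parsimony).
#'
#' @param cv_results a list of [crossvalidate()] results (at least 2).
#' @return Data frame of class `"model_comparison"`, one row per model, best
#'   first; the winning row index is in attribute `"winner"`.
#' @export
select_model <- function(cv_results) {
  if (inherits(cv_results, "cv_result")) cv_results <- list(cv_results)
  if (length(cv_results) < 2) stop("need at least 2 cross-validated models")
  rows <- lapply(cv_results, function(cv) {
    m <- cv$metrics
    data.frame(
      family = cv$spec$family, scope = cv$spec$scope,
      tto_intercept = cv$spec$tto_intercept,
      dce_intercept = cv$spec$dce_intercept,
      n_params = param_count(cv$spec),
      ll_tto = m$ll_tto, ll_dce = m$ll_dce, ll_combined = m$ll_combined,
      pearson_r = if (is.null(m$pearson_r)) NA_real_ else m$pearson_r,
      icc = if (is.null(m$icc)) NA_real_ else m$icc,
      ccc = if (is.null(m$ccc)) NA_real_ else m$ccc,
      mae = if (is.null(m$mae)) NA_real_ else m$mae,
      rmse = if (is.null(m$rmse)) NA_real_ else m$rmse,
      n_failed = cv$n_failed)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$ll_combined, tab$rmse, tab$n_params)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "winner") <- 1L
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' The default candidate model grid
#'
#' The 16-model default sweep for a scope: 4 families crossed with the 4
#' on/off combinations of the TTO and DCE intercepts (for hybrid scope; for
#' single-source scopes the inapplicable intercept is dropped, giving 8
#' candidates).
#'
#' @param scope `"hybrid"`, `"tto"` or `"dce"`.
#' @return List of [model_spec()] objects.
#' @export
default_model_grid <- function(scope = "hybrid") {
  fams <- c("main", "linear", "cale", "calesep")
  specs <- list()
  for (f in fams) {
    ttoi <- if (scope == "dce") FALSE else c(FALSE, TRUE)
    dcei <- if (scope == "tto") FALSE else c(FALSE, TRUE)
    for (ti in ttoi) for (di in dcei)
      specs[[length(specs) + 1L]] <-
        model_spec(f, scope, tto_intercept = ti, dce_intercept = di)
  }
  specs
}
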