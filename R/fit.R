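# Maximum-likelihood fitting. Because every observation sits on one of the
# 32 design states (or pairs), both likelihoods collapse onto per-state
# sufficient statistics: for TTO the uncensored count, mean and within-state
# sum of squares plus the censored count; for DCE the per-pair A/B counts.
# The objective is therefore O(32) per evaluation regardless of sample size,
# which is what makes leave-one-state-out cross-validation and bootstrap
# refitting cheap.

# per-state TTO sufficient statistics aligned with design rows that have data
.tto_stats <- function(tto, design) {
  idx <- match(tto$state_id, design$state_id)
  if (anyNA(idx)) stop("TTO observation references an unknown state_id")
  cens <- if ("censored" %in% names(tto)) tto$censored else tto$value <= -1
  y <- 1 - tto$value
  m <- nrow(design)
  f <- factor(idx, levels = seq_len(m))
  n_unc <- as.vector(table(f[!cens]))
  n_cen <- as.vector(table(f[cens]))
  sum_y <- as.vector(tapply(y[!cens], f[!cens], sum, default = 0))
  sum_y2 <- as.vector(tapply(y[!cens]^2, f[!cens], sum, default = 0))
  sum_y[is.na(sum_y)] <- 0
  sum_y2[is.na(sum_y2)] <- 0
  ybar <- ifelse(n_unc > 0, sum_y / pmax(n_unc, 1), 0)
  ss <- pmax(sum_y2 - n_unc * ybar^2, 0)
  keep <- n_unc + n_cen > 0
  list(L = .state_matrix(design)[keep, , drop = FALSE],
       n_unc = n_unc[keep], ybar = ybar[keep], ss = ss[keep],
       n_cen = n_cen[keep], state_id = design$state_id[keep])
}

# per-pair DCE sufficient statistics
.dce_stats <- function(dce, pairs) {
  idx <- match(dce$pair_id, pairs$pair_id)
  if (anyNA(idx)) stop("DCE observation references an unknown pair_id")
  m <- nrow(pairs)
  f <- factor(idx, levels = seq_len(m))
  n_a <- as.vector(table(f[dce$choice == "A"]))
  n_b <- as.vector(table(f[dce$choice == "B"]))
  keep <- n_a + n_b > 0
  list(LA = .alt_matrix(pairs, "A")[keep, , drop = FALSE],
       LB = .alt_matrix(pairs, "B")[keep, , drop = FALSE],
       n_a = n_a[keep], n_b = n_b[keep], pair_id = pairs$pair_id[keep])
}

# fast positional predictor over a fixed level matrix
.make_predictor <- function(spec, free_names, L) {
  n <- nrow(L)
  if (spec$family == "main") {
    pn <- free_names[grepl("\\.l[0-9]$", free_names)]
    X <- matrix(0, n, length(pn), dimnames = list(NULL, pn))
    for (k in seq_along(pn)) {
      parts <- strsplit(pn[k], ".l", fixed = TRUE)[[1]]
      X[, k] <- as.numeric(L[, parts[1]] == as.integer(parts[2]))
    }
    cols <- match(pn, free_names)
    if (any(rowSums(X) != rowSums(L > 0)))
      stop("state contains a (dimension, level) with no main-effects coefficient")
    return(function(par) as.vector(X %*% par[cols]))
  }
  bidx <- match(DIM_CODES, free_names)
  if (spec$family == "linear") {
    Xl <- L / 7
    return(function(par) as.vector(Xl %*% par[bidx]))
  }
  # cale / calesep: curve templates with free slots
  Midx <- L + 1L
  if (spec$family == "cale") {
    lv <- .free_levels(spec)$UNION
    slots <- lv + 1L
    cidx <- match(paste0("lvl.", lv), free_names)
    tmpl <- rep(NA_real_, 8)
    tmpl[1] <- 0
    tmpl[8] <- 1
    used <- sort(unique(as.vector(Midx)))
    if (!all(used %in% c(1L, 8L, slots)))
      stop("state contains a level with no multiplier under this model scope")
    return(function(par) {
      cv <- tmpl
      cv[slots] <- par[cidx]
      mm <- matrix(cv[Midx], n, 8)
      as.vector(mm %*% par[bidx])
    })
  }
  fl <- .free_levels(spec)
  sS <- fl$SYMPTOM + 1L
  sI <- fl$IMPACT + 1L
  ciS <- match(paste0("lvlS.", fl$SYMPTOM), free_names)
  ciI <- match(paste0("lvlI.", fl$IMPACT), free_names)
  symcol <- DIM_CODES %in% SYMPTOM_DIMS
  tmpl <- rep(NA_real_, 8)
  tmpl[c(1, 8)] <- c(0, 1)
  usedS <- sort(unique(as.vector(Midx[, symcol])))
  usedI <- sort(unique(as.vector(Midx[, !symcol])))
  if (anyNA(tmpl[setdiff(usedS, sS)]) || anyNA(tmpl[setdiff(usedI, sI)]))
    stop("state contains a level with no multiplier under this model scope")
  function(par) {
    cvS <- tmpl; cvS[sS] <- par[ciS]
    cvI <- tmpl; cvI[sI] <- par[ciI]
    mm <- matrix(0, n, 8)
    mm[, symcol] <- cvS[Midx[, symcol]]
    mm[, !symcol] <- cvI[Midx[, !symcol]]
    as.vector(mm %*% par[bidx])
  }
}

# objective factory: returns fn (negative log-likelihood over free params)
# and components(par) giving the TTO/DCE pieces
.make_objective <- function(spec, tstats = NULL, dstats = NULL) {
  pt <- model_bounds(spec)
  free <- pt[!pt$fixed, , drop = FALSE]
  fn_names <- free$name
  i_alpha <- match("alpha_tto", fn_names)
  i_adce <- match("alpha_dce", fn_names)
  i_theta <- match("theta", fn_names)
  i_asig <- match("alpha_sigma", fn_names)
  i_bsig <- match("beta_sigma", fn_names)
  i_sig <- match("sigma", fn_names)
  pred_t <- if (!is.null(tstats)) .make_predictor(spec, fn_names, tstats$L)
  pred_a <- if (!is.null(dstats)) .make_predictor(spec, fn_names, dstats$LA)
  pred_b <- if (!is.null(dstats)) .make_predictor(spec, fn_names, dstats$LB)
  ll_tto <- function(par) {
    if (is.null(tstats)) return(0)
    mu <- pred_t(par)
    if (!is.na(i_alpha)) mu <- mu + par[i_alpha]
    sig <- if (!is.na(i_sig)) rep(par[i_sig], length(mu))
           else par[i_asig] + par[i_bsig] * mu
    # sigma feasibility: evaluate at a floored sigma with a smooth penalty so
    # finite-difference gradients stay sane when a probe crosses the bound
    pen <- 0
    if (any(sig < 1e-3)) {
      pen <- 1e6 * sum(pmax(0, 1e-3 - sig))
      sig <- pmax(sig, 1e-3)
    }
    ll <- -pen - 0.5 * sum(tstats$n_unc * log(2 * pi * sig^2) +
                       (tstats$ss + tstats$n_unc * (tstats$ybar - mu)^2) / sig^2)
    cen <- tstats$n_cen > 0
    if (any(cen))
      ll <- ll + sum(tstats$n_cen[cen] *
                       stats::pnorm((mu[cen] - 2) / sig[cen], log.p = TRUE))
    ll
  }
  ll_dce <- function(par) {
    if (is.null(dstats)) return(0)
    eta <- pred_b(par) - pred_a(par)
    if (!is.na(i_theta)) eta <- eta / par[i_theta]
    if (!is.na(i_adce)) eta <- eta + par[i_adce]
    sum(dstats$n_a * stats::plogis(eta, log.p = TRUE) +
          dstats$n_b * stats::plogis(-eta, log.p = TRUE))
  }
  list(
    free = free,
    fn = function(par) -(ll_tto(par) + ll_dce(par)),
    components = function(par) list(tto = if (!is.null(tstats)) ll_tto(par),
                                    dce = if (!is.null(dstats)) ll_dce(par)))
}

# run a block of code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Control parameters for model fitting
#'
#' @param restarts number of optimizer starts (the first from deterministic
#'   small positive values, the rest randomized from `seed`).
#' @param seed seed for the randomized restarts.
#' @param maxit maximum L-BFGS-B iterations per start.
#' @param factr L-BFGS-B relative convergence tolerance factor.
#' @param start optional named vector of free-parameter starting values
#'   (warm start); used as the first start.
#' @return List of class `"fit_control"`.
#' @export
fit_control <- function(restarts = 5, seed = 1, maxit = 1000, factr = 1e7,
                        start = NULL) {
  structure(list(restarts = restarts, seed = seed, maxit = maxit,
                 factr = factr, start = start), class = "fit_control")
}

#' Fit a value model by constrained maximum likelihood
#'
#' Maximizes the censored heteroscedastic TTO log-likelihood, the
#' conditional-logit DCE log-likelihood, or their hybrid sum (shared
#' preference parameters, DCE scale `theta`), under the box constraints of
#' [model_bounds()], using multi-start L-BFGS-B.
#'
#' @param spec a [model_spec()].
#' @param tto,dce observation tables (as simulated or read from CSV); supply
#'   the ones the scope requires.
#' @param tto_design,dce_pairs the design objects resolving state/pair ids.
#' @param control a [fit_control()] list.
#' @return Object of class `"value_fit"` with elements `coefficients` (full
#'   named vector, fixed parameters included), `loglik` (components and
#'   combined), `convergence` (0 = converged), `restarts`, `spec`.
#' @examples
#' oa <- build_orthogonal_array()
#' des <- map_to_states(oa, "TTO")
#' tto <- simulate_tto(make_truth(), des, n_respondents = 30, seed = 7)
#' fit <- fit_value_model(model_spec("cale", "tto"), tto = tto,
#'                        tto_design = des, control = fit_control(restarts = 2))
#' coef(fit)
#' @export
fit_value_model <- function(spec, tto = NULL, dce = NULL, tto_design = NULL,
                            dce_pairs = NULL, control = fit_control()) {
  stopifnot(inherits(spec, "value_model_spec"))
  if (inherits(control, "list") && !inherits(control, "fit_control"))
    control <- do.call(fit_control, control)
  if (spec$scope %in% c("tto", "hybrid") && (is.null(tto) || is.null(tto_design)))
    stop("scope '", spec$scope, "' requires tto data and tto_design")
  if (spec$scope %in% c("dce", "hybrid") && (is.null(dce) || is.null(dce_pairs)))
    stop("scope '", spec$scope, "' requires dce data and dce_pairs")
  tstats <- if (spec$scope != "dce") .tto_stats(tto, tto_design)
  dstats <- if (spec$scope != "tto") .dce_stats(dce, dce_pairs)
  obj <- .make_objective(spec, tstats, dstats)
  fit <- .optimize(obj, control)
  comps <- obj$components(fit$par)
  coefs <- .full_coefs(spec, fit$par, obj$free$name)
  structure(list(
    spec = spec, coefficients = coefs, free_names = obj$free$name,
    loglik = list(tto = comps$tto, dce = comps$dce,
                  combined = sum(unlist(comps))),
    convergence = fit$convergence, restarts = control$restarts,
    message = fit$message, counts = fit$counts), class = "value_fit")
}

# multi-start L-BFGS-B over an objective factory result
.optimize <- function(obj, control) {
  free <- obj$free
  np <- nrow(free)
  starts <- list()
  s1 <- free$init
  if (!is.null(control$start)) {
    s <- control$start[free$name]
    if (!anyNA(s)) s1 <- as.numeric(s)
  }
  starts[[1]] <- pmin(pmax(s1, free$lower), pmin(free$upper, 1e3))
  if (control$restarts > 1) {
    jit <- .with_seed(control$seed, lapply(seq_len(control$restarts - 1),
      function(i) {
        s <- free$init * stats::runif(np, 0.3, 1.7) +
          ifelse(is.finite(free$lower) & free$lower >= 0, 0,
                 stats::rnorm(np, 0, 0.1))
        pmin(pmax(s, free$lower + 1e-6), pmin(free$upper, 10))
      }))
    starts <- c(starts, jit)
  }
  run1 <- function(s) tryCatch(
    stats::optim(s, obj$fn, method = "L-BFGS-B",
                 lower = free$lower, upper = free$upper,
                 control = list(maxit = control$maxit, factr = control$factr)),
    error = function(e) NULL)
  best <- NULL
  for (s in starts) {
    res <- run1(s)
    if (is.null(res)) next
    # line-search failures on near-degenerate surfaces usually clear on a
    # refresh restart from the stopping point
    tries <- 0
    while (res$convergence != 0 && tries < 2) {
      res2 <- run1(res$par)
      if (is.null(res2) || res2$value > res$value + 1e-10) break
      res <- res2
      tries <- tries + 1
    }
    if (is.null(best) || res$value < best$value - 1e-10 ||
        (res$value < best$value + 1e-10 && res$convergence == 0 &&
           best$convergence != 0))
      best <- res
  }
  if (is.null(best))
    return(list(par = starts[[1]], value = Inf, convergence = 99L,
                message = "all restarts failed", counts = c(0, 0)))
  best
}

# expand free parameters into the full named coefficient vector
.full_coefs <- function(spec, par, free_names) {
  pt <- model_bounds(spec)
  out <- stats::setNames(pt$value, pt$name)
  out[free_names] <- par
  out
}

#' @export
coef.value_fit <- function(object, ...) object$coefficients

#' @export
print.value_fit <- function(x, ...) {
  print(x$spec)
  lab <- if (x$convergence == 0) "converged" else paste("NOT converged, code",
                                                        x$convergence)
  cat(sprintf("  log-likelihood: %s%s combined %.3f (%s)\n",
              if (!is.null(x$loglik$tto)) sprintf("TTO %.3f ", x$loglik$tto) else "",
              if (!is.null(x$loglik$dce)) sprintf("DCE %.3f ", x$loglik$dce) else "",
              x$loglik$combined, lab))
  print(round(x$coefficients, 4))
  if (!is.null(x$bootstrap)) {
    cat("  bootstrap SEs (B = ", x$bootstrap$B, ", ",
        x$bootstrap$n_dropped, " replicates dropped):\n", sep = "")
    print(round(x$bootstrap$se, 4))
  }
  invisible(x)
}

#' @export
predict.value_fit <- function(object, states, ...) {
  predict_disutility(object$spec, object$coefficients, states)
}

#' Cluster-bootstrap standard errors for a fitted model
#'
#' Respondents are the independent sampling unit; they are resampled with
#' replacement, independently within the TTO and DCE samples, the model is
#' refitted to each replicate (warm-started at the original estimate), and
#' the SE of each free coefficient is the standard deviation of its replicate
#' estimates. Non-converged replicates are dropped and counted; more than
#' 10\% dropped is an error.
#'
#' @param fit a `"value_fit"`.
#' @param tto,dce,tto_design,dce_pairs the data the model was fitted to.
#' @param B number of bootstrap replicates.
#' @param seed RNG seed for resampling.
#' @return The fit with a `bootstrap` element: `se` (named vector),
#'   `replicates` (B x p matrix), `B`, `n_dropped`.
#' @export
bootstrap_se <- function(fit, tto = NULL, dce = NULL, tto_design = NULL,
                         dce_pairs = NULL, B = 500, seed = 1) {
  stopifnot(inherits(fit, "value_fit"), B >= 2)
  spec <- fit$spec
  warm <- fit$coefficients[fit$free_names]
  reps <- matrix(NA_real_, B, length(warm),
                 dimnames = list(NULL, fit$free_names))
  conv <- logical(B)
  rs <- .with_seed(seed, lapply(seq_len(B), function(b) list(
    t = if (!is.null(tto)) sample(unique(tto$respondent_id), replace = TRUE),
    d = if (!is.null(dce)) sample(unique(dce$respondent_id), replace = TRUE))))
  split_t <- if (!is.null(tto)) split(seq_len(nrow(tto)), tto$respondent_id)
  split_d <- if (!is.null(dce)) split(seq_len(nrow(dce)), dce$respondent_id)
  for (b in seq_len(B)) {
    tto_b <- if (!is.null(tto)) .resample_cluster(tto, rs[[b]]$t, split_t)
    dce_b <- if (!is.null(dce)) .resample_cluster(dce, rs[[b]]$d, split_d)
    tstats <- if (spec$scope != "dce") .tto_stats(tto_b, tto_design)
    dstats <- if (spec$scope != "tto") .dce_stats(dce_b, dce_pairs)
    obj <- .make_objective(spec, tstats, dstats)
    res <- .optimize(obj, fit_control(restarts = 1, start = warm))
    if (res$convergence == 0) {
      reps[b, ] <- res$par
      conv[b] <- TRUE
    }
  }
  n_dropped <- sum(!conv)
  if (n_dropped > 0.1 * B)
    stop("bootstrap failed: ", n_dropped, " of ", B,
         " replicates did not converge")
  fit$bootstrap <- list(
    se = apply(reps[conv, , drop = FALSE], 2, stats::sd),
    replicates = reps[conv, , drop = FALSE], B = B, n_dropped = n_dropped)
  fit
}

# stack the rows of the drawn respondent ids (duplicates get fresh ids)
.resample_cluster <- function(obs, ids, row_split = NULL) {
  if (is.null(row_split)) row_split <- split(seq_len(nrow(obs)), obs$respondent_id)
  sets <- row_split[as.character(ids)]
  out <- obs[unlist(sets, use.names = FALSE), , drop = FALSE]
  out$respondent_id <- rep(seq_along(ids), lengths(sets))
  out
}
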