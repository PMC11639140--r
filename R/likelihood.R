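# Log-likelihoods. TTO values are modelled as disutilities y = 1 - value,
# right-censored at 2 (the cTTO floor of -1): uncensored observations
# contribute normal log densities, censored ones log Phi((xb - 2)/sigma).
# DCE choices contribute binary-logit terms on the latent-difference
# predictor (d(B) - d(A)) / theta + alpha_dce, with theta only in hybrid
# scope (DCE-only coefficients live on their own latent scale).

# per-observation sigma; errors (or penalizes, for the optimizer) when <= 0
.tto_sigma <- function(spec, coefs, pred) {
  if (spec$heteroscedastic)
    .coef_get(coefs, "alpha_sigma") + .coef_get(coefs, "beta_sigma") * pred
  else rep(.coef_get(coefs, "sigma"), length(pred))
}

#' Censored heteroscedastic TTO log-likelihood
#'
#' @param spec a [model_spec()] whose scope includes TTO data.
#' @param coefs named coefficient vector.
#' @param tto TTO observations (`respondent_id`, `state_id`, `value`, and
#'   optionally `censored`; values of -1 are censored by default).
#' @param design the TTO `"valuation_design"` giving each `state_id` its
#'   levels.
#' @return The log-likelihood (scalar).
#' @examples
#' des <- map_to_states(build_orthogonal_array(), "TTO")
#' tto <- simulate_tto(make_truth(), des, n_respondents = 5, seed = 1)
#' spec <- model_spec("linear", "tto")
#' cf <- c(make_truth()$beta_dim, alpha_sigma = 0.25, beta_sigma = 0.1)
#' tto_loglik(spec, cf, tto, des)
#' @export
tto_loglik <- function(spec, coefs, tto, design) {
  if (spec$scope == "dce") stop("spec scope does not include TTO data")
  idx <- match(tto$state_id, design$state_id)
  if (anyNA(idx)) stop("TTO observation references an unknown state_id")
  pred <- predict_disutility(spec, coefs, design)[idx]
  sig <- .tto_sigma(spec, coefs, pred)
  if (any(sig <= 0)) stop("nonpositive sigma for at least one observation")
  cens <- if ("censored" %in% names(tto)) tto$censored else tto$value <= -1
  y <- 1 - tto$value
  y[cens] <- 2  # a censored record means y in [2, Inf); its stored value is moot
  ll_unc <- sum(stats::dnorm(y[!cens], pred[!cens], sig[!cens], log = TRUE))
  ll_cen <- sum(stats::pnorm((pred[cens] - 2) / sig[cens], log.p = TRUE))
  ll_unc + ll_cen
}

#' Conditional-logit DCE log-likelihood
#'
#' Standard Bernoulli form: `sum(y log p + (1 - y) log(1 - p))` with
#' `p = plogis((d(B) - d(A)) / theta + alpha_dce)` and `y = 1` for a choice
#' of A. `strict_form = TRUE` evaluates the degenerate variant in which the
#' `(1 - y)` factor is dropped from the second term (for comparison only; it
#' is not a proper likelihood).
#'
#' @param spec a [model_spec()] whose scope includes DCE data.
#' @param coefs named coefficient vector.
#' @param dce DCE observations (`respondent_id`, `pair_id`, `choice`).
#' @param pairs the `"dce_design"`.
#' @param strict_form drop the `(1 - y)` factor (default `FALSE`).
#' @return The log-likelihood (scalar).
#' @export
dce_loglik <- function(spec, coefs, dce, pairs, strict_form = FALSE) {
  if (spec$scope == "tto") stop("spec scope does not include DCE data")
  idx <- match(dce$pair_id, pairs$pair_id)
  if (anyNA(idx)) stop("DCE observation references an unknown pair_id")
  da <- predict_disutility(spec, coefs, .alt_matrix(pairs, "A"))
  db <- predict_disutility(spec, coefs, .alt_matrix(pairs, "B"))
  eta <- db - da
  if (spec$scope == "hybrid") {
    theta <- .coef_get(coefs, "theta")
    if (theta <= 0) stop("theta must be positive")
    eta <- eta / theta
  }
  if (spec$dce_intercept) eta <- eta + .coef_get(coefs, "alpha_dce")
  eta <- eta[idx]
  y <- dce$choice == "A"
  if (strict_form)
    return(sum(stats::plogis(eta, log.p = TRUE) * y +
                 stats::plogis(-eta, log.p = TRUE)))
  sum(stats::plogis(ifelse(y, eta, -eta), log.p = TRUE))
}

#' Hybrid log-likelihood
#'
#' Sum of the TTO and DCE components at shared coefficients, with the scale
#' `theta` applying to the DCE predictor only. Either component may be empty
#' (`NULL`), in which case the other is returned unchanged.
#'
#' @inheritParams tto_loglik
#' @inheritParams dce_loglik
#' @return The combined log-likelihood.
#' @export
hybrid_loglik <- function(spec, coefs, tto = NULL, dce = NULL,
                          design = NULL, pairs = NULL) {
  ll <- 0
  if (!is.null(tto) && nrow(tto)) ll <- ll + tto_loglik(spec, coefs, tto, design)
  if (!is.null(dce) && nrow(dce)) ll <- ll + dce_loglik(spec, coefs, dce, pairs)
  ll
}
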