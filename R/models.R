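# Candidate value-model families. A coefficient set plus a health state
# yields a predicted disutility:
#   main:    alpha + sum over (dim, level) indicators       beta[dim, level]
#   linear:  alpha + sum_dim level * beta_dim / 7
#   cale:    alpha + sum_dim m(level) * beta_dim, m shared across dimensions
#   calesep: as cale with separate level curves m for the SYMPTOM and IMPACT
#            presentation groups
# All disutility coefficients are box-constrained to [0, Inf); the CALE level
# multipliers live in [0, 1] with the level-7 multiplier fixed at 1 so that
# beta_dim reads as the level-7 disutility (which is also why the linear
# model divides by 7).

#' Specify a candidate value model
#'
#' @param family `"main"`, `"linear"`, `"cale"` or `"calesep"`.
#' @param scope `"tto"`, `"dce"` or `"hybrid"` (which data the model is fitted
#'   to; determines the observed level sets and the nuisance parameters).
#' @param tto_intercept include a TTO intercept `alpha_tto` (disutility
#'   units, applied to every valued state)?
#' @param dce_intercept include an alternative-position intercept `alpha_dce`
#'   on the DCE latent-difference predictor? Only meaningful when the scope
#'   includes DCE data.
#' @param heteroscedastic model the TTO residual s.d. as
#'   `sigma_j = alpha_sigma + beta_sigma * predicted disutility`? Only
#'   meaningful when the scope includes TTO data; otherwise a single `sigma`
#'   is used (or none, for DCE-only models).
#' @return An object of class `"value_model_spec"`.
#' @examples
#' model_spec("cale", "hybrid")
#' @export
model_spec <- function(family = c("cale", "main", "linear", "calesep"),
                       scope = c("hybrid", "tto", "dce"),
                       tto_intercept = FALSE,
                       dce_intercept = (scope != "tto"),
                       heteroscedastic = (scope != "dce")) {
  family <- match.arg(family)
  scope <- match.arg(scope)
  dce_intercept <- isTRUE(dce_intercept[1])
  heteroscedastic <- isTRUE(heteroscedastic[1])
  if (scope == "tto" && dce_intercept)
    stop("a DCE intercept is meaningful only when the scope includes DCE data")
  if (scope == "dce" && isTRUE(tto_intercept))
    stop("a TTO intercept is not identified from DCE data (it cancels in the choice predictor)")
  if (scope == "dce" && heteroscedastic)
    stop("heteroscedasticity is meaningful only when the scope includes TTO data")
  structure(list(family = family, scope = scope,
                 tto_intercept = isTRUE(tto_intercept),
                 dce_intercept = dce_intercept,
                 heteroscedastic = heteroscedastic),
            class = "value_model_spec")
}

#' @export
print.value_model_spec <- function(x, ...) {
  cat(sprintf("Value model: %s (%s scope)%s%s%s\n", toupper(x$family), x$scope,
              if (x$tto_intercept) " + TTO intercept" else "",
              if (x$dce_intercept) " + DCE intercept" else "",
              if (x$heteroscedastic) " + heteroscedastic sigma" else ""))
  cat("  primary parameters:", param_count(x), "\n")
  invisible(x)
}

.spec_arm <- function(spec) switch(spec$scope, tto = "TTO", dce = "DCE",
                                   hybrid = "HYBRID")

# free CALE level-multiplier levels (level 0 is reference, level 7 fixed at 1)
.free_levels <- function(spec) {
  lv <- observed_levels(.spec_arm(spec))
  list(SYMPTOM = setdiff(lv$SYMPTOM, c(0L, 7L)),
       IMPACT = setdiff(lv$IMPACT, c(0L, 7L)),
       UNION = setdiff(sort(union(lv$SYMPTOM, lv$IMPACT)), c(0L, 7L)))
}

#' Count the free primary parameters of a model
#'
#' Counts the free preference parameters (dimension and level coefficients),
#' excluding intercepts, the DCE scale `theta` and the noise parameters.
#'
#' @param spec a [model_spec()].
#' @return Integer count.
#' @examples
#' param_count(model_spec("main", "hybrid")) # 44
#' param_count(model_spec("linear", "tto"))  # 8
#' @export
param_count <- function(spec) {
  stopifnot(inherits(spec, "value_model_spec"))
  fl <- .free_levels(spec)
  switch(spec$family,
    main = count_main_effect_params(.spec_arm(spec)),
    linear = 8L,
    cale = 8L + length(fl$UNION),
    calesep = 8L + length(fl$SYMPTOM) + length(fl$IMPACT))
}

#' Parameter box constraints and fixed values
#'
#' Returns one row per model parameter with its bounds, starting value and
#' whether it is fixed. Disutility-bearing coefficients are bounded to
#' `[0, Inf)`; CALE level multipliers to `[0, 1]` with the level-7 multiplier
#' fixed at 1 (the identification pin that makes `beta_dim` the level-7
#' disutility); `theta > 0`; `alpha_sigma >= 1e-3` (a numerical floor far
#' below any real elicitation noise) with `beta_sigma` free but
#' checked for sigma positivity over the design during fitting.
#'
#' @param spec a [model_spec()].
#' @return Data frame with columns `name`, `lower`, `upper`, `init`, `fixed`,
#'   `value` (the value of fixed parameters), `primary`.
#' @examples
#' model_bounds(model_spec("cale", "hybrid"))
#' @export
model_bounds <- function(spec) {
  stopifnot(inherits(spec, "value_model_spec"))
  rows <- list()
  add <- function(name, lower, upper, init, fixed = FALSE, value = NA_real_,
                  primary = TRUE)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, lower = lower, upper = upper, init = init, fixed = fixed,
      value = value, primary = primary)
  lv <- observed_levels(.spec_arm(spec))
  if (spec$family == "main") {
    for (d in DIM_CODES) {
      set <- if (d %in% SYMPTOM_DIMS) lv$SYMPTOM else lv$IMPACT
      for (l in setdiff(set, 0L))
        add(paste0(d, ".l", l), 0, Inf, 0.05 * l)
    }
  } else {
    for (d in DIM_CODES) add(d, 0, Inf, 0.3)
    if (spec$family == "cale") {
      for (l in .free_levels(spec)$UNION)
        add(paste0("lvl.", l), 0, 1, l / 7)
      add("lvl.7", 1, 1, 1, fixed = TRUE, value = 1)
    } else if (spec$family == "calesep") {
      fl <- .free_levels(spec)
      for (l in fl$SYMPTOM) add(paste0("lvlS.", l), 0, 1, l / 7)
      add("lvlS.7", 1, 1, 1, fixed = TRUE, value = 1)
      for (l in fl$IMPACT) add(paste0("lvlI.", l), 0, 1, l / 7)
      add("lvlI.7", 1, 1, 1, fixed = TRUE, value = 1)
    }
  }
  if (spec$tto_intercept) add("alpha_tto", -Inf, Inf, 0, primary = FALSE)
  if (spec$scope != "tto" && spec$dce_intercept)
    add("alpha_dce", -Inf, Inf, 0, primary = FALSE)
  if (spec$scope == "hybrid") add("theta", 1e-6, Inf, 1, primary = FALSE)
  if (spec$scope != "dce") {
    if (spec$heteroscedastic) {
      add("alpha_sigma", 1e-3, Inf, 0.3, primary = FALSE)
      add("beta_sigma", -Inf, Inf, 0, primary = FALSE)
    } else {
      add("sigma", 1e-3, Inf, 0.3, primary = FALSE)
    }
  }
  do.call(rbind, rows)
}

# coefficient lookup with informative error
.coef_get <- function(coefs, name, default = NULL) {
  if (name %in% names(coefs)) return(unname(coefs[[name]]))
  if (!is.null(default)) return(default)
  stop("missing coefficient '", name, "' for this model specification")
}

#' Predicted disutility of health states
#'
#' Evaluates the family's disutility equation at a coefficient set. With no
#' intercept the best (all-zero) state has disutility 0 by construction.
#'
#' @param spec a [model_spec()].
#' @param coefs named numeric vector of coefficients (fixed parameters such
#'   as the level-7 multiplier may be omitted; they default to their pinned
#'   values).
#' @param states states coercible to a state matrix.
#' @return Numeric vector of nonnegative disutilities (plus the intercept,
#'   if any).
#' @examples
#' spec <- model_spec("linear", "tto", heteroscedastic = FALSE)
#' cf <- c(WE = 0.35, LO = 0, DA = 0, LE = 0, PA = 0, TI = 0, AN = 0, DE = 0,
#'         sigma = 0.3)
#' predict_disutility(spec, cf, make_state(c(7, 0, 0, 0, 0, 0, 0, 0))) # 0.35
#' @export
predict_disutility <- function(spec, coefs, states) {
  stopifnot(inherits(spec, "value_model_spec"))
  m <- .state_matrix(states)
  alpha <- if (spec$tto_intercept) .coef_get(coefs, "alpha_tto") else 0
  if (spec$family == "main") {
    d <- rep(0, nrow(m))
    for (j in seq_along(DIM_CODES)) {
      lv <- m[, j]
      for (l in unique(lv[lv > 0L]))
        d[lv == l] <- d[lv == l] + .coef_get(coefs, paste0(DIM_CODES[j], ".l", l))
    }
    return(alpha + d)
  }
  beta <- vapply(DIM_CODES, function(d) .coef_get(coefs, d), 0)
  if (any(beta < 0)) stop("negative dimension coefficient")
  mult <- .multiplier_matrix(spec, coefs)  # 8 levels x 8 dims
  mm <- matrix(mult[cbind(as.vector(m) + 1L, rep(1:8, each = nrow(m)))],
               nrow(m), 8)
  if (anyNA(mm))
    stop("state contains a level with no multiplier under this model scope ",
         "(unobserved levels are handled by tariff interpolation)")
  alpha + as.vector(mm %*% beta)
}

# level-multiplier lookup, rows = levels 0..7, cols = dimensions
.multiplier_matrix <- function(spec, coefs) {
  out <- matrix(NA_real_, 8, 8, dimnames = list(0:7, DIM_CODES))
  if (spec$family == "linear") {
    out[] <- (0:7) / 7
    return(out)
  }
  get_curve <- function(prefix, free) {
    cv <- rep(NA_real_, 8)
    cv[1] <- 0
    cv[8] <- .coef_get(coefs, paste0(prefix, ".7"), default = 1)
    for (l in free) cv[l + 1] <- .coef_get(coefs, paste0(prefix, ".", l))
    cv
  }
  if (spec$family == "cale") {
    cv <- get_curve("lvl", .free_levels(spec)$UNION)
    out[] <- cv
  } else {
    fl <- .free_levels(spec)
    out[, SYMPTOM_DIMS] <- get_curve("lvlS", fl$SYMPTOM)
    out[, IMPACT_DIMS] <- get_curve("lvlI", fl$IMPACT)
  }
  out
}

#' Serialize a coefficient set to JSON
#'
#' Writes the family, scope, constraint metadata and coefficient values of a
#' fitted model (or any named coefficient vector) to JSON.
#'
#' @param spec a [model_spec()].
#' @param coefs named coefficient vector.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_coefficients_json <- function(spec, coefs, path) {
  pt <- model_bounds(spec)
  obj <- list(
    family = spec$family, scope = spec$scope,
    tto_intercept = spec$tto_intercept, dce_intercept = spec$dce_intercept,
    heteroscedastic = spec$heteroscedastic,
    coefficients = as.list(coefs),
    fixed = as.list(stats::setNames(pt$value[pt$fixed], pt$name[pt$fixed])),
    bounds = pt[, c("name", "lower", "upper")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a coefficient set written by [write_coefficients_json()]
#'
#' @param path JSON file.
#' @return List with elements `spec` and `coefficients`.
#' @export
read_coefficients_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- model_spec(obj$family, obj$scope, obj$tto_intercept,
                     obj$dce_intercept, obj$heteroscedastic)
  list(spec = spec, coefficients = unlist(obj$coefficients))
}
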