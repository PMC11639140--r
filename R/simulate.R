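# Synthetic respondent cohorts: cTTO values from a latent disutility with
# heteroscedastic normal noise and a censoring floor at -1, and DCE choices
# from a binary logit on the rescaled latent-utility difference.

#' Define a generating preference structure
#'
#' A truth profile is the generative counterpart of a fitted value model: a
#' CALE-type disutility function d(state) = alpha + sum_dim beta_dim *
#' m(level), a TTO noise law sigma(state) = alpha_sigma + beta_sigma *
#' d(state), a DCE scale `theta` and an alternative-position intercept.
#'
#' Profiles:
#' \describe{
#'   \item{`"paper-like"`}{substantial disutility on all eight dimensions with
#'     the largest losses on pain (PA) and depression (DE); a flat level curve
#'     between levels 3 and 4 and a large drop between levels 5 and 7; worst
#'     state disutility above 2, so severe states are censored at the TTO
#'     floor with appreciable probability.}
#'   \item{`"linear"`}{the same dimension weights with an exactly linear level
#'     curve m(l) = l/7.}
#'   \item{`"null"`}{no disutility anywhere; TTO values are all 1 (up to
#'     noise) and DCE choices are driven only by the position intercept.}
#' }
#'
#' @param profile `"paper-like"`, `"linear"` or `"null"`.
#' @param overrides named list replacing individual fields (`beta_dim`,
#'   `beta_level`, `tto_intercept`, `dce_intercept`, `theta`, `alpha_sigma`,
#'   `beta_sigma`, `round_grid`).
#' @return A list of class `"truth_profile"`.
#' @examples
#' truth <- make_truth("paper-like")
#' truth$beta_dim
#' @export
make_truth <- function(profile = c("paper-like", "linear", "null"),
                       overrides = list()) {
  profile <- match.arg(profile)
  beta_dim <- c(WE = 0.25, LO = 0.22, DA = 0.25, LE = 0.20,
                PA = 0.45, TI = 0.25, AN = 0.30, DE = 0.48)
  truth <- switch(profile,
    "paper-like" = list(
      beta_dim = beta_dim,
      beta_level = c(0, 0.15, 0.28, 0.40, 0.40, 0.55, 0.775, 1),
      tto_intercept = 0, dce_intercept = 0.15, theta = 0.8,
      alpha_sigma = 0.25, beta_sigma = 0.10),
    "linear" = list(
      beta_dim = beta_dim,
      beta_level = (0:7) / 7,
      tto_intercept = 0, dce_intercept = 0.15, theta = 0.8,
      alpha_sigma = 0.25, beta_sigma = 0.10),
    "null" = list(
      beta_dim = beta_dim * 0,
      beta_level = (0:7) / 7,
      tto_intercept = 0, dce_intercept = 0.15, theta = 0.8,
      alpha_sigma = 0.25, beta_sigma = 0))
  truth$round_grid <- NULL  # optional elicitation grid, e.g. 0.05; off by default
  truth$profile <- profile
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(truth))
    if (length(bad)) stop("unknown truth field(s): ", paste(bad, collapse = ", "))
    truth[names(overrides)] <- overrides
  }
  .validate_truth(truth)
  class(truth) <- "truth_profile"
  truth
}

.validate_truth <- function(truth) {
  stopifnot(length(truth$beta_dim) == 8, length(truth$beta_level) == 8)
  if (is.null(names(truth$beta_dim))) names(truth$beta_dim) <- DIM_CODES
  if (any(truth$beta_dim < 0)) stop("dimension disutilities must be nonnegative")
  if (truth$beta_level[1] != 0) stop("level-0 multiplier must be 0")
  if (any(truth$beta_level < 0)) stop("level multipliers must be nonnegative")
  if (truth$theta <= 0) stop("theta must be positive")
  if (truth$alpha_sigma < 0) stop("alpha_sigma must be nonnegative")
  # sigma must be nonnegative over every state reachable by the designs
  dmax <- truth$tto_intercept + sum(truth$beta_dim)  # worst state
  smin <- min(truth$alpha_sigma, truth$alpha_sigma + truth$beta_sigma * dmax)
  if (smin < 0) stop("sigma = alpha_sigma + beta_sigma * d negative over the design")
  invisible(truth)
}

#' @export
print.truth_profile <- function(x, ...) {
  cat("Truth profile '", x$profile, "'\n", sep = "")
  cat("  beta_dim:  ", paste0(names(x$beta_dim), "=", x$beta_dim, collapse = " "), "\n")
  cat("  level curve:", paste(signif(x$beta_level, 3), collapse = " "), "\n")
  cat(sprintf("  theta=%g  dce_intercept=%g  sigma=%g + %g*d\n",
              x$theta, x$dce_intercept, x$alpha_sigma, x$beta_sigma))
  invisible(x)
}

#' True disutility of states under a truth profile
#'
#' @param truth a [make_truth()] profile.
#' @param states states coercible to a state matrix (an `inqol_state`, a
#'   matrix, or a data frame with dimension columns).
#' @return Numeric vector of disutilities.
#' @export
truth_disutility <- function(truth, states) {
  m <- .state_matrix(states)
  mult <- matrix(truth$beta_level[m + 1L], nrow(m), 8)
  truth$tto_intercept + as.vector(mult %*% truth$beta_dim)
}

# balanced 50/50 deterministic block allocation (odd n: extra respondent in block 1)
.block_of <- function(n) ifelse(seq_len(n) <= ceiling(n / 2), 1L, 2L)

#' Simulate composite-TTO observations
#'
#' Each respondent values one block's 16 states. The latent disutility is
#' d(state) + e with e ~ Normal(0, sigma(state)^2); the reported value is
#' 1 - latent, clamped to 1 above, and recorded as -1 with `censored = TRUE`
#' whenever the latent value falls below the cTTO floor of -1.
#'
#' @param truth a [make_truth()] profile.
#' @param design the TTO `"valuation_design"` from [map_to_states()].
#' @param n_respondents number of respondents (study default 200).
#' @param seed integer seed for reproducibility.
#' @return Data frame with `respondent_id`, `state_id`, `value`, `censored`.
#' @examples
#' des <- map_to_states(build_orthogonal_array(), "TTO")
#' tto <- simulate_tto(make_truth(), des, n_respondents = 20, seed = 1)
#' @export
simulate_tto <- function(truth, design, n_respondents = 200, seed = NULL) {
  stopifnot(inherits(truth, "truth_profile"), n_respondents >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- truth_disutility(truth, design)
  sig <- truth$alpha_sigma + truth$beta_sigma * d
  if (any(sig < 0)) stop("sigma nonpositive for a design state")
  blocks <- .block_of(n_respondents)
  out <- vector("list", n_respondents)
  for (i in seq_len(n_respondents)) {
    rows <- which(design$block == blocks[i])
    latent <- d[rows] + stats::rnorm(length(rows), 0, sig[rows])
    value <- 1 - latent
    if (!is.null(truth$round_grid))
      value <- round(value / truth$round_grid) * truth$round_grid
    censored <- value < -1
    value <- pmin(pmax(value, -1), 1)
    out[[i]] <- data.frame(respondent_id = i, state_id = design$state_id[rows],
                           value = value, censored = censored)
  }
  do.call(rbind, out)
}

#' Simulate DCE choices
#'
#' Each respondent answers one block's 16 pairs; the probability of choosing
#' alternative A is `plogis((d(B) - d(A)) / theta + dce_intercept)`.
#'
#' @param truth a [make_truth()] profile.
#' @param pairs the `"dce_design"` from [build_dce_pairs()].
#' @param n_respondents number of respondents (study default 508).
#' @param seed integer seed.
#' @return Data frame with `respondent_id`, `pair_id`, `choice` (`"A"`/`"B"`).
#' @examples
#' prs <- build_dce_pairs(map_to_states(build_orthogonal_array(), "DCE"))
#' dce <- simulate_dce(make_truth(), prs, n_respondents = 20, seed = 1)
#' @export
simulate_dce <- function(truth, pairs, n_respondents = 508, seed = NULL) {
  stopifnot(inherits(truth, "truth_profile"), n_respondents >= 1)
  if (truth$theta <= 0) stop("theta must be positive")
  if (!is.null(seed)) set.seed(seed)
  da <- truth_disutility(truth, .alt_matrix(pairs, "A"))
  db <- truth_disutility(truth, .alt_matrix(pairs, "B"))
  p_a <- stats::plogis((db - da) / truth$theta + truth$dce_intercept)
  blocks <- .block_of(n_respondents)
  out <- vector("list", n_respondents)
  for (i in seq_len(n_respondents)) {
    rows <- which(pairs$block == blocks[i])
    choice <- ifelse(stats::runif(length(rows)) < p_a[rows], "A", "B")
    out[[i]] <- data.frame(respondent_id = i, pair_id = pairs$pair_id[rows],
                           choice = choice)
  }
  do.call(rbind, out)
}

#' Read/write observation tables and truth profiles
#'
#' CSV schemas: TTO observations as `respondent_id, state_id, value`
#' (censoring is implied by value -1 and re-derived on read); DCE
#' observations as `respondent_id, pair_id, choice`. Values are written with
#' 17 significant digits so the round trip is bit-exact. Truth profiles are
#' serialized as JSON.
#'
#' @param x the table or truth profile to write.
#' @param path file path.
#' @return The data read, or `path` invisibly for writers.
#' @name observation_io
NULL

#' @rdname observation_io
#' @export
write_tto_observations <- function(x, path) {
  stopifnot(all(c("respondent_id", "state_id", "value") %in% names(x)))
  out <- data.frame(respondent_id = x$respondent_id, state_id = x$state_id,
                    value = sprintf("%.17g", x$value))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname observation_io
#' @export
read_tto_observations <- function(path) {
  x <- utils::read.csv(path, colClasses = c("integer", "integer", "numeric"))
  if (!all(c("respondent_id", "state_id", "value") %in% names(x)))
    stop("malformed TTO observation file: ", path)
  if (any(x$value < -1 | x$value > 1)) stop("TTO values must lie in [-1, 1]")
  x$censored <- x$value <= -1
  x
}

#' @rdname observation_io
#' @export
write_dce_observations <- function(x, path) {
  stopifnot(all(c("respondent_id", "pair_id", "choice") %in% names(x)))
  utils::write.csv(x[, c("respondent_id", "pair_id", "choice")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname observation_io
#' @export
read_dce_observations <- function(path) {
  x <- utils::read.csv(path, colClasses = c("integer", "integer", "character"))
  if (!all(c("respondent_id", "pair_id", "choice") %in% names(x)))
    stop("malformed DCE observation file: ", path)
  if (!all(x$choice %in% c("A", "B"))) stop("choices must be 'A' or 'B'")
  x
}

#' @rdname observation_io
#' @export
write_truth_json <- function(x, path) {
  stopifnot(inherits(x, "truth_profile"))
  obj <- unclass(x)
  obj$beta_dim <- as.list(obj$beta_dim)  # keep dimension names in JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname observation_io
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  profile <- obj$profile
  obj$profile <- NULL
  obj$beta_dim <- unlist(obj$beta_dim)
  make_truth(profile, overrides = obj[!vapply(obj, is.null, TRUE)])
}
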