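# Tariff construction and scoring: a complete dimension x level disutility
# lookup derived from a fitted model. Levels the designs never show (level 6
# everywhere; more for single-arm scopes) are filled as the arithmetic
# midpoint of the nearest observed flanking levels, then any logical
# inconsistency (a logically worse level with a smaller disutility) is
# repaired by pool-adjacent-violators averaging, with every touched cell
# flagged.

#' Build a disutility tariff from a fitted model
#'
#' @param fit a converged [fit_value_model()] result.
#' @param repair apply weakly-monotone repair (pool-adjacent-violators via
#'   isotonic least squares) per dimension? Default `TRUE`.
#' @param apply_intercept should [score_responses()] add the fitted TTO
#'   intercept (if any) to every non-best state? Recorded in the tariff
#'   metadata.
#' @return Object of class `"inqol_tariff"`: `entries` (8 x 8 matrix,
#'   dimensions x levels 0-7), `provenance` (same shape, `"fitted"`,
#'   `"interpolated"` or `"monotonized"`), `intercept`, `apply_intercept`,
#'   `spec`.
#' @examples
#' des <- map_to_states(build_orthogonal_array(), "TTO")
#' tto <- simulate_tto(make_truth(), des, n_respondents = 50, seed = 3)
#' fit <- fit_value_model(model_spec("cale", "tto"), tto = tto,
#'                        tto_design = des, control = fit_control(restarts = 2))
#' tariff <- build_tariff(fit)
#' tariff$entries[, "6"]  # midpoint of levels 5 and 7
#' @export
build_tariff <- function(fit, repair = TRUE, apply_intercept = TRUE) {
  stopifnot(inherits(fit, "value_fit"))
  if (fit$convergence != 0) stop("refusing to build a tariff from a non-converged fit")
  spec <- fit$spec
  coefs <- fit$coefficients
  entries <- matrix(NA_real_, 8, 8, dimnames = list(DIM_CODES, 0:7))
  prov <- matrix(NA_character_, 8, 8, dimnames = list(DIM_CODES, 0:7))
  entries[, 1] <- 0
  prov[, 1] <- "fitted"
  zero <- matrix(0L, 1, 8, dimnames = list(NULL, DIM_CODES))
  d0 <- predict_disutility(spec, coefs, zero)
  lv <- observed_levels(.spec_arm(spec))
  for (i in seq_along(DIM_CODES)) {
    dim <- DIM_CODES[i]
    for (l in 1:7) {
      st <- zero
      st[1, dim] <- l
      ok <- .entry_known(spec, dim, l, lv)
      if (ok) {
        entries[i, l + 1] <- predict_disutility(spec, coefs, st) - d0
        prov[i, l + 1] <- "fitted"
      }
    }
    # fill unobserved levels as midpoints of nearest known flanking levels
    known <- which(!is.na(entries[i, ]))  # includes level 0
    for (l in setdiff(1:7, known - 1)) {
      lo <- max(known[known < l + 1])
      hi <- min(known[known > l + 1])
      entries[i, l + 1] <- (entries[i, lo] + entries[i, hi]) / 2
      prov[i, l + 1] <- "interpolated"
    }
  }
  if (repair) {
    for (i in seq_along(DIM_CODES)) {
      y <- entries[i, 2:8]
      yf <- stats::isoreg(1:7, y)$yf  # PAVA: isotonic least squares
      changed <- abs(yf - y) > 1e-12
      entries[i, 2:8] <- yf
      prov[i, 2:8][changed] <- "monotonized"
    }
  }
  alpha <- if (spec$tto_intercept) unname(coefs["alpha_tto"]) else 0
  structure(list(entries = entries, provenance = prov, intercept = alpha,
                 apply_intercept = isTRUE(apply_intercept), spec = spec,
                 repair = isTRUE(repair)),
            class = "inqol_tariff")
}

# is the (dimension, level) entry determined by fitted coefficients?
.entry_known <- function(spec, dim, l, lv) {
  set <- if (dim %in% SYMPTOM_DIMS) lv$SYMPTOM else lv$IMPACT
  switch(spec$family,
    linear = TRUE,                      # linear in level: defined everywhere
    main = l %in% set,
    cale = l %in% c(0L, 7L, .free_levels(spec)$UNION),
    calesep = {
      fl <- .free_levels(spec)
      grp <- if (dim %in% SYMPTOM_DIMS) fl$SYMPTOM else fl$IMPACT
      l %in% c(0L, 7L, grp)
    })
}

#' @export
print.inqol_tariff <- function(x, ...) {
  cat("INQoL-8D disutility tariff (", toupper(x$spec$family), " ",
      x$spec$scope, " fit)\n", sep = "")
  print(round(x$entries, 4))
  n_int <- sum(x$provenance == "interpolated")
  n_mon <- sum(x$provenance == "monotonized")
  cat(n_int, "interpolated and", n_mon, "monotonized entries;",
      "intercept", signif(x$intercept, 4),
      if (x$apply_intercept) "(applied in scoring)\n" else "(not applied)\n")
  invisible(x)
}

#' Score INQoL responses to utilities
#'
#' Utility = 1 - (intercept for non-best states, if applied) - sum of the
#' tariff entries of each dimension's level. The best (all-zero) state
#' scores exactly 1. Utilities below -1 are reported as computed, not
#' floored.
#'
#' @param tariff an [build_tariff()] result (or one read back with
#'   [import_tariff()]).
#' @param responses states coercible to a state matrix: a data frame with
#'   one column per dimension code (`FA` accepted for `TI`), a matrix, or a
#'   single `inqol_state`. An optional `respondent_id` column is carried
#'   through.
#' @return Data frame with `respondent_id`, `utility`, and one `d_<dim>`
#'   disutility-decomposition column per dimension.
#' @examples
#' \dontrun{
#' score_responses(tariff, data.frame(WE = 1, LO = 0, DA = 0, LE = 0,
#'                                    PA = 7, TI = 0, AN = 0, DE = 0))
#' }
#' @export
score_responses <- function(tariff, responses) {
  stopifnot(inherits(tariff, "inqol_tariff"))
  ids <- if (is.data.frame(responses) && "respondent_id" %in% names(responses))
    responses$respondent_id else NULL
  m <- .state_matrix(responses)
  dd <- matrix(0, nrow(m), 8, dimnames = list(NULL, paste0("d_", DIM_CODES)))
  for (j in 1:8) dd[, j] <- tariff$entries[j, m[, j] + 1]
  total <- rowSums(dd)
  nonbest <- rowSums(m) > 0
  if (tariff$apply_intercept) total <- total + tariff$intercept * nonbest
  data.frame(respondent_id = if (is.null(ids)) seq_len(nrow(m)) else ids,
             utility = 1 - total, dd)
}

#' Write / read a tariff as CSV
#'
#' One row per dimension: `dimension`, `group`, entry columns `level_0` ..
#' `level_7`, provenance columns `prov_0` .. `prov_7`, and the scoring
#' metadata (`intercept`, `apply_intercept`, `family`, `scope`) repeated on
#' every row. The round trip is value-exact and preserves provenance.
#' Import validates the schema and the tariff invariants (all dimensions
#' present, level-0 entries 0).
#'
#' @param tariff an `"inqol_tariff"`.
#' @param path CSV file path.
#' @return `import_tariff` returns the tariff; `export_tariff` returns
#'   `path` invisibly.
#' @export
export_tariff <- function(tariff, path) {
  stopifnot(inherits(tariff, "inqol_tariff"))
  ent <- matrix(sprintf("%.17g", tariff$entries), 8, 8,
                dimnames = list(NULL, paste0("level_", 0:7)))
  prv <- tariff$provenance
  colnames(prv) <- paste0("prov_", 0:7)
  out <- data.frame(
    dimension = DIM_CODES,
    group = ifelse(DIM_CODES %in% SYMPTOM_DIMS, "SYMPTOM", "IMPACT"),
    ent, prv,
    intercept = sprintf("%.17g", tariff$intercept),
    apply_intercept = tariff$apply_intercept,
    family = tariff$spec$family, scope = tariff$spec$scope)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_tariff
#' @export
import_tariff <- function(path) {
  x <- utils::read.csv(path, colClasses = "character")
  need <- c("dimension", "group", paste0("level_", 0:7), paste0("prov_", 0:7),
            "intercept", "apply_intercept", "family", "scope")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("malformed tariff file, missing column(s): ",
         paste(miss, collapse = ", "))
  if (!setequal(x$dimension, DIM_CODES))
    stop("tariff file must contain exactly the 8 dimensions")
  x <- x[match(DIM_CODES, x$dimension), ]
  entries <- as.matrix(x[, paste0("level_", 0:7)])
  storage.mode(entries) <- "double"
  dimnames(entries) <- list(DIM_CODES, 0:7)
  if (anyNA(entries)) stop("non-numeric tariff entry")
  if (any(entries[, 1] != 0))
    stop("level-0 entries must be 0 (row ",
         DIM_CODES[which(entries[, 1] != 0)[1]], ")")
  prov <- as.matrix(x[, paste0("prov_", 0:7)])
  dimnames(prov) <- list(DIM_CODES, 0:7)
  if (!all(prov %in% c("fitted", "interpolated", "monotonized")))
    stop("invalid provenance flag in tariff file")
  spec <- model_spec(x$family[1], x$scope[1],
                     tto_intercept = as.numeric(x$intercept[1]) != 0)
  structure(list(entries = entries, provenance = prov,
                 intercept = as.numeric(x$intercept[1]),
                 apply_intercept = as.logical(x$apply_intercept[1]),
                 spec = spec, repair = NA),
            class = "inqol_tariff")
}
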