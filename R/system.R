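# The reduced INQoL descriptive system: 8 dimensions on ordinal levels 0-7.

DIM_CODES <- c("WE", "LO", "DA", "LE", "PA", "TI", "AN", "DE")
SYMPTOM_DIMS <- c("WE", "LO", "PA", "TI")
IMPACT_DIMS <- c("DA", "LE", "AN", "DE")

# Default display labels. The symptom dimensions (WE, LO, PA, TI) are preceded
# in the instrument by a yes/no presence question; answering "No" maps to
# level 0, so level 0 is the reference for both presentation formats. Labels
# are display metadata only and are configurable through inqol_dimensions().
.SYMPTOM_LABELS <- c(
  "0" = "None (symptom not present)",
  "1" = "very little", "2" = "some", "3" = "a fair amount",
  "4" = "a moderate amount", "5" = "a considerable amount",
  "6" = "a very considerable amount", "7" = "an extreme amount")
.IMPACT_LABELS <- c(
  "0" = "Not at all",
  "1" = "Slightly", "2" = "Somewhat", "3" = "A fair amount",
  "4" = "Moderately", "5" = "Considerably",
  "6" = "Very considerably", "7" = "Extremely")

.DIM_NAMES <- c(
  WE = "Muscle weakness", LO = "Muscle locking", DA = "Daily activities",
  LE = "Leisure activities", PA = "Pain", TI = "Tiredness/fatigue",
  AN = "Anxiety", DE = "Depression")

#' The INQoL-8D descriptive system
#'
#' Returns the definition of the reduced 8-dimension INQoL descriptive system
#' used for valuation: dimension codes, the two presentation groups, and
#' per-level display labels. Four symptom dimensions (weakness `WE`, muscle
#' locking `LO`, pain `PA`, tiredness `TI`) are preceded in the instrument by
#' a yes/no presence question ("No" maps to level 0); four impact dimensions
#' (daily activities `DA`, leisure `LE`, anxiety `AN`, depression `DE`) are
#' asked directly with level 0 meaning "Not at all". `FA` (fatigue) is
#' accepted everywhere as an alias for `TI`.
#'
#' @param labels optional named list overriding the per-dimension level label
#'   vectors (each a character vector named `"0"` to `"7"`).
#' @return A data frame with one row per dimension (columns `code`, `name`,
#'   `group`) and a `"labels"` attribute holding the level-label vectors.
#' @examples
#' inqol_dimensions()
#' @export
inqol_dimensions <- function(labels = NULL) {
  d <- data.frame(
    code = DIM_CODES,
    name = unname(.DIM_NAMES[DIM_CODES]),
    group = ifelse(DIM_CODES %in% SYMPTOM_DIMS, "SYMPTOM", "IMPACT"),
    stringsAsFactors = FALSE)
  lab <- lapply(d$code, function(cd) {
    if (cd %in% SYMPTOM_DIMS) .SYMPTOM_LABELS else .IMPACT_LABELS
  })
  names(lab) <- d$code
  if (!is.null(labels)) {
    stopifnot(is.list(labels))
    for (cd in names(labels)) {
      cd2 <- .canon_dim(cd)
      v <- labels[[cd]]
      if (!is.character(v) || !setequal(names(v), as.character(0:7)))
        stop("label override for ", cd, " must name all levels 0-7")
      lab[[cd2]] <- v[as.character(0:7)]
    }
  }
  attr(d, "labels") <- lab
  d
}

.canon_dim <- function(code) {
  code <- toupper(code)
  code[code == "FA"] <- "TI"  # the instrument calls tiredness "fatigue" too
  bad <- setdiff(code, DIM_CODES)
  if (length(bad)) stop("unknown dimension code(s): ", paste(bad, collapse = ", "))
  code
}

#' Construct and validate an INQoL-8D health state
#'
#' A health state is an ordered vector of 8 integer levels in 0-7, one per
#' dimension in the canonical order `WE, LO, DA, LE, PA, TI, AN, DE`. The
#' all-zero state is full health (utility 1 by construction).
#'
#' @param levels numeric vector of length 8 with integer values in 0-7. May
#'   carry dimension-code names in any order (`FA` accepted for `TI`);
#'   unnamed vectors are taken in canonical order.
#' @return A named integer vector of class `"inqol_state"`.
#' @examples
#' make_state(c(1, 2, 0, 1, 4, 7, 0, 3))
#' make_state(c(PA = 7, WE = 0, LO = 0, DA = 0, LE = 0, FA = 0, AN = 0, DE = 0))
#' @export
make_state <- function(levels) {
  if (length(levels) != 8L)
    stop("a health state needs exactly 8 levels, got ", length(levels))
  if (!is.null(names(levels))) {
    nm <- .canon_dim(names(levels))
    if (anyDuplicated(nm)) stop("duplicated dimension names in state")
    if (!setequal(nm, DIM_CODES)) stop("state names must cover all 8 dimensions")
    levels <- levels[match(DIM_CODES, nm)]
  }
  if (!is.numeric(levels) || any(is.na(levels)) || any(levels != round(levels))) {
    bad <- which(!is.finite(levels) | levels != round(levels))[1]
    stop("non-integer level for dimension ", DIM_CODES[bad])
  }
  if (any(levels < 0 | levels > 7)) {
    bad <- which(levels < 0 | levels > 7)[1]
    stop("level out of range [0, 7] for dimension ", DIM_CODES[bad],
         " (got ", levels[bad], ")")
  }
  out <- as.integer(levels)
  names(out) <- DIM_CODES
  class(out) <- "inqol_state"
  out
}

#' @export
print.inqol_state <- function(x, ...) {
  cat("INQoL-8D state:", paste0(names(x), "=", unclass(x), collapse = " "), "\n")
  invisible(x)
}

# Coerce states to an n x 8 integer matrix with canonical column order.
# Accepts an inqol_state, a plain length-8 vector, a matrix, or a data frame
# with dimension-code columns (extra columns ignored).
.state_matrix <- function(x) {
  if (inherits(x, "inqol_state")) x <- matrix(unclass(x), 1, 8,
                                              dimnames = list(NULL, DIM_CODES))
  if (is.data.frame(x)) {
    nm <- toupper(names(x))
    nm[nm == "FA"] <- "TI"
    names(x) <- nm
    if (!all(DIM_CODES %in% nm))
      stop("missing dimension column(s): ",
           paste(setdiff(DIM_CODES, nm), collapse = ", "))
    x <- as.matrix(x[, DIM_CODES, drop = FALSE])
  }
  if (is.null(dim(x))) {
    if (length(x) != 8L) stop("expected 8 levels per state")
    x <- matrix(x, 1, 8, dimnames = list(NULL, DIM_CODES))
  }
  if (ncol(x) != 8L) stop("state matrix must have 8 columns")
  if (!is.null(colnames(x))) {
    cn <- .canon_dim(colnames(x))
    x <- x[, match(DIM_CODES, cn), drop = FALSE]
  }
  if (any(x < 0 | x > 7) || any(x != round(x)))
    stop("state levels must be integers in [0, 7]")
  storage.mode(x) <- "integer"
  colnames(x) <- DIM_CODES
  x
}

#' Levels observed under each study arm
#'
#' The valuation designs restrict each dimension to four of its eight levels.
#' The cTTO states use levels 1, 3, 5, 7 for the symptom dimensions and
#' 0, 3, 5, 7 for the impact dimensions; the DCE states use 1, 2, 4, 7 and
#' 0, 1, 4, 7. `HYBRID` returns the per-group unions. Level 6 is observed in
#' no arm, which is why tariffs interpolate it.
#'
#' @param arm one of `"TTO"`, `"DCE"`, `"HYBRID"`.
#' @return Named list with integer vectors `SYMPTOM` and `IMPACT`.
#' @examples
#' observed_levels("TTO")
#' observed_levels("HYBRID")
#' @export
observed_levels <- function(arm = c("TTO", "DCE", "HYBRID")) {
  arm <- match.arg(toupper(arm), c("TTO", "DCE", "HYBRID"))
  sets <- list(
    TTO = list(SYMPTOM = c(1L, 3L, 5L, 7L), IMPACT = c(0L, 3L, 5L, 7L)),
    DCE = list(SYMPTOM = c(1L, 2L, 4L, 7L), IMPACT = c(0L, 1L, 4L, 7L)))
  if (arm == "HYBRID")
    return(list(
      SYMPTOM = sort(union(sets$TTO$SYMPTOM, sets$DCE$SYMPTOM)),
      IMPACT = sort(union(sets$TTO$IMPACT, sets$DCE$IMPACT))))
  sets[[arm]]
}

#' Count the primary parameters of a full main-effects model
#'
#' One parameter per observed imperfect (dimension, level) combination; level
#' 0 (absence / "Not at all") is the reference and carries none. This is 28
#' for each arm modelled alone and 44 for a cTTO+DCE hybrid.
#'
#' @inheritParams observed_levels
#' @return Integer parameter count.
#' @examples
#' count_main_effect_params("TTO")    # 28
#' count_main_effect_params("HYBRID") # 44
#' @export
count_main_effect_params <- function(arm = c("TTO", "DCE", "HYBRID")) {
  lv <- observed_levels(arm)
  4L * length(setdiff(lv$SYMPTOM, 0L)) + 4L * length(setdiff(lv$IMPACT, 0L))
}

#' Serialize the descriptive system to JSON
#'
#' Writes dimension codes, groups, names and level labels as JSON, the
#' single source of truth other tools can consume.
#'
#' @param path file to write.
#' @param system output of [inqol_dimensions()].
#' @return `path`, invisibly.
#' @export
export_system <- function(path, system = inqol_dimensions()) {
  obj <- list(
    dimensions = system,
    labels = attr(system, "labels"),
    groups = list(SYMPTOM = SYMPTOM_DIMS, IMPACT = IMPACT_DIMS))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
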