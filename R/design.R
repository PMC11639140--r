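# Orthogonal valuation designs: a 32-run OA on 4 symbols, mapped to cTTO
# states and Street-shifted DCE pairs, in two blocks of 16.

#' Build (or load) the 32-run orthogonal array
#'
#' Returns a strength-2 orthogonal array OA(32, 4^8, 2): 32 runs by 8 factors
#' on symbols 0-3 such that every pair of columns contains each of the 16
#' symbol combinations exactly twice. The bundled array is constructed
#' deterministically from a partial spread of 8 pairwise-disjoint 2-dim
#' subspaces of GF(2)^5 (Rao--Hamming construction); any user-supplied array
#' is accepted from a whitespace-delimited text file. Verification is
#' mandatory in both cases.
#'
#' @param source `"builtin"` or a path to a 32 x 8 matrix of symbols 0-3.
#' @return A 32 x 8 integer matrix of class `"orthogonal_array"`.
#' @examples
#' oa <- build_orthogonal_array()
#' verify_orthogonal_array(oa)
#' @seealso [verify_orthogonal_array()], [map_to_states()]
#' @export
build_orthogonal_array <- function(source = "builtin") {
  if (identical(source, "builtin")) {
    oa <- .builtin_oa()
  } else {
    oa <- as.matrix(utils::read.table(source, header = FALSE))
    dimnames(oa) <- NULL
  }
  if (!is.numeric(oa) || !identical(dim(oa), c(32L, 8L)))
    stop("orthogonal array must be a 32 x 8 matrix, got ",
         paste(dim(oa), collapse = " x "))
  if (!all(oa %in% 0:3)) stop("orthogonal array symbols must be in {0, 1, 2, 3}")
  storage.mode(oa) <- "integer"
  if (!verify_orthogonal_array(oa))
    stop("array fails strength-2 orthogonality verification")
  structure(oa, class = "orthogonal_array")
}

# Deterministic OA(32, 4^8, 2). Each 4-level factor j is defined by a line
# {u_j, v_j, u_j XOR v_j} of nonzero vectors of GF(2)^5; pairwise-disjoint
# lines give 16 linearly independent parity pairs for every two factors,
# hence strength 2. The 8 disjoint lines are found by backtracking in
# lexicographic order, so the result is reproducible.
.builtin_oa <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    lines <- NULL
    for (u in 1:30) for (v in (u + 1):31) {
      w <- bitwXor(u, v)
      if (w > v) lines <- rbind(lines, c(u, v, w))
    }
    used <- rep(FALSE, 31)
    sel <- integer(0)
    rec <- function(start, depth) {
      if (depth == 0L) return(TRUE)
      if (start > nrow(lines)) return(FALSE)
      for (i in start:nrow(lines)) {
        tri <- lines[i, ]
        if (!any(used[tri])) {
          used[tri] <<- TRUE
          sel <<- c(sel, i)
          if (rec(i + 1L, depth - 1L)) return(TRUE)
          used[tri] <<- FALSE
          sel <<- sel[-length(sel)]
        }
      }
      FALSE
    }
    if (!rec(1L, 8L)) stop("internal error: no partial spread found") # unreachable
    spread <- lines[sel, , drop = FALSE]
    parity <- vapply(0:31, function(x) sum(bitwAnd(x, 2^(0:4)) > 0) %% 2, 0)
    oa <- matrix(0L, 32, 8)
    for (j in 1:8) for (x in 0:31)
      oa[x + 1, j] <- 2L * as.integer(parity[bitwAnd(x, spread[j, 1]) + 1]) +
        as.integer(parity[bitwAnd(x, spread[j, 2]) + 1])
    cache <<- oa
    oa
  }
})

#' Verify strength-2 orthogonality by exhaustive counting
#'
#' Checks that for every one of the 28 column pairs each of the 16 symbol
#' combinations occurs exactly 32/16 = 2 times.
#'
#' @param oa a 32 x 8 matrix of symbols 0-3.
#' @return `TRUE`/`FALSE`; on failure the attribute `"failures"` lists the
#'   offending column pairs.
#' @export
verify_orthogonal_array <- function(oa) {
  if (!is.matrix(oa) || nrow(oa) != 32L || ncol(oa) != 8L || !all(oa %in% 0:3))
    return(structure(FALSE, failures = "wrong shape or symbols"))
  fails <- character(0)
  for (a in 1:7) for (b in (a + 1):8) {
    tab <- table(factor(oa[, a], 0:3), factor(oa[, b], 0:3))
    if (!all(tab == 2L)) fails <- c(fails, paste0("(", a, ",", b, ")"))
  }
  structure(length(fails) == 0L, failures = if (length(fails)) fails)
}

#' @export
print.orthogonal_array <- function(x, ...) {
  cat("OA(32, 4^8, 2): 32 runs x 8 factors, symbols 0-3\n")
  print(unclass(x)[1:4, ])
  cat("... (", nrow(x) - 4L, " more runs)\n", sep = "")
  invisible(x)
}

# pull one alternative's level matrix out of a dce_design
.alt_matrix <- function(pairs, alt) {
  m <- as.matrix(pairs[, paste0(alt, "_", DIM_CODES)])
  colnames(m) <- DIM_CODES
  .state_matrix(m)
}

# Symbol k (0-3) maps to the k-th smallest level of the group's arm level set.
.symbols_to_levels <- function(symbols, arm) {
  lv <- observed_levels(arm)
  out <- matrix(0L, nrow(symbols), 8, dimnames = list(NULL, DIM_CODES))
  for (j in seq_along(DIM_CODES)) {
    set <- if (DIM_CODES[j] %in% SYMPTOM_DIMS) lv$SYMPTOM else lv$IMPACT
    out[, j] <- set[symbols[, j] + 1L]
  }
  out
}

#' Map the orthogonal array to valuation states
#'
#' Converts the 32 symbol rows to health states under one arm's level
#' selection (symbol k = k-th smallest level of the group's set) and assigns
#' runs 1-16 to block 1 and 17-32 to block 2.
#'
#' @param oa an `"orthogonal_array"` (see [build_orthogonal_array()]).
#' @param arm `"TTO"` or `"DCE"`.
#' @return A data frame of class `"valuation_design"` with columns
#'   `state_id`, `block` and one level column per dimension; the generating
#'   symbols are kept in the `"symbols"` attribute.
#' @examples
#' tto <- map_to_states(build_orthogonal_array(), "TTO")
#' head(tto)
#' @export
map_to_states <- function(oa, arm = c("TTO", "DCE")) {
  arm <- match.arg(toupper(arm), c("TTO", "DCE"))
  if (!inherits(oa, "orthogonal_array"))
    oa <- build_orthogonal_array(if (is.character(oa)) oa else stop(
      "oa must be an orthogonal_array or a path"))
  lev <- .symbols_to_levels(unclass(oa), arm)
  out <- data.frame(state_id = 1:32, block = assign_blocks(1:32), lev)
  attr(out, "symbols") <- unclass(oa)
  attr(out, "arm") <- arm
  class(out) <- c("valuation_design", "data.frame")
  out
}

#' Build the Street-shifted DCE choice pairs
#'
#' For each run, alternative A is the DCE-mapped state and alternative B is
#' obtained by incrementing every symbol by 1 modulo 4 before level mapping
#' (so level 1 in A becomes level 2 in B, and the top symbol wraps to the
#' lowest level). A and B therefore differ in all eight dimensions.
#'
#' @param states a `"valuation_design"` built with `arm = "DCE"` (must carry
#'   symbol provenance), or an `"orthogonal_array"`.
#' @return Data frame of class `"dce_design"` with `pair_id`, `block`,
#'   `A_<dim>` and `B_<dim>` level columns.
#' @examples
#' pairs <- build_dce_pairs(map_to_states(build_orthogonal_array(), "DCE"))
#' @export
build_dce_pairs <- function(states) {
  if (inherits(states, "orthogonal_array"))
    states <- map_to_states(states, "DCE")
  symbols <- attr(states, "symbols")
  if (is.null(symbols))
    stop("states must carry symbol provenance (build them with map_to_states)")
  if (!identical(attr(states, "arm"), "DCE"))
    stop("DCE pairs must be built from the DCE-mapped states")
  a <- .symbols_to_levels(symbols, "DCE")
  b <- .symbols_to_levels((symbols + 1L) %% 4L, "DCE")
  colnames(a) <- paste0("A_", DIM_CODES)
  colnames(b) <- paste0("B_", DIM_CODES)
  out <- data.frame(pair_id = 1:32, block = assign_blocks(1:32), a, b)
  attr(out, "symbols_a") <- symbols
  attr(out, "symbols_b") <- (symbols + 1L) %% 4L
  class(out) <- c("dce_design", "data.frame")
  out
}

#' Assign the two administration blocks
#'
#' Items 1-16 form block 1 and items 17-32 block 2; each respondent completes
#' one block of 16 states (cTTO) or 16 pairs (DCE).
#'
#' @param ids integer vector of exactly 32 item ids (values 1-32).
#' @return Integer vector of block labels (1 or 2) aligned with `ids`.
#' @examples
#' table(assign_blocks(1:32))
#' @export
assign_blocks <- function(ids) {
  if (length(ids) != 32L || !all(sort(ids) == 1:32))
    stop("expected exactly the 32 item ids 1..32")
  ifelse(ids <= 16L, 1L, 2L)
}

#' Export the full design as CSV
#'
#' One row per run with the OA symbols, the TTO state levels, the DCE A/B
#' levels and the block assignment.
#'
#' @param oa an `"orthogonal_array"`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
export_design <- function(oa, path) {
  if (!inherits(oa, "orthogonal_array")) stop("oa must be an orthogonal_array")
  tto <- .symbols_to_levels(unclass(oa), "TTO")
  dce <- build_dce_pairs(map_to_states(oa, "DCE"))
  sym <- unclass(oa)
  colnames(sym) <- paste0("s", 1:8)
  colnames(tto) <- paste0("tto_", DIM_CODES)
  out <- data.frame(run = 1:32, block = assign_blocks(1:32), sym, tto,
                    dce[, c(paste0("A_", DIM_CODES), paste0("B_", DIM_CODES))])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
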