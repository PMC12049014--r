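# Exact global alignment under 2-piece affine gap penalties.
#
# A gap of length g costs min(gap_open + g*gap_extend,
# gap_open2 + g*gap_extend2): two affine pieces approximating a concave gap
# cost, so long gaps (common in SMRT reads) are charged at the shallower
# second slope. Five matrices H/E/F/E2/F2 are filled either in row-column
# order (the SWG-style reference) or in diagonal-antidiagonal order
# (r = i + j, t = i), where all cells of one anti-diagonal are independent
# and updated in bulk from diagonals r-1 and r-2. H's maximization includes
# the second-piece matrices; the 3-term variant is available via
# `strict_eq1` for comparison, but it cannot realize the stated 2-piece gap
# cost.

#' Scoring scheme for 2-piece affine-gap alignment
#'
#' Defaults are the conventional PacBio-style 2-piece parameters:
#' match 2, mismatch -4, first piece (open 4, extend 2), second piece
#' (open 24, extend 1). Any residue pair involving `N` scores as a mismatch.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open,gap_extend First affine piece (positive penalties).
#' @param gap_open2,gap_extend2 Second affine piece (positive penalties).
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -4L, gap_open = 4L,
                           gap_extend = 2L, gap_open2 = 24L,
                           gap_extend2 = 1L) {
  s <- lapply(list(match = match, mismatch = mismatch, gap_open = gap_open,
                   gap_extend = gap_extend, gap_open2 = gap_open2,
                   gap_extend2 = gap_extend2), as.integer)
  if (s$match <= 0 || s$mismatch >= 0) stop("need match > 0 > mismatch")
  if (s$gap_extend <= 0 || s$gap_extend2 <= 0)
    stop("gap extension penalties must be > 0")
  if (s$gap_open < 0 || s$gap_open2 < 0)
    stop("gap open penalties must be >= 0")
  structure(s, class = "scoring_scheme")
}

#' Cost of a gap under the 2-piece affine model
#'
#' `min(gap_open + g*gap_extend, gap_open2 + g*gap_extend2)`, vectorized
#' over `length`.
#'
#' @param length Gap length(s), each >= 1.
#' @param s A [scoring_scheme()].
#' @return Integer penalty (positive).
#' @export
gap_cost <- function(length, s = scoring_scheme()) {
  if (any(length < 1)) stop("gap length must be >= 1")
  pmin(s$gap_open + length * s$gap_extend,
       s$gap_open2 + length * s$gap_extend2)
}

#' Shift a lane vector by one slot
#'
#' `result[1] = fill`, `result[i] = values[i-1]`: the abstract form of the
#' per-diagonal SIMD byte shift used by the anti-diagonal layout. Boundary
#' slots are filled with an explicit sentinel rather than 0, preserving
#' exact global-alignment semantics.
#'
#' @param values A vector.
#' @param fill Fill value for the vacated first slot.
#' @return A vector of the same length.
#' @export
lane_shift <- function(values, fill) {
  n <- length(values)
  if (n == 0) return(values)
  c(fill, values[-n])
}

as_alignment_result <- function(raw, target, query) {
  cigar <- data.frame(length = raw$cigar_len, op = raw$cigar_op,
                      stringsAsFactors = FALSE)
  structure(list(score = raw$score, cigar = cigar,
                 t_span = c(0L, nchar(target)), q_span = c(0L, nchar(query))),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> score %d, CIGAR %s (target %d bp, query %d bp)\n",
              x$score, cigar_string(x$cigar), x$t_span[2], x$q_span[2]))
  invisible(x)
}

#' Global alignment, row-column fill order
#'
#' The reference implementation (Smith-Waterman-Gotoh role): fills H, E, F,
#' E2, F2 row by row with boundaries `H(0,0) = 0`,
#' `H(i,0) = -gap_cost(i)`, `H(0,j) = -gap_cost(j)` and undefined gap cells
#' at a `neg_inf` sentinel. Traceback prefers M over D over I and gap
#' extension over re-opening, giving deterministic CIGARs.
#'
#' @param target,query Sequences over `{A,C,G,T,N}` (may be empty).
#' @param s A [scoring_scheme()].
#' @param strict_eq1 If `TRUE`, H's maximization omits the second-piece
#'   matrices (3-term variant, for comparison only).
#' @return A list of class `alignment_result` with `score`, `cigar`
#'   (data frame of `length`, `op` over M/I/D), `t_span`, `q_span`.
#' @export
align_rowcol <- function(target, query, s = scoring_scheme(),
                         strict_eq1 = FALSE) {
  as_alignment_result(.align_rowcol_cpp(target, query, s, strict_eq1),
                      target, query)
}

#' Global alignment, diagonal-antidiagonal fill order
#'
#' Identical scores and CIGARs to [align_rowcol()] for every input. Cells
#' are reindexed by `r = i + j`, `t = i`; each anti-diagonal is computed
#' from diagonals r-1 and r-2 using bulk elementwise operations on
#' contiguous per-diagonal buffers plus [lane_shift()] for the
#' `(r-1, t-1)` / `(r-2, t-1)` neighbours.
#'
#' @inheritParams align_rowcol
#' @return A list of class `alignment_result`.
#' @export
align_antidiag <- function(target, query, s = scoring_scheme(),
                           strict_eq1 = FALSE) {
  as_alignment_result(.align_antidiag_cpp(target, query, s, strict_eq1),
                      target, query)
}

#' DP matrices for inspection
#'
#' Returns the five filled matrices (rows `0..L_t`, columns `0..L_q`) for
#' small inputs, from either fill order. Used to check the layout identity
#' that the anti-diagonal cell `(r, t)` equals the row-column cell
#' `(i = t, j = r - t)`.
#'
#' @inheritParams align_rowcol
#' @param layout `"rowcol"` or `"antidiag"`.
#' @return A list of integer matrices `H`, `E`, `F`, `E2`, `F2` plus the
#'   `neg_inf` sentinel value.
#' @export
dp_matrices <- function(target, query, s = scoring_scheme(),
                        layout = c("rowcol", "antidiag"),
                        strict_eq1 = FALSE) {
  layout <- match.arg(layout)
  .dp_matrices_cpp(target, query, s, strict_eq1, layout == "antidiag")
}

#' Format a CIGAR data frame as a string
#'
#' @param cigar Data frame with `length` and `op` columns.
#' @return A CIGAR string, or `"*"` when empty.
#' @export
cigar_string <- function(cigar) {
  if (is.null(cigar) || nrow(cigar) == 0) return("*")
  paste0(cigar$length, cigar$op, collapse = "")
}

#' Parse a CIGAR string into a data frame
#'
#' @param cigar A CIGAR string (`"*"` gives an empty data frame).
#' @return Data frame with `length` and `op`.
#' @export
parse_cigar <- function(cigar) {
  if (identical(cigar, "*") || !nzchar(cigar))
    return(data.frame(length = integer(0), op = character(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  data.frame(length = lens, op = ops, stringsAsFactors = FALSE)
}

cigar_query_length <- function(cigar) {
  sum(cigar$length[cigar$op %in% c("M", "I", "S", "=", "X")])
}

cigar_target_length <- function(cigar) {
  sum(cigar$length[cigar$op %in% c("M", "D", "=", "X")])
}

# Merge adjacent runs with the same op (after concatenating piece CIGARs).
merge_cigar_runs <- function(cigar) {
  if (nrow(cigar) <= 1) return(cigar)
  keep <- cigar$length > 0
  cigar <- cigar[keep, , drop = FALSE]
  if (nrow(cigar) <= 1) return(cigar)
  grp <- cumsum(c(TRUE, cigar$op[-1] != cigar$op[-nrow(cigar)]))
  data.frame(length = as.integer(tapply(cigar$length, grp, sum)),
             op = cigar$op[!duplicated(grp)], stringsAsFactors = FALSE)
}

#' Re-score an alignment path
#'
#' Sums the residue scores over M columns and subtracts [gap_cost()] for
#' each maximal run of I and of D. Validates that the CIGAR consumes
#' exactly both sequences. Serves as an internal consistency oracle for the
#' DP tracebacks.
#'
#' @param cigar Data frame with `length` and `op` (M/I/D), or a CIGAR
#'   string.
#' @param target,query The aligned sequences.
#' @param s A [scoring_scheme()].
#' @return Integer score.
#' @export
score_cigar <- function(cigar, target, query, s = scoring_scheme()) {
  if (is.character(cigar)) cigar <- parse_cigar(cigar)
  if (cigar_query_length(cigar) != nchar(query) ||
      cigar_target_length(cigar) != nchar(target))
    stop("CIGAR does not consume exactly both sequences")
  cigar <- merge_cigar_runs(cigar)
  tc <- strsplit(target, "", fixed = TRUE)[[1]]
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  ti <- 0L; qi <- 0L; score <- 0L
  for (w in seq_len(nrow(cigar))) {
    len <- cigar$length[w]
    op <- cigar$op[w]
    if (op == "M") {
      a <- tc[ti + seq_len(len)]; b <- qc[qi + seq_len(len)]
      eq <- a == b & a != "N"
      score <- score + sum(ifelse(eq, s$match, s$mismatch))
      ti <- ti + len; qi <- qi + len
    } else if (op == "D") {
      score <- score - gap_cost(len, s)
      ti <- ti + len
    } else if (op == "I") {
      score <- score - gap_cost(len, s)
      qi <- qi + len
    } else stop("unsupported CIGAR op: ", op)
  }
  as.integer(score)
}
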