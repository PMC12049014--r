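# Per-read mapping: exact-k-mer anchors inside each candidate region,
# collinear chaining over a DAG, piecewise base-level alignment of the
# inter-anchor gaps, best-hit selection and SAM emission.

#' Find exact shared k-mer anchors
#'
#' All (read_pos, ref_pos) pairs where the region and the read share an
#' identical, `N`-free k-mer, found via a hash of the region's k-mers and
#' sorted by (read_pos, ref_pos).
#'
#' @param region Candidate region sequence.
#' @param read Read sequence.
#' @param k Anchor k-mer length.
#' @return Data frame with 0-based `read_pos`, `ref_pos`.
#' @export
find_anchors <- function(region, read, k) {
  if (k < 1) stop("k must be >= 1")
  empty <- data.frame(read_pos = integer(0), ref_pos = integer(0))
  if (nchar(region) < k || nchar(read) < k) return(empty)
  rc <- kmer_codes(region, k, step = 1L)
  qc <- kmer_codes(read, k, step = 1L)
  rpos <- which(!is.na(rc)) - 1L
  rc <- rc[!is.na(rc)]
  qpos <- which(!is.na(qc)) - 1L
  qc <- qc[!is.na(qc)]
  if (length(rc) == 0 || length(qc) == 0) return(empty)
  ord <- order(rc, rpos, method = "radix")
  rc_s <- rc[ord]; rpos_s <- rpos[ord]
  lo <- findInterval(qc - 0.5, rc_s)
  hi <- findInterval(qc + 0.5, rc_s)
  n <- hi - lo
  keep <- n > 0L
  if (!any(keep)) return(empty)
  read_pos <- rep.int(qpos[keep], n[keep])
  ref_pos <- rpos_s[sequence(n[keep], from = lo[keep] + 1L)]
  out <- data.frame(read_pos = read_pos, ref_pos = ref_pos)
  out[order(out$read_pos, out$ref_pos), , drop = FALSE]
}

#' Chain anchors over a DAG
#'
#' One node per anchor (reward `k * match`) plus source/sink; an edge
#' u -> v exists iff v starts at least k after u on both sequences; its
#' cost is [gap_cost()] of the diagonal difference between u's end and v's
#' start (0 when collinear). The maximum-score source-to-sink path is found
#' by DP in read-position order; ties prefer more anchors, then the chain
#' starting leftmost on the reference.
#'
#' @param anchors Data frame from [find_anchors()] (sorted).
#' @param s A [scoring_scheme()].
#' @param k Anchor length used to build `anchors`.
#' @return A list of class `anchor_chain` with `anchors` (data frame) and
#'   `chain_score` (0 for an empty input).
#' @export
chain_anchors <- function(anchors, s = scoring_scheme(), k) {
  if (nrow(anchors) == 0)
    return(structure(list(anchors = anchors, chain_score = 0L, k = k),
                     class = "anchor_chain"))
  res <- .chain_anchors_cpp(anchors$read_pos, anchors$ref_pos, as.integer(k),
                            s$match, s$gap_open, s$gap_extend, s$gap_open2,
                            s$gap_extend2)
  structure(list(anchors = anchors[res$chain, , drop = FALSE],
                 chain_score = res$score, k = k),
            class = "anchor_chain")
}

# Align one inter-anchor (or flank) piece; empty sides short-circuit to
# pure gap runs with identical scores to the full DP.
align_piece <- function(target, query, s, dp_log = NULL) {
  lt <- nchar(target); lq <- nchar(query)
  if (lt == 0 && lq == 0)
    return(list(score = 0L,
                cigar = data.frame(length = integer(0), op = character(0))))
  if (lq == 0)
    return(list(score = -gap_cost(lt, s),
                cigar = data.frame(length = lt, op = "D")))
  if (lt == 0)
    return(list(score = -gap_cost(lq, s),
                cigar = data.frame(length = lq, op = "I")))
  res <- align_antidiag(target, query, s)
  if (!is.null(dp_log))
    dp_log$pairs[[length(dp_log$pairs) + 1L]] <-
      list(target = target, query = query, score = res$score)
  list(score = res$score, cigar = res$cigar)
}

#' Piecewise base-level alignment of a candidate region
#'
#' Chained anchors become exact M runs; every inter-anchor gap pair, plus
#' the head pair before the first anchor and the tail pair after the last,
#' is aligned globally with [align_antidiag()] and the CIGARs are
#' concatenated. Region flank beyond the read's reach is trimmed, not
#' penalized: leading/trailing D runs are removed, their gap cost is added
#' back, and the start coordinate adjusted (the region is a deliberate
#' superset of the read's true span). An empty chain falls back to a single
#' global alignment of the read against the whole region, trimmed the same
#' way.
#'
#' @param region Candidate region sequence.
#' @param read Read sequence (orientation matching the candidate strand).
#' @param chain An [chain_anchors()] result.
#' @param s A [scoring_scheme()].
#' @param dp_log Optional environment with a `pairs` list; every DP
#'   invocation appends its `(target, query, score)` triple, enabling
#'   exactness audits against [align_rowcol()].
#' @return A list of class `alignment_result`; `t_span` gives the aligned
#'   0-based half-open interval within `region`.
#' @export
align_candidate <- function(region, read, chain, s = scoring_scheme(),
                            dp_log = NULL) {
  k <- chain$k
  an <- chain$anchors
  pieces <- list()
  score <- 0L
  if (nrow(an) == 0) {
    p <- align_piece(region, read, s, dp_log)
    score <- p$score
    pieces[[1]] <- p$cigar
  } else {
    # head flank
    p <- align_piece(substr(region, 1L, an$ref_pos[1]),
                     substr(read, 1L, an$read_pos[1]), s, dp_log)
    score <- score + p$score
    pieces[[length(pieces) + 1L]] <- p$cigar
    for (w in seq_len(nrow(an))) {
      score <- score + k * s$match
      pieces[[length(pieces) + 1L]] <- data.frame(length = k, op = "M")
      t_from <- an$ref_pos[w] + k
      q_from <- an$read_pos[w] + k
      t_to <- if (w < nrow(an)) an$ref_pos[w + 1L] else nchar(region)
      q_to <- if (w < nrow(an)) an$read_pos[w + 1L] else nchar(read)
      if (t_from > t_to || q_from > q_to)
        stop("inconsistent chain: overlapping anchors")
      p <- align_piece(substr(region, t_from + 1L, t_to),
                       substr(read, q_from + 1L, q_to), s, dp_log)
      score <- score + p$score
      pieces[[length(pieces) + 1L]] <- p$cigar
    }
  }
  cigar <- merge_cigar_runs(do.call(rbind, pieces))
  # trim un-penalized region flanks (leading/trailing D runs)
  t_start <- 0L
  t_end <- nchar(region)
  if (nrow(cigar) > 0 && cigar$op[1] == "D") {
    t_start <- cigar$length[1]
    score <- score + gap_cost(cigar$length[1], s)
    cigar <- cigar[-1, , drop = FALSE]
  }
  if (nrow(cigar) > 0 && cigar$op[nrow(cigar)] == "D") {
    t_end <- t_end - cigar$length[nrow(cigar)]
    score <- score + gap_cost(cigar$length[nrow(cigar)], s)
    cigar <- cigar[-nrow(cigar), , drop = FALSE]
  }
  structure(list(score = as.integer(score), cigar = cigar,
                 t_span = c(t_start, t_end), q_span = c(0L, nchar(read))),
            class = "alignment_result")
}

# Map one oriented read sequence against one candidate region.
align_one_candidate <- function(reference_seq, cand, read_seq, k, s, dp_log) {
  region <- substr(reference_seq, cand$ref_start + 1L, cand$ref_end)
  anchors <- find_anchors(region, read_seq, k)
  chain <- chain_anchors(anchors, s, k)
  res <- align_candidate(region, read_seq, chain, s, dp_log)
  list(result = res, cand = cand,
       sam_pos = cand$ref_start + res$t_span[1] + 1L)
}

#' Map a read against an indexed reference
#'
#' Runs seed extraction, window-hit counting and candidate selection on
#' both the read and its reverse complement, aligns every candidate region
#' piecewise, and keeps the highest-scoring result (ties: `+` strand
#' first, then lowest reference start). MAPQ is the score gap to the
#' second-best candidate, capped at 60. Reads with no candidates on either
#' strand are reported unmapped.
#'
#' @param rht A [build_rht()] index of `reference`.
#' @param reference The [seq_record()] the index was built from.
#' @param read A [seq_record()].
#' @param params A [map_params()] object.
#' @param dp_log Optional DP audit environment (see [align_candidate()]).
#' @return A list of class `mapped_read`: `read_id`, `is_mapped`, `strand`,
#'   `sam_pos` (1-based), `mapq`, `score`, `cigar`, `seq_aligned` (read in
#'   aligned orientation), `region` (the winning candidate row).
#' @export
map_read <- function(rht, reference, read, params = map_params(),
                     dp_log = NULL) {
  s <- params$scoring
  k <- rht$params$k
  oriented <- list(`+` = read$seq, `-` = revcomp(read$seq))
  cands <- list()
  for (strand in names(oriented)) {
    sd <- extract_seed(seq_record(read$id, oriented[[strand]]), rht$params)
    hits <- count_window_hits(rht, sd)
    cc <- select_candidates(hits, params, rht, strand)
    if (nrow(cc) > 0)
      cands <- c(cands, lapply(seq_len(nrow(cc)), function(w) cc[w, ]))
  }
  if (length(cands) == 0)
    return(structure(list(read_id = read$id, is_mapped = FALSE,
                          strand = NA_character_, sam_pos = NA_integer_,
                          mapq = 0L, score = NA_integer_, cigar = NULL,
                          seq_aligned = read$seq, qual = read$qual,
                          region = NULL),
                     class = "mapped_read"))
  results <- lapply(cands, function(cand)
    align_one_candidate(reference$seq, cand, oriented[[cand$strand]], k, s,
                        dp_log))
  scores <- vapply(results, function(r) r$result$score, 0L)
  # best hit: score desc, '+' before '-', then lowest ref_start
  strand_rank <- vapply(results, function(r)
    if (r$cand$strand == "+") 0L else 1L, 0L)
  starts <- vapply(results, function(r) r$cand$ref_start, 0L)
  best <- order(-scores, strand_rank, starts)[1]
  second <- if (length(scores) > 1) max(scores[-best]) else -Inf
  mapq <- as.integer(min(60, max(0, scores[best] - second)))
  b <- results[[best]]
  qual <- read$qual
  if (b$cand$strand == "-" && !is.null(qual))
    qual <- paste(rev(strsplit(qual, "", fixed = TRUE)[[1]]), collapse = "")
  structure(list(read_id = read$id, is_mapped = TRUE,
                 strand = b$cand$strand, sam_pos = b$sam_pos, mapq = mapq,
                 score = b$result$score, cigar = b$result$cigar,
                 seq_aligned = oriented[[b$cand$strand]], qual = qual,
                 region = b$cand),
            class = "mapped_read")
}

#' @export
print.mapped_read <- function(x, ...) {
  if (x$is_mapped)
    cat(sprintf("<mapped_read> %s: %s strand, pos %d, mapq %d, score %d\n",
                x$read_id, x$strand, x$sam_pos, x$mapq, x$score))
  else cat(sprintf("<mapped_read> %s: unmapped\n", x$read_id))
  invisible(x)
}

#' Convert a mapped read to a SAM record
#'
#' @param mr A [map_read()] result.
#' @param ref_name Reference name for RNAME.
#' @param index Input read index (output sort key).
#' @return A [sam_record()].
#' @export
mapped_read_to_sam <- function(mr, ref_name, index = NA_integer_) {
  if (!mr$is_mapped)
    return(sam_record(mr$read_id, 4L, "*", 0L, 0L, "*", mr$seq_aligned,
                      qual = if (is.null(mr$qual)) "*" else mr$qual,
                      index = index))
  flag <- if (mr$strand == "-") 16L else 0L
  sam_record(mr$read_id, flag, ref_name, mr$sam_pos, mr$mapq,
             cigar_string(mr$cigar), mr$seq_aligned,
             qual = if (is.null(mr$qual)) "*" else mr$qual,
             tags = sprintf("AS:i:%d", mr$score), index = index)
}

#' Create a fresh DP audit log
#'
#' An environment collecting every `(target, query, score)` DP invocation
#' performed by the mapper, for exactness audits against the row-column
#' reference implementation.
#'
#' @return An environment with an empty `pairs` list.
#' @export
new_dp_log <- function() {
  e <- new.env(parent = emptyenv())
  e$pairs <- list()
  e
}
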