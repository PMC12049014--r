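# Synthetic references and SMRT-like noisy reads with ground truth, plus
# recall evaluation. The error channel emulates a PacBio CLR profile:
# insertion-dominated, ~15% total error by default.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulation configuration
#'
#' Default error rates (substitution 0.02, insertion 0.09, deletion 0.04;
#' ~15% total, insertion-dominated) emulate PacBio CLR chemistry. Read
#' lengths are drawn from a truncated normal clamped to
#' `[min_read_length, max_read_length]`; the upper default (2600 bp) keeps
#' a read inside one candidate region (window plus extensions) so the
#' single-mid-seed mapper can recover its full span.
#'
#' @param ref_length Reference length in bp.
#' @param n_reads Number of reads.
#' @param read_length_mean,read_length_sd Read length distribution (bp).
#' @param min_read_length,max_read_length Clamp bounds (bp).
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities.
#' @param rc_prob Probability a read is reverse-complemented.
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(ref_length = 100000L, n_reads = 200L,
                       read_length_mean = 2000L, read_length_sd = 400L,
                       min_read_length = 200L, max_read_length = 2600L,
                       sub_rate = 0.02, ins_rate = 0.09, del_rate = 0.04,
                       rc_prob = 0.5, seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates >= 1) || sum(rates) >= 1)
    stop("error rates must be in [0, 1) and sum to < 1")
  if (rc_prob < 0 || rc_prob > 1) stop("rc_prob must be in [0, 1]")
  if (ref_length < read_length_mean)
    stop("reference shorter than the mean read length")
  if (max_read_length > ref_length)
    stop("max_read_length exceeds the reference length")
  structure(list(ref_length = as.integer(ref_length),
                 n_reads = as.integer(n_reads),
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 min_read_length = as.integer(min_read_length),
                 max_read_length = as.integer(max_read_length),
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, rc_prob = rc_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a uniform random reference
#'
#' i.i.d. uniform bases over `{A,C,G,T}`; deterministic given the seed.
#'
#' @param length Reference length in bp (>= 1).
#' @param seed RNG seed.
#' @param id Record id.
#' @return A [seq_record()].
#' @export
simulate_reference <- function(length, seed = 1L, id = "ref") {
  if (length < 1) stop("length must be >= 1")
  seq <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), length,
                                      replace = TRUE), collapse = ""))
  seq_record(id, seq)
}

# Apply the per-base error channel to one sequence. Returns the noisy
# sequence and the number of error events.
apply_errors <- function(seq, sub_rate, ins_rate, del_rate) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  alphabet <- c("A", "C", "G", "T")
  op <- sample(c("M", "S", "I", "D"), n, replace = TRUE,
               prob = c(1 - sub_rate - ins_rate - del_rate, sub_rate,
                        ins_rate, del_rate))
  out <- bases
  is_sub <- op == "S"
  if (any(is_sub)) {
    # substitute with one of the three other bases
    shift <- sample(1:3, sum(is_sub), replace = TRUE)
    cur <- match(bases[is_sub], alphabet)
    out[is_sub] <- alphabet[(cur - 1 + shift) %% 4 + 1]
  }
  is_ins <- op == "I"
  if (any(is_ins))
    out[is_ins] <- paste0(sample(alphabet, sum(is_ins), replace = TRUE),
                          bases[is_ins])
  out[op == "D"] <- ""
  list(seq = paste(out, collapse = ""), n_errors = sum(op != "M"),
       n_sub = sum(is_sub), n_ins = sum(is_ins), n_del = sum(op == "D"))
}

#' Simulate noisy reads with ground truth
#'
#' Each read draws a length from the truncated normal, an origin uniformly
#' on the reference, copies the substring, applies the per-base error
#' channel (an insertion places a random base before the original one),
#' and is reverse-complemented with probability `rc_prob`. Qualities are
#' constant `I`. Deterministic given `cfg$seed`.
#'
#' @param ref A [seq_record()] reference.
#' @param cfg A [sim_config()].
#' @return A list with `reads` (list of [seq_record()]) and `truth`
#'   (data frame: `read_id`, `ref_start`, `ref_end` 0-based half-open,
#'   `strand`, `n_errors`, `n_sub`, `n_ins`, `n_del`, `orig_length`).
#' @export
simulate_reads <- function(ref, cfg) {
  L <- nchar(ref$seq)
  if (cfg$max_read_length > L) stop("reads longer than the reference")
  with_seed(cfg$seed, {
    reads <- vector("list", cfg$n_reads)
    truth <- vector("list", cfg$n_reads)
    for (w in seq_len(cfg$n_reads)) {
      rl <- round(rnorm(1, cfg$read_length_mean, cfg$read_length_sd))
      rl <- min(max(rl, cfg$min_read_length), cfg$max_read_length)
      start <- floor(runif(1, 0, L - rl + 1))
      orig <- substr(ref$seq, start + 1, start + rl)
      err <- apply_errors(orig, cfg$sub_rate, cfg$ins_rate, cfg$del_rate)
      strand <- if (runif(1) < cfg$rc_prob) "-" else "+"
      seq <- if (strand == "-") revcomp(err$seq) else err$seq
      id <- sprintf("read_%05d", w)
      reads[[w]] <- seq_record(id, seq, qual = strrep("I", nchar(seq)))
      truth[[w]] <- data.frame(read_id = id, ref_start = start,
                               ref_end = start + rl, strand = strand,
                               n_errors = err$n_errors, n_sub = err$n_sub,
                               n_ins = err$n_ins, n_del = err$n_del,
                               orig_length = rl, stringsAsFactors = FALSE)
    }
    list(reads = reads, truth = do.call(rbind, truth))
  })
}

#' Write / read a ground-truth table
#'
#' Tab-separated with a header line: `read_id`, `ref_start`, `ref_end`,
#' `strand`, `n_errors`.
#'
#' @param truth Data frame from [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  cols <- c("read_id", "ref_start", "ref_end", "strand", "n_errors")
  utils::write.table(truth[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Evaluate mapping recall and DP exactness
#'
#' Mapping recall: the percentage of reads whose leftmost mapped
#' coordinate lies within `tolerance` bp of the true origin with the
#' correct strand. DP-exactness recall: the percentage of recorded DP
#' invocations whose anti-diagonal score equals the row-column reference
#' score on the same pair (the validation role of an independent
#' Smith-Waterman-Gotoh implementation).
#'
#' @param mapped List of [map_read()] results.
#' @param truth Ground-truth data frame (see [write_truth()]).
#' @param tolerance Position tolerance in bp (default 1024 = `L_win/2`).
#' @param dp_log Optional DP audit environment from [new_dp_log()].
#' @param s Scoring scheme used by the pipeline (for the re-scoring).
#' @return A list of class `eval_report`: `n_reads`, `n_mapped`,
#'   `n_unmapped`, `n_correct`, `mapping_recall` (percent),
#'   `dp_invocations`, `dp_exact`, `dp_exactness_recall` (percent or `NA`).
#' @export
evaluate <- function(mapped, truth, tolerance = 1024L, dp_log = NULL,
                     s = scoring_scheme()) {
  ids <- vapply(mapped, `[[`, "", "read_id")
  mt <- match(ids, truth$read_id)
  if (anyNA(mt)) stop("mapped read ids missing from the truth table")
  is_mapped <- vapply(mapped, `[[`, TRUE, "is_mapped")
  pos <- vapply(mapped, function(m)
    if (m$is_mapped) m$sam_pos - 1 else NA_real_, 0)
  strand <- vapply(mapped, function(m)
    if (m$is_mapped) m$strand else NA_character_, "")
  ok <- is_mapped & abs(pos - truth$ref_start[mt]) <= tolerance &
    strand == truth$strand[mt]
  ok[is.na(ok)] <- FALSE
  dp_n <- NA_integer_; dp_exact <- NA_integer_; dp_recall <- NA_real_
  if (!is.null(dp_log)) {
    dp_n <- length(dp_log$pairs)
    dp_exact <- sum(vapply(dp_log$pairs, function(pr)
      align_rowcol(pr$target, pr$query, s)$score == pr$score, TRUE))
    dp_recall <- if (dp_n > 0) 100 * dp_exact / dp_n else 100
  }
  structure(list(n_reads = length(mapped), n_mapped = sum(is_mapped),
                 n_unmapped = sum(!is_mapped), n_correct = sum(ok),
                 mapping_recall = if (length(mapped)) 100 * mean(ok) else 0,
                 dp_invocations = dp_n, dp_exact = dp_exact,
                 dp_exactness_recall = dp_recall),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d reads: %d mapped (%d correct), recall %.2f%%\n",
              x$n_reads, x$n_mapped, x$n_correct, x$mapping_recall))
  if (!is.na(x$dp_invocations))
    cat(sprintf("  DP exactness: %d/%d invocations (%.2f%%)\n",
                x$dp_exact, x$dp_invocations, x$dp_exactness_recall))
  invisible(x)
}
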