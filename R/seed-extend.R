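# Seed generation and candidate-window selection.
#
# One seed per read: the middle min(L_win/2, read length) bases. Every
# overlapping k-mer of the seed (step 1 on the read side) is looked up in
# the RHT and tallies the windows it occurs in; the N_top windows with most
# hits, extended by L_ext on both sides, become candidate regions.

#' Mapping parameters
#'
#' @param N_top Number of candidate windows kept per strand (default 5).
#' @param L_ext Extension of each candidate window, bp on each side
#'   (default 400).
#' @param nesd_threshold Read length (bp) below which a read counts as
#'   "short" for the non-equal sequence distribution (default 1024).
#' @param scoring A [scoring_scheme()].
#' @return A list of class `map_params`.
#' @export
map_params <- function(N_top = 5L, L_ext = 400L, nesd_threshold = 1024L,
                       scoring = scoring_scheme()) {
  if (N_top < 1) stop("N_top must be >= 1")
  if (L_ext < 0) stop("L_ext must be >= 0")
  structure(list(N_top = as.integer(N_top), L_ext = as.integer(L_ext),
                 nesd_threshold = as.integer(nesd_threshold),
                 scoring = scoring),
            class = "map_params")
}

#' Extract the mid-read seed
#'
#' The seed is the centered substring of length `min(L_win/2, read length)`
#' (left-biased when the surplus is odd); reads shorter than `L_win/2` are
#' used whole.
#'
#' @param read A [seq_record()].
#' @param params An [index_params()] object.
#' @return A list of class `seed` with `read_id`, `seed_sequence`,
#'   `offset_in_read` (0-based).
#' @export
extract_seed <- function(read, params) {
  len <- nchar(read$seq)
  if (len == 0) stop("empty read")
  seed_len <- min(params$window_stride, len)
  off <- (len - seed_len) %/% 2L
  structure(list(read_id = read$id,
                 seed_sequence = substr(read$seq, off + 1L, off + seed_len),
                 offset_in_read = off),
            class = "seed")
}

#' Count k-mer hits per window for a seed
#'
#' Every overlapping k-mer of the seed (read-side step 1; k-mers containing
#' `N` are skipped) is queried against the RHT; each returned window id
#' increments its tally (multiplicity kept).
#'
#' @param rht A [build_rht()] index.
#' @param seed An [extract_seed()] seed.
#' @return Named integer vector of tallies (names are window ids, only
#'   windows with tally >= 1); empty when the seed is shorter than `k`.
#' @export
count_window_hits <- function(rht, seed) {
  k <- rht$params$k
  if (nchar(seed$seed_sequence) < k)
    return(stats::setNames(integer(0), character(0)))
  codes <- kmer_codes(seed$seed_sequence, k, step = 1L)
  wins <- query_windows_many(rht, codes)
  if (length(wins) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- tabulate(wins + 1L, nbins = rht$n_windows)
  hit <- which(tab > 0L)
  stats::setNames(tab[hit], hit - 1L)
}

#' Select and extend candidate regions
#'
#' Windows are sorted by hit count descending (ties by ascending window
#' id); the first `N_top` become candidate regions, extended by `L_ext` on
#' each side and clamped to the reference.
#'
#' @param hits Named tally vector from [count_window_hits()].
#' @param params A [map_params()] object.
#' @param rht The index the hits came from.
#' @param strand `"+"` or `"-"`: the read orientation that produced the
#'   hits.
#' @return Data frame with `window_id`, `hit_count`, `ref_start`, `ref_end`
#'   (0-based half-open), `strand`, in selection order; empty when `hits`
#'   is empty.
#' @export
select_candidates <- function(hits, params, rht, strand = "+") {
  if (length(hits) == 0)
    return(data.frame(window_id = integer(0), hit_count = integer(0),
                      ref_start = integer(0), ref_end = integer(0),
                      strand = character(0)))
  ids <- as.integer(names(hits))
  ord <- order(-hits, ids)
  take <- ord[seq_len(min(params$N_top, length(ord)))]
  ids <- ids[take]
  win <- rht$windows[match(ids, rht$windows$window_id), ]
  data.frame(window_id = ids,
             hit_count = as.integer(hits[take]),
             ref_start = pmax(0L, win$start - params$L_ext),
             ref_end = pmin(rht$ref_length, win$end + params$L_ext),
             strand = strand,
             stringsAsFactors = FALSE)
}
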