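# Regional Hash Table: overlapping reference windows plus a CSR-style
# k-mer -> window-number map (PointerList + WindowList).

#' Index parameters
#'
#' @param k k-mer length; the dense PointerList has `4^k + 1` entries, so
#'   `k <= 13` is required (use a smaller `k`; a sparse mode is not provided).
#' @param L_win Window length in bp (even). Windows start every `L_win/2` bp.
#' @param ref_kmer_step Step between indexed k-mers inside a window
#'   (default `k`, i.e. non-overlapping k-mers on the reference side).
#' @return A list of class `index_params` with fields `k`, `L_win`,
#'   `window_stride` and `ref_kmer_step`.
#' @export
index_params <- function(k = 13L, L_win = 2048L, ref_kmer_step = k) {
  k <- as.integer(k); L_win <- as.integer(L_win)
  ref_kmer_step <- as.integer(ref_kmer_step)
  if (k < 1L) stop("k must be >= 1")
  if (k > 13L)
    stop("k = ", k, " needs a PointerList of 4^", k,
         " + 1 entries, beyond the dense-mode memory cap; use k <= 13")
  if (L_win < 2L || L_win %% 2L != 0L) stop("L_win must be even and >= 2")
  if (ref_kmer_step < 1L) stop("ref_kmer_step must be >= 1")
  structure(list(k = k, L_win = L_win, window_stride = L_win %/% 2L,
                 ref_kmer_step = ref_kmer_step),
            class = "index_params")
}

#' Encode a k-mer as a 2-bit integer code
#'
#' Big-endian 2-bit encoding with A=0, C=1, G=2, T=3 (first base most
#' significant). Returns `NA` for k-mers containing `N`.
#'
#' @param seq A string of length `k`.
#' @param k k-mer length; defaults to `nchar(seq)`.
#' @return Integer code in `[0, 4^k)`, or `NA`.
#' @export
encode_kmer <- function(seq, k = nchar(seq)) {
  if (nchar(seq) != k) stop("sequence length != k")
  .kmer_codes_cpp(normalize_sequence(seq), as.integer(k), 1L)[1]
}

# All step-`step` k-mer codes of a sequence (NA where a k-mer contains N).
kmer_codes <- function(seq, k, step = 1L) {
  .kmer_codes_cpp(seq, as.integer(k), as.integer(step))
}

#' Partition a reference into overlapping windows
#'
#' Windows of length `L_win` start at every multiple of `L_win/2` below the
#' reference length; ends are clamped to the reference length and trailing
#' windows shorter than `k` (too short to host a k-mer) are dropped.
#'
#' @param ref_length Reference length in bp.
#' @param params An [index_params()] object.
#' @return A data frame with columns `window_id` (0-based), `start`, `end`
#'   (0-based half-open bp).
#' @export
partition_windows <- function(ref_length, params) {
  if (ref_length < 1) stop("ref_length must be >= 1")
  starts <- seq.int(0L, ref_length - 1L, by = params$window_stride)
  ends <- pmin(starts + params$L_win, ref_length)
  keep <- (ends - starts) >= params$k
  data.frame(window_id = seq_along(starts)[keep] - 1L,
             start = starts[keep], end = ends[keep])
}

#' Build the Regional Hash Table of a reference
#'
#' Within each window, k-mers are taken at in-window offsets
#' `0, step, 2*step, ...` (offset + k <= window length). Every non-`N` k-mer
#' contributes one (code, window) occurrence -- duplicates within a window
#' are kept, so query tallies reflect occurrence multiplicity. Occurrences
#' are grouped into CSR form by two-pass counting.
#'
#' @param reference A [seq_record()].
#' @param params An [index_params()] object.
#' @return A list of class `rht` with fields `params`, `ref_name`,
#'   `ref_length`, `n_windows`, `windows`, `pointer_list` (length `4^k + 1`)
#'   and `window_list`.
#' @export
build_rht <- function(reference, params = index_params()) {
  seq <- reference$seq
  if (is.null(seq) || nchar(seq) == 0) stop("empty reference")
  k <- params$k
  win <- partition_windows(nchar(seq), params)
  # step-1 codes over the whole reference, indexed once; window extraction
  # then just gathers at the right absolute positions
  all_codes <- kmer_codes(seq, k, step = 1L)
  occ_code <- vector("list", nrow(win))
  occ_win <- vector("list", nrow(win))
  for (w in seq_len(nrow(win))) {
    len <- win$end[w] - win$start[w]
    offs <- seq.int(0L, len - k, by = params$ref_kmer_step)
    codes <- all_codes[win$start[w] + offs + 1L]
    keep <- !is.na(codes)
    occ_code[[w]] <- codes[keep]
    occ_win[[w]] <- rep.int(win$window_id[w], sum(keep))
  }
  codes <- unlist(occ_code, use.names = FALSE)
  wins <- unlist(occ_win, use.names = FALSE)
  nbins <- 4^k
  counts <- tabulate(codes + 1L, nbins = nbins)
  pointer_list <- c(0L, cumsum(counts))
  # stable order: windows were generated ascending, so within each code's
  # slice window ids stay ascending
  ord <- order(codes, method = "radix")
  structure(list(params = params, ref_name = reference$id,
                 ref_length = nchar(seq), n_windows = nrow(win),
                 windows = win, pointer_list = pointer_list,
                 window_list = wins[ord]),
            class = "rht")
}

#' @export
print.rht <- function(x, ...) {
  cat(sprintf(paste0("<rht> %s: %d bp, %d windows (L_win=%d, stride=%d), ",
                     "k=%d, %d k-mer occurrences\n"),
              x$ref_name, x$ref_length, x$n_windows, x$params$L_win,
              x$params$window_stride, x$params$k,
              length(x$window_list)))
  invisible(x)
}

#' Query the windows containing a k-mer code
#'
#' @param rht An [build_rht()] index.
#' @param code Integer code in `[0, 4^k)`.
#' @return Integer vector of window ids (with repeats for multiple
#'   occurrences in one window); empty when the k-mer is absent.
#' @export
query_windows <- function(rht, code) {
  if (is.na(code) || code < 0 || code >= 4^rht$params$k)
    stop("code out of range [0, 4^k)")
  lo <- rht$pointer_list[code + 1L]
  hi <- rht$pointer_list[code + 2L]
  if (hi <= lo) return(integer(0))
  rht$window_list[(lo + 1L):hi]
}

# Vectorized gather for many codes at once (NAs dropped). Returns all window
# ids concatenated, one per occurrence.
query_windows_many <- function(rht, codes) {
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0) return(integer(0))
  lo <- rht$pointer_list[codes + 1L]
  hi <- rht$pointer_list[codes + 2L]
  n <- hi - lo
  keep <- n > 0L
  if (!any(keep)) return(integer(0))
  rht$window_list[sequence(n[keep], from = lo[keep] + 1L)]
}

#' Save an RHT index to a file
#'
#' Little-endian binary format: the magic string `RHT`, a format version,
#' the parameters and reference metadata, then the PointerList and
#' WindowList arrays.
#'
#' @param rht An [build_rht()] index.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_rht <- function(rht, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RHT", con, nchars = 3, eos = NULL)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(c(rht$params$k, rht$params$L_win, rht$params$ref_kmer_step,
             rht$ref_length, rht$n_windows), con, size = 4, endian = "little")
  nm <- charToRaw(rht$ref_name)
  writeBin(length(nm), con, size = 4, endian = "little")
  writeBin(nm, con)
  writeBin(length(rht$window_list), con, size = 4, endian = "little")
  writeBin(rht$pointer_list, con, size = 4, endian = "little")
  writeBin(rht$window_list, con, size = 4, endian = "little")
  invisible(path)
}

#' Load an RHT index from a file
#'
#' @param path Path written by [save_rht()].
#' @return A list of class `rht`.
#' @export
load_rht <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchars = 3)
  if (!identical(magic, "RHT")) stop("not an RHT index file: ", path)
  version <- readBin(con, "integer", size = 4, endian = "little")
  if (version != 1L) stop("unsupported RHT index version ", version)
  meta <- readBin(con, "integer", n = 5, size = 4, endian = "little")
  nm_len <- readBin(con, "integer", size = 4, endian = "little")
  ref_name <- rawToChar(readBin(con, "raw", n = nm_len))
  n_wl <- readBin(con, "integer", size = 4, endian = "little")
  params <- index_params(k = meta[1], L_win = meta[2], ref_kmer_step = meta[3])
  pointer_list <- readBin(con, "integer", n = 4^params$k + 1, size = 4,
                          endian = "little")
  window_list <- readBin(con, "integer", n = n_wl, size = 4,
                         endian = "little")
  structure(list(params = params, ref_name = ref_name, ref_length = meta[4],
                 n_windows = meta[5],
                 windows = partition_windows(meta[4], params),
                 pointer_list = pointer_list, window_list = window_list),
            class = "rht")
}
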