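# Independent oracles, deliberately naive and kept free of the package's
# DP code paths.

# O(n^3) global alignment score: the gap matrices are replaced by explicit
# enumeration of every gap length, charged at the closed-form 2-piece cost.
oracle_gap_cost <- function(g, s) {
  pmin(s$gap_open + g * s$gap_extend, s$gap_open2 + g * s$gap_extend2)
}

oracle_align_score <- function(target, query, s) {
  Lt <- nchar(target); Lq <- nchar(query)
  tc <- strsplit(target, "", fixed = TRUE)[[1]]
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  H <- matrix(-Inf, Lt + 1, Lq + 1)
  H[1, 1] <- 0
  for (i in 0:Lt) {
    for (j in 0:Lq) {
      if (i == 0 && j == 0) next
      best <- -Inf
      if (i > 0 && j > 0) {
        m <- if (tc[i] == qc[j] && tc[i] != "N") s$match else s$mismatch
        best <- max(best, H[i, j] + m)
      }
      if (i > 0) # target-consuming gap of every length g = 1..i
        best <- max(best, max(H[seq_len(i), j + 1] - oracle_gap_cost(i:1, s)))
      if (j > 0)
        best <- max(best, max(H[i + 1, seq_len(j)] - oracle_gap_cost(j:1, s)))
      H[i + 1, j + 1] <- best
    }
  }
  H[Lt + 1, Lq + 1]
}

random_dna <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_scheme <- function() {
  scoring_scheme(match = sample(1:3, 1), mismatch = -sample(2:6, 1),
                 gap_open = sample(0:6, 1), gap_extend = sample(1:4, 1),
                 gap_open2 = sample(8:30, 1), gap_extend2 = sample(1:4, 1))
}

# Brute-force RHT query: re-extract step-k k-mers from every window and
# collect the windows containing the code.
brute_force_windows <- function(ref_seq, params, code) {
  win <- partition_windows(nchar(ref_seq), params)
  k <- params$k
  hits <- integer(0)
  for (w in seq_len(nrow(win))) {
    wseq <- substr(ref_seq, win$start[w] + 1L, win$end[w])
    offs <- seq.int(0L, nchar(wseq) - k, by = params$ref_kmer_step)
    for (o in offs) {
      km <- substr(wseq, o + 1L, o + k)
      if (!grepl("N", km, fixed = TRUE) && encode_kmer(km) == code)
        hits <- c(hits, win$window_id[w])
    }
  }
  hits
}
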