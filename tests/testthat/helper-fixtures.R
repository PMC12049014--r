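# Programmatic fixtures, built once per test run and cached.

# 4-record FASTQ whose record byte spans are [0,16), [16,36), [36,52),
# [52,72) -- small enough to enumerate heads by hand.
write_fixture_fastq <- function(path = tempfile(fileext = ".fq")) {
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "@r2", "ACGTAC", "+", "IIIIII",
               "@r3", "ACGT", "+", "IIII",
               "@r4", "ACGTAC", "+", "IIIIII"), path)
  path
}

fixture_spans <- function() cbind(start = c(0, 16, 36, 52),
                                  end = c(16, 36, 52, 72))

# FASTQ with n records of varying sizes (deterministic).
write_varied_fastq <- function(n, path = tempfile(fileext = ".fq"),
                               seed = 99) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  lines <- unlist(lapply(seq_len(n), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(5:40, 1), TRUE),
               collapse = "")
    c(paste0("@x", i), s, "+", strrep("I", nchar(s)))
  }))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  writeLines(lines, path)
  path
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache))
    assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Small mapping fixture: 10 kb reference indexed at the defaults.
map_fixture <- function() {
  cached("map_fixture", {
    ref <- simulate_reference(10000, seed = 11)
    list(ref = ref, rht = build_rht(ref, index_params()))
  })
}

# Study-condition dataset: 100 kb reference, 200 noisy SMRT-like reads.
acc_dataset <- function() {
  cached("acc_dataset", {
    ref <- simulate_reference(100000, seed = 101)
    rht <- build_rht(ref, index_params())
    sim <- simulate_reads(ref, sim_config(seed = 202))
    list(ref = ref, rht = rht, reads = sim$reads, truth = sim$truth)
  })
}

# The noisy reads mapped once, with every DP invocation logged.
acc_mapped_noisy <- function() {
  cached("acc_mapped_noisy", {
    d <- acc_dataset()
    dp <- new_dp_log()
    mapped <- lapply(d$reads, function(r)
      map_read(d$rht, d$ref, r, dp_log = dp))
    list(mapped = mapped, dp = dp)
  })
}
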