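test_that("simulate_reference is deterministic and roughly uniform", {
  expect_identical(simulate_reference(500, seed = 7)$seq,
                   simulate_reference(500, seed = 7)$seq)
  expect_false(identical(simulate_reference(500, seed = 7)$seq,
                         simulate_reference(500, seed = 8)$seq))
  ref <- simulate_reference(100000, seed = 1)
  freq <- table(strsplit(ref$seq, "", fixed = TRUE)[[1]]) / 100000
  expect_true(all(freq >= 0.23 & freq <= 0.27)) # 5-sd binomial envelope
  expect_true(simulate_reference(1, seed = 2)$seq %in% c("A", "C", "G", "T"))
  expect_error(simulate_reference(0), ">= 1")
})

test_that("the identity channel copies exact substrings with truth", {
  ref <- simulate_reference(20000, seed = 3)
  cfg <- sim_config(ref_length = 20000, n_reads = 25,
                    read_length_mean = 800, read_length_sd = 150,
                    min_read_length = 300, max_read_length = 1500,
                    sub_rate = 0, ins_rate = 0, del_rate = 0, rc_prob = 0,
                    seed = 4)
  sim <- simulate_reads(ref, cfg)
  expect_length(sim$reads, 25)
  for (w in seq_len(25)) {
    tr <- sim$truth[w, ]
    expect_identical(sim$reads[[w]]$seq,
                     substr(ref$seq, tr$ref_start + 1, tr$ref_end))
    expect_equal(tr$n_errors, 0)
  }
  expect_true(all(sim$truth$ref_start >= 0 & sim$truth$ref_end <= 20000 &
                    sim$truth$ref_start < sim$truth$ref_end))
  # determinism, and rc_prob flips orientation
  sim2 <- simulate_reads(ref, cfg)
  expect_identical(vapply(sim$reads, `[[`, "", "seq"),
                   vapply(sim2$reads, `[[`, "", "seq"))
  cfg_rc <- sim_config(ref_length = 20000, n_reads = 25,
                       read_length_mean = 800, read_length_sd = 150,
                       min_read_length = 300, max_read_length = 1500,
                       sub_rate = 0, ins_rate = 0, del_rate = 0,
                       rc_prob = 1, seed = 4)
  sim_rc <- simulate_reads(ref, cfg_rc)
  expect_true(all(sim_rc$truth$strand == "-"))
})

test_that("realized error counts sit inside 5-sd binomial envelopes", {
  ref <- simulate_reference(50000, seed = 5)
  cfg <- sim_config(ref_length = 50000, n_reads = 30,
                    read_length_mean = 1000, read_length_sd = 150,
                    min_read_length = 500, max_read_length = 2000, seed = 6)
  sim <- simulate_reads(ref, cfg)
  n <- sum(sim$truth$orig_length)
  expect_gt(n, 1e4)
  for (ty in list(c("n_sub", 0.02), c("n_ins", 0.09), c("n_del", 0.04))) {
    p <- as.numeric(ty[2])
    x <- sum(sim$truth[[ty[1]]])
    band <- 5 * sqrt(n * p * (1 - p))
    expect_gt(x, n * p - band)
    expect_lt(x, n * p + band)
  }
})

test_that("aligned edit fraction tracks the configured total error rate", {
  ref <- simulate_reference(30000, seed = 5)
  cfg <- sim_config(ref_length = 30000, n_reads = 60,
                    read_length_mean = 600, read_length_sd = 100,
                    min_read_length = 300, max_read_length = 900, seed = 9)
  sim <- simulate_reads(ref, cfg)
  s <- scoring_scheme()
  frac <- vapply(seq_along(sim$reads), function(w) {
    tr <- sim$truth[w, ]
    orig <- substr(ref$seq, tr$ref_start + 1, tr$ref_end)
    q <- if (tr$strand == "-") revcomp(sim$reads[[w]]$seq)
         else sim$reads[[w]]$seq
    a <- align_rowcol(orig, q, s)
    gap_cols <- sum(a$cigar$length[a$cigar$op != "M"])
    # mismatch columns inside M runs
    mm <- 0L; ti <- 0L; qi <- 0L
    tc <- strsplit(orig, "", fixed = TRUE)[[1]]
    qc <- strsplit(q, "", fixed = TRUE)[[1]]
    for (v in seq_len(nrow(a$cigar))) {
      len <- a$cigar$length[v]; op <- a$cigar$op[v]
      if (op == "M") {
        mm <- mm + sum(tc[ti + seq_len(len)] != qc[qi + seq_len(len)])
        ti <- ti + len; qi <- qi + len
      } else if (op == "D") ti <- ti + len else qi <- qi + len
    }
    (gap_cols + mm) / tr$orig_length
  }, 0)
  expect_lt(abs(mean(frac) - 0.15), 0.03)
})

test_that("evaluate scores mapping recall against the truth table", {
  ref <- simulate_reference(20000, seed = 13)
  rht <- build_rht(ref, index_params(k = 11))
  cfg <- sim_config(ref_length = 20000, n_reads = 15,
                    read_length_mean = 800, read_length_sd = 100,
                    min_read_length = 400, max_read_length = 1500,
                    sub_rate = 0, ins_rate = 0, del_rate = 0, seed = 14)
  sim <- simulate_reads(ref, cfg)
  mapped <- lapply(sim$reads, function(r) map_read(rht, ref, r))
  rep <- evaluate(mapped, sim$truth, tolerance = 1024)
  expect_equal(rep$mapping_recall, 100)
  expect_equal(rep$n_unmapped, 0)
  # strand mismatches and distant positions are not counted as correct
  wrong <- sim$truth
  wrong$strand <- chartr("+-", "-+", wrong$strand)
  expect_equal(evaluate(mapped, wrong, tolerance = 1024)$mapping_recall, 0)
  # empty input: recall 0, no crash
  empty <- evaluate(list(), sim$truth, tolerance = 1024)
  expect_equal(empty$mapping_recall, 0)
})

test_that("truth tables round-trip through the TSV format", {
  truth <- data.frame(read_id = c("a", "b"), ref_start = c(0L, 10L),
                      ref_end = c(5L, 30L), strand = c("+", "-"),
                      n_errors = c(0L, 3L), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_truth(truth, path)
  expect_equal(read_truth(path), truth)
})
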