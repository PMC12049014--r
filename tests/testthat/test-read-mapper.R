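test_that("find_anchors lists every exact shared k-mer pair", {
  a <- find_anchors("ACGTACGT", "ACGT", k = 4)
  expect_equal(a$read_pos, c(0L, 0L))
  expect_equal(a$ref_pos, c(0L, 4L))
  # brute-force cross-check on random sequences
  set.seed(14)
  for (rep in 1:5) {
    region <- random_dna(60); read <- random_dna(40); k <- sample(2:4, 1)
    got <- find_anchors(region, read, k)
    want <- expand.grid(read_pos = 0:(nchar(read) - k),
                        ref_pos = 0:(nchar(region) - k))
    keep <- mapply(function(qp, rp)
      substr(read, qp + 1, qp + k) == substr(region, rp + 1, rp + k),
      want$read_pos, want$ref_pos)
    want <- want[keep, ]
    want <- want[order(want$read_pos, want$ref_pos), ]
    expect_equal(got$read_pos, want$read_pos)
    expect_equal(got$ref_pos, want$ref_pos)
  }
  expect_equal(nrow(find_anchors("AAAA", "CCCC", k = 3)), 0)
  one <- find_anchors("ACGT", "ACGT", k = 4)
  expect_equal(unlist(one), c(read_pos = 0L, ref_pos = 0L))
})

test_that("chain_anchors keeps collinear anchors and drops costly joins", {
  s <- scoring_scheme()
  k <- 3
  # collinear, equal offsets: both anchors chained, no gap penalty
  an <- data.frame(read_pos = c(0L, 5L), ref_pos = c(0L, 5L))
  ch <- chain_anchors(an, s, k)
  expect_equal(nrow(ch$anchors), 2)
  expect_equal(ch$chain_score, 2 * k * s$match)
  # joining across a 6-diagonal shift costs more than a second anchor earns
  an2 <- data.frame(read_pos = c(0L, 3L), ref_pos = c(0L, 9L))
  ch2 <- chain_anchors(an2, s, k)
  expect_equal(nrow(ch2$anchors), 1)
  expect_equal(ch2$anchors$ref_pos, 0L) # tie broken toward leftmost start
  expect_equal(ch2$chain_score, k * s$match)
  # crossing anchors violate collinearity: no edge
  an3 <- data.frame(read_pos = c(0L, 4L), ref_pos = c(4L, 0L))
  expect_equal(nrow(chain_anchors(an3, s, k = 4)$anchors), 1)
  # empty input
  ch0 <- chain_anchors(data.frame(read_pos = integer(0),
                                  ref_pos = integer(0)), s, k)
  expect_equal(nrow(ch0$anchors), 0)
  expect_equal(ch0$chain_score, 0)
})

test_that("align_candidate stitches anchors and flank pieces exactly", {
  s <- scoring_scheme()
  k <- 5
  set.seed(31)
  region <- random_dna(80)
  # read == region: all-M, full match score
  ch <- chain_anchors(find_anchors(region, region, k), s, k)
  res <- align_candidate(region, region, ch, s)
  expect_equal(res$score, 80 * s$match)
  expect_equal(cigar_string(res$cigar), "80M")
  expect_equal(res$t_span, c(0, 80))
  # one substituted base: piecewise equals the full row-column DP
  read <- paste0(substr(region, 1, 39),
                 chartr("ACGT", "CAGT", substr(region, 40, 40)),
                 substr(region, 41, 80))
  ch2 <- chain_anchors(find_anchors(region, read, k), s, k)
  res2 <- align_candidate(region, read, ch2, s)
  full <- align_rowcol(region, read, s)
  expect_equal(res2$score, full$score)
  expect_equal(res2$score, 80 * s$match - s$match + s$mismatch)
  # empty chain falls back to one global alignment with flank trimming
  sub <- substr(region, 21, 60)
  empty <- chain_anchors(data.frame(read_pos = integer(0),
                                    ref_pos = integer(0)), s, k)
  res3 <- align_candidate(region, sub, empty, s)
  expect_equal(res3$t_span, c(20, 60))
  expect_equal(res3$score, 40 * s$match) # flank D runs trimmed, not charged
  expect_equal(score_cigar(res3$cigar,
                           substr(region, res3$t_span[1] + 1,
                                  res3$t_span[2]), sub, s), res3$score)
})

test_that("map_read recovers planted reads on both strands", {
  fx <- map_fixture()
  read <- seq_record("fwd", substr(fx$ref$seq, 1001, 3000))
  m <- map_read(fx$rht, fx$ref, read)
  expect_true(m$is_mapped)
  expect_equal(m$sam_pos, 1001)
  expect_equal(m$strand, "+")
  expect_equal(cigar_string(m$cigar), "2000M")
  expect_equal(m$score, 2000 * 2)
  expect_true(m$mapq >= 0 && m$mapq <= 60)

  rc <- seq_record("rev", revcomp(substr(fx$ref$seq, 1001, 3000)))
  m2 <- map_read(fx$rht, fx$ref, rc)
  expect_equal(m2$strand, "-")
  expect_equal(m2$sam_pos, 1001)
  sam <- mapped_read_to_sam(m2, fx$rht$ref_name, index = 1L)
  expect_equal(bitwAnd(sam$flag, 16L), 16L)
  # SAM seq is the reference-strand orientation, CIGAR consumes it exactly
  expect_equal(sam$seq, substr(fx$ref$seq, 1001, 3000))
  expect_equal(score_cigar(sam$cigar,
                           substr(fx$ref$seq, m2$sam_pos,
                                  m2$sam_pos - 1 + 2000), sam$seq,
                           scoring_scheme()), m2$score)

  # deterministic: identical calls give identical results
  expect_identical(map_read(fx$rht, fx$ref, read),
                   map_read(fx$rht, fx$ref, read))
})

test_that("reads sharing no k-mer with the reference stay unmapped", {
  fx <- map_fixture()
  # poly-N shares no k-mer and cannot be seeded
  read <- seq_record("junk", strrep("N", 500))
  m <- map_read(fx$rht, fx$ref, read)
  expect_false(m$is_mapped)
  sam <- mapped_read_to_sam(m, fx$rht$ref_name, index = 1L)
  expect_equal(bitwAnd(sam$flag, 4L), 4L)
  expect_equal(sam$rname, "*")
})

test_that("piecewise DP invocations match the row-column reference", {
  fx <- map_fixture()
  dp <- new_dp_log()
  # a noisy read exercises substitution/indel pieces
  orig <- substr(fx$ref$seq, 4001, 5200)
  noisy <- local({
    set.seed(77)
    ch <- strsplit(orig, "")[[1]]
    idx <- sample(length(ch), 60)
    ch[idx] <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
    paste(ch, collapse = "")
  })
  m <- map_read(fx$rht, fx$ref, seq_record("noisy", noisy), dp_log = dp)
  expect_true(m$is_mapped)
  expect_gt(length(dp$pairs), 0)
  s <- scoring_scheme()
  for (pr in dp$pairs)
    expect_identical(align_rowcol(pr$target, pr$query, s)$score, pr$score)
})
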