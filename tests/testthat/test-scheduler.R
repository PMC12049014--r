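test_that("static_split floors byte boundaries per worker", {
  r <- static_split(1000, 4)
  expect_equal(r$start, c(0, 250, 500, 750))
  expect_equal(r$end, c(250, 500, 750, 1000))
  expect_equal(static_split(1000, 1), data.frame(start = 0, end = 1000))
  r3 <- static_split(10, 3)
  expect_equal(r3$start, c(0, 3, 6))
  expect_equal(r3$end, c(3, 6, 10))
  expect_error(static_split(10, 0), "p must be")
})

test_that("refine_split relocates boundaries to record heads", {
  fq <- write_fixture_fastq()
  refined <- refine_split(fq, static_split(72, 3)) # naive cuts at 24, 48
  expect_equal(refined$start, c(0, 36, 52))
  expect_equal(refined$end, c(36, 52, 72))
  counts <- vapply(seq_len(nrow(refined)), function(w)
    length(read_fastq_range(fq, refined$start[w], refined$end[w])), 0L)
  expect_equal(counts, c(2L, 1L, 1L))
  # boundaries already on heads are a fixed point
  heads <- data.frame(start = c(0, 16, 36, 52), end = c(16, 36, 52, 72))
  expect_equal(refine_split(fq, heads), heads)
  # more workers than records: empty ranges, records conserved
  many <- refine_split(fq, static_split(72, 9))
  cnt <- vapply(seq_len(nrow(many)), function(w)
    length(read_fastq_range(fq, many$start[w], many$end[w])), 0L)
  expect_equal(sum(cnt), 4L)
  expect_true(any(cnt == 0L))
})

test_that("the ILB plan splits alpha statically and batches the rest", {
  fq <- write_varied_fastq(1000)
  plan <- make_ilb_plan(fq, p = 4, alpha = 0.8, bs = 128)
  n_static <- sum(vapply(seq_len(nrow(plan$static_ranges)), function(w)
    length(read_fastq_range(fq, plan$static_ranges$start[w],
                            plan$static_ranges$end[w])), 0L))
  expect_equal(n_static, 800L)
  expect_equal(plan$dynamic_batches$last - plan$dynamic_batches$first + 1,
               c(128L, 72L))
  # pure SSD and pure DSD boundaries
  expect_equal(nrow(make_ilb_plan(fq, 4, alpha = 1)$dynamic_batches), 0)
  pure <- make_ilb_plan(fq, 4, alpha = 0, bs = 1)
  expect_equal(nrow(pure$dynamic_batches), 1000)
  expect_equal(nrow(pure$static_ranges), 0)
  # coverage: static ranges + batches partition the record set
  idx_static <- unlist(lapply(seq_len(nrow(plan$static_ranges)), function(w)
    vapply(read_fastq_range(fq, plan$static_ranges$start[w],
                            plan$static_ranges$end[w]), `[[`, "", "id")))
  all_ids <- vapply(read_fastq(fq), `[[`, "", "id")
  idx_dyn <- unlist(lapply(seq_len(nrow(plan$dynamic_batches)), function(w)
    all_ids[plan$dynamic_batches$first[w]:plan$dynamic_batches$last[w]]))
  expect_setequal(c(idx_static, idx_dyn), all_ids)
  expect_equal(length(c(idx_static, idx_dyn)), length(all_ids))
})

test_that("nesd_partition splits records at the length threshold", {
  recs <- lapply(c(500, 1024, 2000), function(n)
    seq_record(paste0("r", n), strrep("A", n)))
  pt <- nesd_partition(recs, 1024)
  expect_equal(vapply(pt$short, function(r) nchar(r$seq), 0L), 500L)
  expect_equal(vapply(pt$long, function(r) nchar(r$seq), 0L),
               c(1024L, 2000L)) # strict < threshold
  pt0 <- nesd_partition(recs, 0)
  expect_length(pt0$short, 0)
  expect_length(pt0$long, 3)
  expect_equal(length(pt$short) + length(pt$long), length(recs))
})

test_that("the analytic cost model reproduces its closed forms", {
  cp <- cost_model_params(O_c = 1, G = 100, D_send = 100, D_recv = 100,
                          T_cpu = 10, T_dev = 8)
  expect_equal(model_runtime("blocking", cp), 14)
  expect_equal(model_runtime("nonblocking", cp), 12)
  expect_equal(model_runtime("nesd_s", cp), 12) # O_c + (T_send+T_dev+O_c+T_recv)
  # orderings: overlap never hurts when the device is no slower than the host
  set.seed(6)
  for (rep in 1:20) {
    T_dev <- runif(1, 0, 10)
    cp1 <- cost_model_params(O_c = runif(1, 0, 3), G = runif(1, 1, 50),
                             D_send = runif(1, 0, 200),
                             D_recv = runif(1, 0, 200),
                             T_cpu = T_dev + runif(1, 0, 5), T_dev = T_dev)
    expect_lte(model_runtime("nonblocking", cp1),
               model_runtime("blocking", cp1))
    # primed (NESD-l) terms are all larger -> longer total runtime
    cp2 <- cost_model_params(O_c = cp1$O_c, G = cp1$G,
                             D_send = cp1$D_send * 2,
                             D_recv = cp1$D_recv * 2,
                             T_cpu = cp1$T_cpu * 2, T_dev = T_dev + 1)
    expect_gt(model_runtime("nesd_l", cp2), model_runtime("nesd_s", cp1))
  }
})

test_that("DP-matrix transmission time follows the quadratic law exactly", {
  expect_equal(transmission_time(10, 100), 1.0)
  expect_equal(transmission_time(0, 50), 0)
  # exact when the division is exact (power-of-two bandwidth)
  for (L in c(1, 7, 128, 3000)) for (n in c(2, 3, 10)) for (G in c(1, 4, 64))
    expect_identical(transmission_time(n * L, G),
                     n^2 * transmission_time(L, G))
  for (G in c(7, 100))
    expect_equal(transmission_time(3 * 11, G),
                 9 * transmission_time(11, G))
  expect_error(transmission_time(10, 0), "G must be")
})

test_that("speedup and efficiency follow the slowest-worker bound", {
  m <- parallel_metrics(100, c(25, 25, 25, 25))
  expect_equal(m$S_p, 4)
  expect_equal(m$E_p, 1.0)
  m2 <- parallel_metrics(100, c(50, 10, 10, 10))
  expect_equal(m2$S_p, 2)
  expect_equal(m2$E_p, 0.5)
  m1 <- parallel_metrics(100, 100)
  expect_equal(m1$S_p, 1)
  expect_equal(m1$E_p, 1)
  expect_error(parallel_metrics(10, numeric(0)), "empty")
})

test_that("run_parallel processes every record exactly once, any plan", {
  fq <- write_varied_fastq(83)
  truth <- vapply(read_fastq(fq), function(r) nchar(r$seq), 0L)
  mapper <- function(rec) nchar(rec$seq)
  for (p in c(1, 2)) for (alpha in c(0, 0.5, 1)) for (bs in c(1, 16)) {
    plan <- make_ilb_plan(fq, p, alpha = alpha, bs = bs)
    run <- run_parallel(plan, mapper, p)
    expect_equal(unlist(run$results), truth)
    expect_equal(run$metrics$p, p)
    expect_gt(run$metrics$S_p, 0)
  }
})

test_that("worker failures surface the failing record id", {
  fq <- write_fixture_fastq()
  plan <- make_ilb_plan(fq, 1, alpha = 1)
  bad_mapper <- function(rec)
    if (rec$id == "r3") stop("boom on ", rec$id) else rec$id
  expect_error(run_parallel(plan, bad_mapper, 1), "r3")
})
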