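# Work distribution: static byte-range splitting (SSD) with precise FASTQ
# boundary relocation, the integrated static + batched-dynamic plan (ILB),
# the length-threshold partition (NESD), the analytic host/device
# communication cost model, and execution over a local fork-based worker
# pool with speedup/efficiency metrics.

#' Static byte-range split of a file
#'
#' Range `i` (0-based) is `[floor(V*i/p), floor(V*(i+1)/p))`; the ranges
#' tile `[0, V)`.
#'
#' @param V_fastq Total bytes.
#' @param p Number of workers.
#' @return Data frame with `start`, `end` (bytes, half-open).
#' @export
static_split <- function(V_fastq, p) {
  if (p < 1) stop("p must be >= 1")
  if (V_fastq < 0) stop("V_fastq must be >= 0")
  bounds <- floor(V_fastq * (0:p) / p)
  data.frame(start = bounds[-(p + 1)], end = bounds[-1])
}

#' Relocate byte ranges to FASTQ record heads
#'
#' Each range start is advanced to the next record head with
#' [locate_record_head()]; each end becomes the successor's refined start
#' (the last end is the file size). Ranges may come out empty: a worker may
#' get zero records.
#'
#' @param path Path to a 4-line FASTQ file.
#' @param ranges Data frame with `start`, `end` tiling `[0, file size)`.
#' @return Data frame with refined `start`, `end`.
#' @export
refine_split <- function(path, ranges) {
  starts <- vapply(ranges$start, function(b) locate_record_head(path, b), 0)
  ends <- c(starts[-1], file.size(path))
  data.frame(start = starts, end = ends)
}

#' Build an integrated load-balancing plan
#'
#' The first `floor(alpha * n_records)` records are split statically by
#' bytes (then refined to record heads); the remaining records are grouped
#' into consecutive batches of `bs` (the last may be smaller) that workers
#' pull from a shared queue in file order.
#'
#' @param path Path to a 4-line FASTQ file.
#' @param p Number of workers.
#' @param alpha Fraction of records distributed statically, in `[0, 1]`
#'   (default 0.8).
#' @param bs Batch size in records (default 128).
#' @return A list of class `dist_plan`: `path`, `V_fastq`, `p`, `alpha`,
#'   `bs`, `n_records`, `record_offsets`, `static_ranges` (byte ranges),
#'   `dynamic_batches` (1-based record index ranges `first`, `last`).
#' @export
make_ilb_plan <- function(path, p, alpha = 0.8, bs = 128L) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (bs < 1) stop("bs must be >= 1")
  if (p < 1) stop("p must be >= 1")
  offs <- fastq_offsets(path)
  sz <- offs[length(offs)]
  heads <- offs[-length(offs)]
  n <- length(heads)
  n_static <- floor(alpha * n)
  static_end <- if (n_static < n) heads[n_static + 1L] else sz
  if (n_static > 0) {
    ranges <- static_split(static_end, p)
    starts <- vapply(ranges$start, function(b) locate_record_head(path, b), 0)
    static_ranges <- data.frame(start = starts,
                                end = c(starts[-1], static_end))
  } else {
    static_ranges <- data.frame(start = numeric(0), end = numeric(0))
  }
  if (n_static < n) {
    first <- seq.int(n_static + 1L, n, by = bs)
    dynamic_batches <- data.frame(first = first,
                                  last = pmin(first + bs - 1L, n))
  } else {
    dynamic_batches <- data.frame(first = integer(0), last = integer(0))
  }
  structure(list(path = path, V_fastq = sz, p = as.integer(p), alpha = alpha,
                 bs = as.integer(bs), n_records = n, record_offsets = offs,
                 static_ranges = static_ranges,
                 dynamic_batches = dynamic_batches),
            class = "dist_plan")
}

#' @export
print.dist_plan <- function(x, ...) {
  cat(sprintf(paste0("<dist_plan> %d records (%d bytes), p=%d, alpha=%.2f, ",
                     "bs=%d: %d static ranges + %d dynamic batches\n"),
              x$n_records, x$V_fastq, x$p, x$alpha, x$bs,
              nrow(x$static_ranges), nrow(x$dynamic_batches)))
  invisible(x)
}

#' Partition records by length (NESD)
#'
#' Records shorter than `threshold` go to the "short" class (processed by
#' the accelerator-class workers under NESD-s), the rest to the "long"
#' class; order is preserved within each class.
#'
#' @param records List of [seq_record()] objects.
#' @param threshold Length threshold in bp (default 1024; strict `<`).
#' @return A list with `short` and `long` record lists.
#' @export
nesd_partition <- function(records, threshold = 1024L) {
  if (threshold < 0) stop("threshold must be >= 0")
  lens <- vapply(records, function(r) nchar(r$seq), 0L)
  list(short = records[lens < threshold], long = records[lens >= threshold])
}

#' Host/device communication cost model parameters
#'
#' @param O_c Communication startup overhead (time units).
#' @param G Transfer bandwidth (bytes per time unit, > 0).
#' @param D_send,D_recv Data volumes sent to / received from the device.
#' @param T_cpu,T_dev Host and device compute times. For the NESD-l
#'   analysis, supply the primed quantities in the same fields.
#' @return A list of class `cost_model_params` with derived `T_send`,
#'   `T_recv`.
#' @export
cost_model_params <- function(O_c, G, D_send, D_recv, T_cpu = 0,
                              T_dev = 0) {
  if (G <= 0) stop("G must be > 0")
  if (any(c(O_c, D_send, D_recv, T_cpu, T_dev) < 0))
    stop("cost model terms must be non-negative")
  structure(list(O_c = O_c, G = G, D_send = D_send, D_recv = D_recv,
                 T_cpu = T_cpu, T_dev = T_dev, T_send = D_send / G,
                 T_recv = D_recv / G),
            class = "cost_model_params")
}

#' Analytic total runtime of the host/device pipeline
#'
#' Closed forms: blocking communication gives
#' `2*O_c + (D_send + D_recv)/G + T_cpu`; non-blocking substitutes `T_dev`
#' for `T_cpu`; NESD-s gives `O_c + T_cpu` with
#' `T_cpu = T_send + T_dev + O_c + T_recv`; NESD-l evaluates the same form
#' with the primed quantities supplied in `cp`.
#'
#' @param mode One of `"blocking"`, `"nonblocking"`, `"nesd_s"`, `"nesd_l"`.
#' @param cp A [cost_model_params()] object.
#' @return Total runtime (same units as the inputs).
#' @export
model_runtime <- function(mode = c("blocking", "nonblocking", "nesd_s",
                                   "nesd_l"), cp) {
  mode <- match.arg(mode)
  comm <- (cp$D_send + cp$D_recv) / cp$G
  switch(mode,
         blocking = 2 * cp$O_c + comm + cp$T_cpu,
         nonblocking = 2 * cp$O_c + comm + cp$T_dev,
         nesd_s = ,
         nesd_l = cp$O_c + (cp$T_send + cp$T_dev + cp$O_c + cp$T_recv))
}

#' Transmission time of a DP matrix
#'
#' The DP matrix for a sequence of length `L` has `L^2` cells, so its
#' transfer takes `L^2 / G`: doubling the sequence quadruples the
#' communication, which is why short sequences belong on the device.
#'
#' @param L Sequence length (bp).
#' @param G Bandwidth (> 0).
#' @return Time.
#' @export
transmission_time <- function(L, G) {
  if (G <= 0) stop("G must be > 0")
  if (any(L < 0)) stop("L must be >= 0")
  L^2 / G
}

#' Speedup and efficiency metrics
#'
#' `T_p` is the slowest worker's time; speedup `S_p = T_s / T_p` and
#' efficiency `E_p = S_p / p`.
#'
#' @param T_s Best single-worker time.
#' @param per_worker_times Wall time of each worker.
#' @return A list of class `run_metrics` with `T_s`, `T_p`, `p`, `S_p`,
#'   `E_p`, `per_worker_times`.
#' @export
parallel_metrics <- function(T_s, per_worker_times) {
  if (length(per_worker_times) == 0) stop("empty per-worker time list")
  if (any(c(T_s, per_worker_times) <= 0)) stop("times must be > 0")
  p <- length(per_worker_times)
  T_p <- max(per_worker_times)
  S_p <- T_s / T_p
  structure(list(T_s = T_s, T_p = T_p, p = p, S_p = S_p, E_p = S_p / p,
                 per_worker_times = per_worker_times),
            class = "run_metrics")
}

#' @export
print.run_metrics <- function(x, ...) {
  cat(sprintf("<run_metrics> p=%d: T_s=%.3f, T_p=%.3f, S_p=%.2f, E_p=%.2f\n",
              x$p, x$T_s, x$T_p, x$S_p, x$E_p))
  invisible(x)
}

# Simulate the pull-queue assignment of work units to p workers from
# measured unit durations: static range i goes to worker i; each batch goes
# to the earliest-finishing worker. Returns per-worker busy times.
simulate_pull_queue <- function(static_times, batch_times, p) {
  busy <- numeric(p)
  if (length(static_times) > 0)
    busy[seq_along(static_times)] <- static_times
  for (b in batch_times) {
    w <- which.min(busy)
    busy[w] <- busy[w] + b
  }
  busy
}

#' Execute a distribution plan over a local worker pool
#'
#' Each worker consumes its static byte range, then workers pull dynamic
#' batches from a shared queue in file order (fork-based pool; with
#' `p = 1` execution is plain sequential). Every record is mapped exactly
#' once and results are re-ordered by input record index, so the output is
#' independent of scheduling. Per-worker times are reconstructed from the
#' measured per-unit wall times under the pull-queue assignment.
#'
#' @param plan A [make_ilb_plan()] plan.
#' @param mapper Function applied to one [seq_record()]; its return values
#'   are collected.
#' @param p Worker count (defaults to the plan's).
#' @return A list with `results` (in input record order) and `metrics`
#'   (a [parallel_metrics()] object).
#' @export
run_parallel <- function(plan, mapper, p = plan$p) {
  path <- plan$path
  heads <- plan$record_offsets[-length(plan$record_offsets)]
  run_unit_range <- function(u) {
    t0 <- proc.time()[["elapsed"]]
    recs <- read_fastq_range(path, u[1], u[2])
    idx <- match(vapply(recs, `[[`, 0, "offset"), heads)
    out <- lapply(recs, mapper)
    list(idx = idx, out = out,
         elapsed = proc.time()[["elapsed"]] - t0)
  }
  run_unit_batch <- function(u) {
    t0 <- proc.time()[["elapsed"]]
    idx <- seq.int(u[1], u[2])
    recs <- read_fastq_range(path, heads[u[1]],
                             plan$record_offsets[u[2] + 1L])
    out <- lapply(recs, mapper)
    list(idx = idx, out = out,
         elapsed = proc.time()[["elapsed"]] - t0)
  }
  sr <- plan$static_ranges
  static_units <- lapply(seq_len(nrow(sr)),
                         function(w) c(sr$start[w], sr$end[w]))
  db <- plan$dynamic_batches
  batch_units <- lapply(seq_len(nrow(db)),
                        function(w) c(db$first[w], db$last[w]))
  if (p == 1) {
    static_res <- lapply(static_units, run_unit_range)
    batch_res <- lapply(batch_units, run_unit_batch)
  } else {
    static_res <- parallel::mclapply(static_units, run_unit_range,
                                     mc.cores = p)
    # preschedule=FALSE: a fresh task is launched whenever a slot frees --
    # the pull-queue semantics of dynamic batch distribution
    batch_res <- parallel::mclapply(batch_units, run_unit_batch,
                                    mc.cores = p, mc.preschedule = FALSE)
  }
  all_res <- c(static_res, batch_res)
  for (r in all_res)
    if (inherits(r, "try-error") || is.null(r$idx))
      stop("worker failed: ", conditionMessage(attr(r, "condition")))
  idx <- unlist(lapply(all_res, `[[`, "idx"))
  if (length(idx) != plan$n_records || anyDuplicated(idx) ||
      (plan$n_records > 0 && !setequal(idx, seq_len(plan$n_records))))
    stop("coverage violation: records processed ", length(idx),
         " times over ", plan$n_records, " records")
  results <- vector("list", plan$n_records)
  results[idx] <- unlist(lapply(all_res, `[[`, "out"), recursive = FALSE)
  static_times <- vapply(static_res, `[[`, 0, "elapsed")
  batch_times <- vapply(batch_res, `[[`, 0, "elapsed")
  total <- sum(static_times, batch_times)
  eps <- 1e-9
  busy <- simulate_pull_queue(static_times, batch_times, p) + eps
  metrics <- parallel_metrics(total + eps, busy)
  list(results = results, metrics = metrics)
}

#' Map a FASTQ file against a reference and write SAM
#'
#' The high-level driver: builds (or reuses) the RHT, makes an ILB
#' distribution plan, maps every read over the worker pool and writes a
#' deterministic SAM file sorted by input read index.
#'
#' @param reference A [seq_record()] or path to a FASTA file (first record
#'   used).
#' @param reads_path Path to a 4-line FASTQ file.
#' @param out_sam Output SAM path, or `NULL` to skip writing.
#' @param p Worker count.
#' @param alpha,bs ILB parameters (see [make_ilb_plan()]).
#' @param index_params An [index_params()] object.
#' @param map_params A [map_params()] object.
#' @param rht Optional prebuilt [build_rht()] index.
#' @param dp_log Optional DP audit environment (forces sequential
#'   execution so the log is complete).
#' @return A list with `mapped` (list of [map_read()] results), `sam`
#'   (records), `plan`, `metrics`.
#' @export
align_file <- function(reference, reads_path, out_sam = NULL, p = 1L,
                       alpha = 0.8, bs = 128L,
                       index_params = rhtmap::index_params(),
                       map_params = rhtmap::map_params(), rht = NULL,
                       dp_log = NULL) {
  if (is.character(reference)) reference <- read_fasta(reference)[[1]]
  if (is.null(rht)) rht <- build_rht(reference, index_params)
  plan <- make_ilb_plan(reads_path, p, alpha = alpha, bs = bs)
  mapper <- function(rec) map_read(rht, reference, rec, map_params,
                                   dp_log = dp_log)
  run <- run_parallel(plan, mapper, p = if (is.null(dp_log)) p else 1L)
  sam <- lapply(seq_along(run$results), function(w)
    mapped_read_to_sam(run$results[[w]], rht$ref_name, index = w))
  if (!is.null(out_sam)) write_sam(sam, reference, out_sam)
  list(mapped = run$results, sam = sam, plan = plan, metrics = run$metrics)
}
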