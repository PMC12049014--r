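---
title: "Mapping noisy long reads with a Regional Hash Table"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping noisy long reads with a Regional Hash Table}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhtmap)
```

## The problem

Single-molecule long-read sequencing (PacBio CLR and similar chemistries)
produces reads of kilobase length with error rates around 15%, dominated by
insertions. Mapping such reads needs a seeding strategy robust to dense
errors and a base-level aligner whose gap model tolerates long indels.
`rhtmap` implements the full path from FASTQ to SAM: a windowed k-mer index
over the reference, mid-read seeding, candidate-region selection, exact
global alignment under a 2-piece affine gap model, and work-distribution
machinery for sharding the input across workers.

## The Regional Hash Table

The reference is cut into overlapping windows of length `L_win` (default
2048 bp) starting every `L_win/2` bp, so every position is covered by two
windows and a read of up to `L_win/2` bp always fits completely inside at
least one window. Within each window, k-mers are extracted every `k` bases
(non-overlapping) and stored in CSR form: `pointer_list[code]` gives the
offset into `window_list` of the first window containing the k-mer with
that 2-bit code, `pointer_list[code + 1]` the end. Duplicate occurrences of
a k-mer inside one window are retained, so query tallies count occurrences
rather than mere presence.

The dense PointerList has `4^k + 1` entries, which caps `k` at 13
(~268 MB of 32-bit offsets); `index_params()` rejects larger `k`. The
default `k = 13` sits in the middle of the practical 11–15 range: long
enough that a random 100 kb reference contains almost no spurious 13-mer
collisions, short enough that a 15%-error read still retains many exact
k-mers. Trailing windows are clamped to the reference end and kept (every
base stays covered by at least one window); windows shorter than `k` are
dropped since they cannot host a k-mer.

## Seeding and candidate selection

One seed per read: the centered `min(L_win/2, read length)` bases. Seed
k-mers are taken at step 1 — on the read side sensitivity matters, since
only error-free k-mers that also land on the reference's step-`k` grid can
hit the index. With sub/ins/del rates of 0.02/0.09/0.04, a grid k-mer
survives in the read with probability about `0.85^13 ≈ 0.12`, so a 1024 bp
seed overlapping ~78 grid k-mers yields roughly nine expected hits in its
true window, while random windows almost never reach two. The `N_top`
(default 5) windows by hit count, extended by `L_ext` (default 400) bp per
side and clamped, become candidate regions. Both the read and its reverse
complement are seeded independently; all candidates from both orientations
go to alignment and the global best wins.

## Base-level alignment

Scoring uses match/mismatch `(+2, -4)` and a 2-piece affine gap cost

```
cost(g) = min(p_o + g * p_e,  p_o' + g * p_e')   with (4, 2) and (24, 1),
```

the conventional parameterization for SMRT data: the second piece takes
over at `g = 20`, so long insertions are charged at slope 1 instead of 2.
Five matrices are filled — `H` plus gap matrices `E/F` (first piece) and
`E2/F2` (second piece). `H`'s maximization runs over all five terms: with
only the first-piece matrices in the max, the stated two-piece cost is
unattainable (a 30-gap would cost 64 instead of 54). The 3-term variant is
kept behind `strict_eq1 = TRUE` for comparison, and a test demonstrates
exactly this discrepancy.

Boundary conditions: `H(0,0) = 0`, `H(i,0) = -cost(i)`, `H(0,j) = -cost(j)`;
gap cells that cannot be reached hold a `neg_inf` sentinel chosen so that
repeated subtraction cannot underflow the integer score type. Filling the
boundary gap cells through the ordinary recurrences reproduces exactly
`-cost(·)` in `H`, so no special casing is needed beyond the origin.

Two fill orders produce identical matrices:

* `align_rowcol()` — row-by-row, the reference implementation playing the
  Smith-Waterman-Gotoh validation role;
* `align_antidiag()` — by anti-diagonals under `r = i + j`, `t = i`. Cells
  of one anti-diagonal are mutually independent; the `(r-1, t-1)` and
  `(r-2, t-1)` neighbours are brought into elementwise position by a
  one-slot lane shift of the contiguous per-diagonal buffer (`lane_shift()`
  is the exported abstract form of that SIMD-style shift; the vacated slot
  is filled with the sentinel, not 0, because the scores here are not
  offset-packed).

Traceback runs over the stored matrices with deterministic tie-breaking
(M over D over I; gap extension over re-opening). `score_cigar()`
recomputes the score of any emitted path from first principles and is
asserted against the DP score throughout the tests. Scores are integers,
so "exact agreement" is well defined. Equivalence of the two layouts is
tested exhaustively on all sequence pairs up to length 4 over `{A, C}`,
on seeded random pairs up to length 64 under randomized schemes, and both
are checked against an O(n³) oracle that replaces the gap matrices with
explicit enumeration of every gap length.

## Per-read alignment

Within each candidate region, all exact shared k-mers (step 1 on both
sides) become anchors; a DAG over collinear anchors (edge `u -> v` iff `v`
starts at least `k` after `u` on both sequences, edge cost = gap cost of
the diagonal shift) is solved by DP for the maximum-score path. This
sparse-chaining construction is a standard reading of "optimal path
through a DAG of matches" — the source material leaves the graph
unspecified, so it is isolated in `chain_anchors()` where it could be
swapped. Ties prefer more anchors, then the chain starting leftmost on the
reference, keeping output deterministic.

Anchors become exact M runs; inter-anchor pairs, the head pair and the
tail pair are aligned globally with `align_antidiag()` and concatenated.
Because the region is a deliberate superset of the read's true span
(`L_ext` padding), leading/trailing D runs are *trimmed*: removed from the
CIGAR with their gap cost added back and the start coordinate advanced.
This converts the region-global alignment into a read-glocal one without
distorting candidate comparison. A consequence used by the tests: the
reported score always equals `score_cigar()` of the emitted CIGAR against
the trimmed target interval.

MAPQ is the score gap between the best and second-best candidate, capped
at 60 — a pragmatic invention, as the upstream method defines none.

## Work distribution

Three strategies, all operating on byte offsets of strict 4-line FASTQ
records:

* **SSD** — `static_split()` cuts the file into `p` equal byte ranges
  (`floor(V*i/p)` boundaries); `refine_split()` advances each boundary to
  the next record head (`locate_record_head()` guards against `@` inside
  quality strings by validating the full 4-line structure) and each range
  ends where the next begins.
* **DSD** — consecutive batches of `bs` records served from a shared
  queue.
* **ILB** — `make_ilb_plan()`: the first `floor(alpha * n)` records
  (default `alpha = 0.8`, read as a fraction — the only reading consistent
  with "the remaining `1 - alpha`") are SSD-split by bytes then refined;
  the rest is batched with `bs = 128` by default.

`run_parallel()` executes a plan on a fork-based local pool:
`p` static-range tasks, then dynamic batches with one task launched
whenever a slot frees — pull-queue semantics without a message-passing
runtime, which is out of scope here. Results are re-ordered by input
record index and the SAM writer additionally sorts by that index, so
output bytes are invariant to `p`, `alpha`, `bs` and scheduling (asserted
across the full grid in the tests). Per-worker times are reconstructed by
replaying the measured per-unit wall times through the pull-queue
assignment (static range *i* to worker *i*, each batch to the
earliest-finishing worker); `parallel_metrics()` then reports
`S_p = T_s / T_p` with `T_p` the slowest worker and `E_p = S_p / p`.
Wall-clock speedups are reported, never asserted: on shared hardware they
measure the machine, not the algorithm.

The host/device cost model is purely analytic: `model_runtime()` evaluates
the closed forms `2*O_c + (D_send + D_recv)/G + T_cpu` (blocking), the
same with `T_dev` (non-blocking), and `O_c + T_cpu` with
`T_cpu = T_send + T_dev + O_c + T_recv` (NESD-s; NESD-l evaluates the same
form under the primed, uniformly larger quantities). `transmission_time()`
encodes the quadratic law `L²/G` for DP-matrix transfer — the reason
short reads belong on the accelerator: `nesd_partition()` splits records
at 1024 bp for that purpose.

## The simulator

`simulate_reference()` draws i.i.d. uniform bases. `simulate_reads()`
draws an origin uniformly, a length from a truncated normal, then applies
a per-base channel: substitution 0.02 (to a different base), insertion
0.09 (a random base placed before the original, which is kept), deletion
0.04 — ~15% total, insertion-dominated, emulating a CLR error profile.
Half the reads are reverse-complemented. Ground truth (origin interval,
strand, per-type error counts) is recorded for every read.

Read lengths default to mean 2000, sd 400, clamped to [200, 2600] bp. The
upper clamp is a design constraint, not a convenience: a candidate region
is one window plus two extensions (2048 + 800 = 2848 bp), and the
single-mid-seed mapper can only recover a read's full span if the read
fits inside one region. Real CLR libraries contain much longer reads;
mapping those would require multi-seed or split-candidate handling, which
is explicitly out of scope, so passing tests here say nothing about reads
longer than a window.

What the simulator does *not* model: non-uniform base composition and
genomic repeats (a uniform random 100 kb reference is far easier to seed
than a repetitive genome), context-dependent and homopolymer errors,
chimeras, and quality-value information (qualities are constant and never
read). Recall numbers on this generator are therefore upper bounds on
real-data behaviour.

## Problem sizes and numerical choices

The validation dataset is a 100 kb reference with 200 noisy reads —
roughly 400 kb of read bases and twenty-thousand-odd DP invocations per
run, enough to exercise every candidate/anchor/piece code path while a
full check (every anti-diagonal DP score re-verified against the
row-column implementation) stays in the minutes range. Unit tests use
k ≤ 5 toy indexes whose CSR content can be enumerated by hand, and
20–30 kb references for mapper-level properties.

Degenerate inputs are pinned down by tests: empty sequences (score
`-cost(n)` against a pure gap, 0 against nothing), all-`N` seeds (no
candidates, read unmapped), k-mers containing `N` (excluded from both
index and anchors, `N` scores as mismatch in DP), workers receiving zero
records, and `alpha` at both endpoints.

## Known limitations

* Single-contig references (or caller-side concatenation).
* One primary alignment per read; no secondary/supplementary records, no
  split or chimeric alignment.
* The candidate-region cap on read length discussed above.
* Banding is not used in any oracle comparison; full matrices are stored,
  so pathological inputs (two unrelated multi-kilobase sequences with an
  empty chain) transiently allocate five `L_t × L_q` integer matrices.
* The worker pool measures distribution semantics, not hardware speedups;
  published multi-node scaling numbers are not reproducible in-process
  and are not asserted anywhere.
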