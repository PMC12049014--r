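# FASTA / FASTQ / SAM input-output.
#
# FASTQ is treated as strict 4-line records so that byte offsets of record
# heads are well defined; that is what the byte-range scheduler relies on.
# Internal coordinates are 0-based half-open; SAM POS is emitted 1-based.

#' Construct a sequence record
#'
#' A lightweight carrier for one sequence: id, uppercased sequence over
#' `{A,C,G,T,N}`, optional quality string and optional byte offset of the
#' record head in its source file.
#'
#' @param id Record identifier (first whitespace-separated token of a header).
#' @param seq Sequence string; uppercased, and any symbol outside
#'   `{A,C,G,T,N}` replaced by `N` with a warning.
#' @param qual Optional quality string of the same length as `seq`.
#' @param offset Optional 0-based byte offset of the record head.
#' @return A list of class `seq_record`.
#' @export
seq_record <- function(id, seq, qual = NULL, offset = NULL) {
  seq <- normalize_sequence(seq)
  if (!is.null(qual) && nchar(qual) != nchar(seq))
    stop("quality length (", nchar(qual), ") != sequence length (",
         nchar(seq), ") for record '", id, "'")
  structure(list(id = id, seq = seq, qual = qual, offset = offset),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %d bp%s\n", x$id, nchar(x$seq),
              if (is.null(x$qual)) "" else " (+qual)"))
  invisible(x)
}

normalize_sequence <- function(seq) {
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    warning(sum(nchar(bad)), " non-ACGTN symbol(s) replaced by N",
            call. = FALSE)
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  seq
}

#' Read a FASTA file
#'
#' Wrapped sequence lines are concatenated; sequences are uppercased and
#' non-ACGTN symbols become `N` (with a warning). Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A list of [seq_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  unname(Map(function(id, s) seq_record(id, s), ids, seqs))
}

#' Write a FASTA file
#'
#' @param records List of [seq_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "seq"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Byte offsets of every FASTQ record head, plus the file size as a final
# element. Validates the strict 4-line structure on the way.
fastq_offsets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0) return(0L)
  if (n %% 4 != 0)
    stop("malformed FASTQ (line count ", n, " not a multiple of 4): ", path)
  heads <- seq(1L, n, by = 4L)
  if (any(substr(lines[heads], 1L, 1L) != "@"))
    stop("malformed FASTQ (header line without '@'): ", path)
  if (any(substr(lines[heads + 2L], 1L, 1L) != "+"))
    stop("malformed FASTQ (separator line without '+'): ", path)
  if (any(nchar(lines[heads + 1L]) != nchar(lines[heads + 3L])))
    stop("malformed FASTQ (quality length != sequence length): ", path)
  starts <- c(0, cumsum(nchar(lines, type = "bytes") + 1L))
  as.numeric(c(starts[heads], file.size(path)))
}

#' Locate the next FASTQ record head
#'
#' Returns the smallest record-head byte offset `>= offset`, or the file size
#' when no head follows. A record head is an `@` line whose record satisfies
#' the strict 4-line FASTQ structure (the `+` separator two lines later and a
#' quality line of the same length as the sequence line), which guards
#' against `@` characters inside quality strings.
#'
#' @param path Path to a 4-line FASTQ file.
#' @param offset Byte offset in `[0, file size]`.
#' @return A byte offset (numeric scalar).
#' @export
locate_record_head <- function(path, offset) {
  sz <- file.size(path)
  if (offset < 0 || offset > sz)
    stop("offset ", offset, " outside [0, ", sz, "]")
  offs <- fastq_offsets(path)
  heads <- offs[-length(offs)]
  nxt <- heads[heads >= offset]
  if (length(nxt) == 0) return(sz)
  nxt[1]
}

parse_fastq_lines <- function(lines, head_offsets = NULL) {
  n <- length(lines)
  if (n %% 4 != 0) stop("truncated FASTQ record (", n, " lines)")
  heads <- seq_len(n %/% 4) * 4L - 3L
  out <- vector("list", length(heads))
  for (w in seq_along(heads)) {
    h <- heads[w]
    id <- sub("\\s.*$", "", sub("^@", "", lines[h]))
    out[[w]] <- seq_record(id, lines[h + 1L], qual = lines[h + 3L],
                           offset = if (is.null(head_offsets)) NULL
                                    else head_offsets[w])
  }
  out
}

#' Read a FASTQ file
#'
#' Strict 4-line records; records carry their source byte offset.
#'
#' @param path Path to a FASTQ file.
#' @return A list of [seq_record()] objects.
#' @export
read_fastq <- function(path) {
  offs <- fastq_offsets(path)
  lines <- readLines(path)
  parse_fastq_lines(lines, head_offsets = offs[-length(offs)])
}

#' Read the FASTQ records whose heads lie in a byte range
#'
#' `start` and `end` must each coincide with a record head or the end of
#' file; exactly the records whose heads lie in `[start, end)` are returned,
#' each carrying its `source_offset`.
#'
#' @param path Path to a 4-line FASTQ file.
#' @param start,end Byte range (half-open).
#' @return A list of [seq_record()] objects (possibly empty).
#' @export
read_fastq_range <- function(path, start, end) {
  offs <- fastq_offsets(path)
  sz <- offs[length(offs)]
  if (!(start %in% offs))
    stop("range start ", start, " is not a record head")
  if (!(end %in% offs))
    stop("range end ", end, " is not a record head or end of file")
  if (start >= end) return(list())
  heads <- offs[-length(offs)]
  keep <- heads >= start & heads < end
  if (!any(keep)) return(list())
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, where = start)
  raw <- readBin(con, "raw", n = end - start)
  lines <- strsplit(rawToChar(raw), "\n", fixed = TRUE)[[1]]
  parse_fastq_lines(lines, head_offsets = heads[keep])
}

#' Write a FASTQ file
#'
#' @param records List of [seq_record()] objects; missing qualities are
#'   written as `I` runs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    qual <- if (is.null(r$qual)) strrep("I", nchar(r$seq)) else r$qual
    c(paste0("@", r$id), r$seq, "+", qual)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a SAM record
#'
#' @param qname Read name.
#' @param flag SAM flag bitfield (`0x4` unmapped, `0x10` reverse strand).
#' @param rname Reference name (`*` for unmapped).
#' @param pos 1-based leftmost reference coordinate (0 for unmapped).
#' @param mapq Mapping quality in `[0, 60]`.
#' @param cigar CIGAR string (`*` for unmapped).
#' @param seq Read sequence, oriented as aligned.
#' @param qual Quality string or `*`.
#' @param tags Character vector of preformatted optional tags.
#' @param index Input read index, used as the output sort key so SAM output
#'   is independent of worker scheduling.
#' @return A list of class `sam_record`.
#' @export
sam_record <- function(qname, flag, rname, pos, mapq, cigar, seq, qual = "*",
                       tags = character(), index = NA_integer_) {
  rec <- structure(list(qname = qname, flag = as.integer(flag),
                        rname = rname, pos = as.integer(pos),
                        mapq = as.integer(mapq), cigar = cigar, seq = seq,
                        qual = qual, tags = tags, index = index),
                   class = "sam_record")
  validate_sam_record(rec)
  rec
}

validate_sam_record <- function(rec) {
  unmapped <- bitwAnd(rec$flag, 4L) != 0L
  if (unmapped) {
    if (rec$rname != "*")
      stop("unmapped record '", rec$qname, "' must have rname '*'")
    return(invisible(rec))
  }
  if (rec$pos < 1L)
    stop("mapped record '", rec$qname, "' has pos < 1")
  if (rec$mapq < 0L || rec$mapq > 60L)
    stop("mapq outside [0, 60] for '", rec$qname, "'")
  qlen <- cigar_query_length(parse_cigar(rec$cigar))
  if (qlen != nchar(rec$seq))
    stop("CIGAR consumes ", qlen, " query bases but seq has ",
         nchar(rec$seq), " for '", rec$qname, "'")
  if (rec$qual != "*" && nchar(rec$qual) != nchar(rec$seq))
    stop("qual length != seq length for '", rec$qname, "'")
  invisible(rec)
}

#' Write a SAM file
#'
#' Emits `@HD`, `@SQ` and `@PG` header lines followed by the records sorted
#' by their input `index`, so the output does not depend on the order in
#' which workers produced the records.
#'
#' @param records List of [sam_record()] objects.
#' @param ref A [seq_record()] (or a list with `id` and `seq`) providing the
#'   `@SQ` name and length.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, ref, path) {
  for (rec in records) validate_sam_record(rec)
  idx <- vapply(records, function(r) as.numeric(r$index), 0)
  if (anyNA(idx)) idx[is.na(idx)] <- seq_len(sum(is.na(idx))) + max(idx, 0, na.rm = TRUE)
  records <- records[order(idx)]
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", ref$id, nchar(ref$seq)),
           sprintf("@PG\tID:rhtmap\tPN:rhtmap\tVN:%s",
                   as.character(utils::packageVersion("rhtmap"))))
  body <- vapply(records, function(r) {
    fields <- c(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, "*", 0L, 0L,
                r$seq, r$qual)
    paste(c(fields, r$tags), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Reverse-complement a sequence string
#'
#' @param seq Sequence over `{A,C,G,T,N}`.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  if (nchar(seq) == 0) return(seq)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}
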