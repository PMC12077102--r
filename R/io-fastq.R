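# FASTQ and FASTA I/O.
#
# Reads are carried as a "read table": a data.table with columns
#   id      read identifier (first whitespace token, leading '@' stripped)
#   seq     uppercase DNA string
#   qual    Phred+33 quality string (same length as seq), or NA for FASTA
#   mate    1L/2L for paired input, NA otherwise
#   pair_id id with a trailing "/1" "/2" or " 1" " 2" tag removed
# Contigs and genomes are carried as named character vectors (ACGTN).

# open a connection, transparently handling gzip via magic bytes
open_maybe_gz <- function(path) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = 2L)
  close(con)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    gzfile(path, "rt")
  } else {
    file(path, "rt")
  }
}

strip_mate_tag <- function(id) sub("[/_.]([12])$", "", id)

parse_fastq_lines <- function(lines, path) {
  n <- length(lines)
  if (n == 0L) {
    return(data.table(id = character(), seq = character(), qual = character()))
  }
  if (n %% 4L != 0L) {
    stop(sprintf("truncated FASTQ record %d in '%s' (file has %d lines, not a multiple of 4)",
                 n %/% 4L + 1L, path, n), call. = FALSE)
  }
  hdr <- lines[seq(1L, n, by = 4L)]
  seq <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ record %d in '%s' (missing '@' or '+' line)",
                 bad[1], path), call. = FALSE)
  }
  bad <- which(nchar(seq) == 0L | nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ record %d in '%s' (empty sequence or quality length mismatch)",
                 bad[1], path), call. = FALSE)
  }
  # Phred+33 sanity: printable range '!'..'J' (Q0..Q41); anything above
  # indicates Phred+64, which is rejected rather than guessed.
  codes <- utf8ToInt(paste(qual, collapse = ""))
  if (length(codes) && (min(codes) < 33L || max(codes) > 74L)) {
    stop(sprintf("quality string outside Phred+33 range in '%s'; other encodings are not supported",
                 path), call. = FALSE)
  }
  id <- sub("^@", "", vapply(strsplit(hdr, "[ \t]"), `[[`, "", 1L))
  data.table(id = id, seq = toupper(seq), qual = qual)
}

#' Read FASTQ files (Phred+33), optionally as a synchronized pair
#'
#' @param path path to a FASTQ file (gzip auto-detected by magic bytes).
#' @param path2 optional mate-2 file; when given, the two files must be
#'   record-synchronized and pairing metadata (`mate`, `pair_id`) is filled.
#' @return a read table (`data.table` with columns `id`, `seq`, `qual`,
#'   `mate`, `pair_id`).
#' @export
read_fastq <- function(path, path2 = NULL) {
  con <- open_maybe_gz(path)
  on.exit(close(con), add = TRUE)
  r1 <- parse_fastq_lines(readLines(con), path)
  if (is.null(path2)) {
    r1[, `:=`(mate = NA_integer_, pair_id = NA_character_)]
    return(r1[])
  }
  con2 <- open_maybe_gz(path2)
  on.exit(close(con2), add = TRUE)
  r2 <- parse_fastq_lines(readLines(con2), path2)
  if (nrow(r1) != nrow(r2)) {
    stop(sprintf("desynchronized pairs: '%s' has %d records, '%s' has %d",
                 path, nrow(r1), path2, nrow(r2)), call. = FALSE)
  }
  p1 <- strip_mate_tag(r1$id)
  p2 <- strip_mate_tag(r2$id)
  bad <- which(p1 != p2)
  if (length(bad)) {
    stop(sprintf("desynchronized pairs at record %d: '%s' vs '%s'",
                 bad[1], r1$id[bad[1]], r2$id[bad[1]]), call. = FALSE)
  }
  r1[, `:=`(mate = 1L, pair_id = p1)]
  r2[, `:=`(mate = 2L, pair_id = p2)]
  rbindlist(list(r1, r2))
}

#' Write a read table to FASTQ
#'
#' @param reads a read table (see [read_fastq()]).
#' @param path output file; `.gz` suffix triggers gzip compression.
#' @param path2 optional mate-2 output; when given, mate-1 records go to
#'   `path` and mate-2 records to `path2`.
#' @export
write_fastq <- function(reads, path, path2 = NULL) {
  emit <- function(dt, p) {
    con <- if (grepl("\\.gz$", p)) gzfile(p, "wt") else file(p, "wt")
    on.exit(close(con))
    if (nrow(dt)) {
      writeLines(paste0("@", dt$id, "\n", dt$seq, "\n+\n", dt$qual), con, sep = "\n")
    }
    invisible(NULL)
  }
  if (is.null(path2)) {
    emit(reads, path)
  } else {
    emit(reads[reads$mate %in% 1L, ], path)
    emit(reads[reads$mate %in% 2L, ], path2)
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file (gzip auto-detected by [Biostrings::readDNAStringSet()]).
#' @return named uppercase character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- vapply(strsplit(names(x), "[ \t]"), `[[`, "", 1L)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
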