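# Tabular evidence formats: classifier hit TSV (Centrifuge dialect), m8
# alignment tables (BLAST/PLAST tabular), jgi depth tables (MetaBAT2
# jgi_summarize_bam_contig_depths dialect), marker-call TSV (Metaxa2-style)
# and bin-membership TSV.
#
# Parsers never silently drop rows: rows failing numeric conversion are
# counted in attr(x, "n_rejected") and reported with a warning.

CLASSIFIER_COLS <- c("readID", "seqID", "taxID", "score", "2ndBestScore",
                     "hitLength", "queryLength", "numMatches")
M8_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
             "qstart", "qend", "sstart", "send", "evalue", "bitscore")

split_tsv_lines <- function(lines, ncol_expected, path, what) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < ncol_expected)
  if (length(bad)) {
    stop(sprintf("%s format error in '%s': line %d has %d column(s), expected >= %d",
                 what, path, bad[1], nf[bad[1]], ncol_expected), call. = FALSE)
  }
  fields
}

finish_hits <- function(dt, numeric_cols, path) {
  ok <- rep(TRUE, nrow(dt))
  for (cn in numeric_cols) {
    v <- suppressWarnings(as.numeric(dt[[cn]]))
    ok <- ok & !is.na(v)
    set(dt, j = cn, value = v)
  }
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warning(sprintf("rejected %d row(s) of '%s' failing numeric conversion",
                    n_rejected, path), call. = FALSE)
  }
  out <- dt[ok]
  setattr(out, "n_rejected", n_rejected)
  out
}

#' Read classifier or m8 alignment hit tables
#'
#' The `classifier` dialect is a header-bearing TSV in the Centrifuge output
#' layout (`readID seqID taxID score 2ndBestScore hitLength queryLength
#' numMatches`). The `m8` dialect is the headerless 12(+1)-column tabular
#' alignment format shared by BLAST `-outfmt 6` and PLAST; an optional 13th
#' column is taken as the subject taxid. Coordinates stay 1-based inclusive
#' at the I/O boundary; `q_start <= q_end` is enforced by swapping (the
#' subject pair is swapped along with it).
#'
#' @param path TSV file (gzip auto-detected).
#' @param dialect `"classifier"` or `"m8"`.
#' @return a `data.table` of [classifier hits][classifier_hits] or
#'   alignment hits; rejected-row count in `attr(x, "n_rejected")`.
#' @export
read_tabular_hits <- function(path, dialect = c("classifier", "m8")) {
  dialect <- match.arg(dialect)
  con <- open_maybe_gz(path)
  on.exit(close(con))
  lines <- readLines(con)
  if (dialect == "classifier") {
    if (length(lines) == 0L) {
      stop(sprintf("classifier table '%s' is empty (header line required)", path),
           call. = FALSE)
    }
    hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (!identical(hdr[seq_along(CLASSIFIER_COLS)], CLASSIFIER_COLS)) {
      stop(sprintf("classifier table '%s' has unexpected header: %s",
                   path, paste(hdr, collapse = " ")), call. = FALSE)
    }
    lines <- lines[-1]
    if (!length(lines)) return(empty_classifier_hits())
    fields <- split_tsv_lines(lines, length(CLASSIFIER_COLS), path, "classifier")
    m <- matrix(unlist(lapply(fields, `[`, seq_len(8L))), ncol = 8L, byrow = TRUE)
    dt <- data.table(query_id = m[, 1], ref_id = m[, 2], taxid = m[, 3],
                     score = m[, 4], second_best = m[, 5], hit_length = m[, 6],
                     query_length = m[, 7], num_matches = m[, 8])
    out <- finish_hits(dt, c("taxid", "score", "second_best", "hit_length",
                             "query_length", "num_matches"), path)
    out[, `:=`(taxid = as.integer(taxid), hit_length = as.integer(hit_length),
               query_length = as.integer(query_length),
               num_matches = as.integer(num_matches))]
    return(out[])
  }
  if (!length(lines)) return(empty_alignment_hits())
  fields <- split_tsv_lines(lines, 12L, path, "m8")
  has_tax <- lengths(fields) >= 13L
  m <- matrix(unlist(lapply(fields, `[`, seq_len(12L))), ncol = 12L, byrow = TRUE)
  dt <- data.table(query_id = m[, 1], subject_id = m[, 2], pident = m[, 3],
                   aln_length = m[, 4], mismatch = m[, 5], gapopen = m[, 6],
                   q_start = m[, 7], q_end = m[, 8], s_start = m[, 9],
                   s_end = m[, 10], evalue = m[, 11], bitscore = m[, 12],
                   subject_taxid = ifelse(has_tax,
                                          vapply(fields, function(f) if (length(f) >= 13L) f[13] else NA_character_, ""),
                                          NA_character_))
  out <- finish_hits(dt, c("pident", "aln_length", "mismatch", "gapopen",
                           "q_start", "q_end", "s_start", "s_end",
                           "evalue", "bitscore"), path)
  out[, subject_taxid := suppressWarnings(as.integer(subject_taxid))]
  # normalize query orientation
  flip <- out$q_start > out$q_end
  if (any(flip)) {
    qs <- out$q_start[flip]; out[flip, q_start := q_end]; out[flip, q_end := qs]
    ss <- out$s_start[flip]; out[flip, s_start := s_end]; out[flip, s_end := ss]
  }
  out[, `:=`(aln_length = as.integer(aln_length),
             q_start = as.integer(q_start), q_end = as.integer(q_end),
             s_start = as.integer(s_start), s_end = as.integer(s_end))]
  out[]
}

empty_classifier_hits <- function() {
  data.table(query_id = character(), ref_id = character(), taxid = integer(),
             score = numeric(), second_best = numeric(), hit_length = integer(),
             query_length = integer(), num_matches = integer())
}

empty_alignment_hits <- function() {
  data.table(query_id = character(), subject_id = character(), pident = numeric(),
             aln_length = integer(), mismatch = numeric(), gapopen = numeric(),
             q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), evalue = numeric(), bitscore = numeric(),
             subject_taxid = integer())
}

#' Write classifier or m8 hit tables
#'
#' @param hits a hit table as returned by [read_tabular_hits()] (or built by
#'   [classify_with_index()] / the simulator).
#' @param path output TSV.
#' @param dialect `"classifier"` or `"m8"`.
#' @export
write_hits <- function(hits, path, dialect = c("classifier", "m8")) {
  dialect <- match.arg(dialect)
  if (dialect == "classifier") {
    out <- data.table(hits$query_id, hits$ref_id, hits$taxid, hits$score,
                      hits$second_best, hits$hit_length, hits$query_length,
                      hits$num_matches)
    setnames(out, CLASSIFIER_COLS)
    fwrite(out, path, sep = "\t", quote = FALSE, col.names = TRUE)
  } else {
    out <- data.table(hits$query_id, hits$subject_id, hits$pident,
                      hits$aln_length, hits$mismatch, hits$gapopen,
                      hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                      hits$evalue, hits$bitscore)
    if (!all(is.na(hits$subject_taxid))) out[, V13 := hits$subject_taxid]
    fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a jgi-style contig depth table
#'
#' Expects the MetaBAT2 `jgi_summarize_bam_contig_depths` layout: header
#' columns `contigName`, `contigLen`, `totalAvgDepth`, then per-sample
#' depth/variance pairs. `mean_depth` is taken from `totalAvgDepth`;
#' per-sample columns are preserved (attribute `samples`) for round-trip.
#'
#' @param path depth TSV.
#' @return `data.table` with `contig_id`, `contig_len`, `mean_depth`,
#'   `depth_var`.
#' @export
read_depth_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  req <- c("contigName", "contigLen", "totalAvgDepth")
  miss <- setdiff(req, names(dt))
  if (length(miss)) {
    stop(sprintf("depth table '%s' is missing required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(dt), req)
  var_cols <- grep("-var$", extra, value = TRUE)
  out <- data.table(contig_id = as.character(dt$contigName),
                    contig_len = as.integer(dt$contigLen),
                    mean_depth = as.numeric(dt$totalAvgDepth),
                    depth_var = if (length(var_cols)) as.numeric(dt[[var_cols[1]]]) else 0)
  if (any(out$mean_depth < 0, na.rm = TRUE)) {
    stop(sprintf("depth table '%s' contains negative depths", path), call. = FALSE)
  }
  if (length(extra)) setattr(out, "samples", dt[, extra, with = FALSE])
  out[]
}

#' Write a jgi-style contig depth table
#'
#' @param depth a depth table from [read_depth_table()] or [estimate_depth()].
#' @param path output TSV.
#' @export
write_depth_table <- function(depth, path) {
  out <- data.table(contigName = depth$contig_id, contigLen = depth$contig_len,
                    totalAvgDepth = depth$mean_depth)
  samples <- attr(depth, "samples")
  if (!is.null(samples)) {
    out <- cbind(out, samples)
  } else {
    out[, `:=`(sample1.bam = depth$mean_depth, `sample1.bam-var` = depth$depth_var)]
  }
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write marker-call tables (Metaxa2-style)
#'
#' TSV with header `contig_id marker pident aln_length taxon_label`, where
#' `marker` is one of `SSU`, `LSU`, `MITO` and `taxon_label` is a free-text
#' lineage string.
#'
#' @param path TSV file.
#' @return `data.table` of marker calls.
#' @export
read_marker_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("contig_id", "marker", "taxon_label")))
  req <- c("contig_id", "marker", "pident", "aln_length", "taxon_label")
  miss <- setdiff(req, names(dt))
  if (length(miss)) {
    stop(sprintf("marker table '%s' is missing column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(unique(dt$marker), c("SSU", "LSU", "MITO"))
  if (length(bad)) {
    stop(sprintf("marker table '%s' has unknown marker type(s): %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  }
  dt[, .(contig_id, marker, pident = as.numeric(pident),
         aln_length = as.integer(aln_length), taxon_label)]
}

#' @rdname read_marker_table
#' @param calls marker-call `data.table`.
#' @export
write_marker_table <- function(calls, path) {
  fwrite(calls[, .(contig_id, marker, pident, aln_length, taxon_label)],
         path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write bin membership tables
#'
#' TSV with header `contig_id bin_id reason`; binned contigs carry an empty
#' reason, rejected contigs carry one of the four reason codes.
#'
#' @param path TSV file.
#' @export
read_bin_membership <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              na.strings = NULL)
  req <- c("contig_id", "bin_id", "reason")
  miss <- setdiff(req, names(dt))
  if (length(miss)) {
    stop(sprintf("bin membership table '%s' is missing column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  dt[, req, with = FALSE]
}

#' @rdname read_bin_membership
#' @param membership membership `data.table` (`contig_id`, `bin_id`, `reason`).
#' @export
write_bin_membership <- function(membership, path) {
  fwrite(membership[, .(contig_id, bin_id, reason)], path, sep = "\t",
         quote = FALSE)
  invisible(path)
}
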