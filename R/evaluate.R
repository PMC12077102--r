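# Recovery and assembly metrics.
#
# Precision = TP / (TP + FP), Recall = TP / (TP + FN), computed at both
# contig-count and base-pair granularity (contig-level is the primary
# report). NG50/LG50 are the classic reference-relative contiguity
# metrics; genome fraction is the unioned share of reference bases
# recovered; weighted SCG completeness sums per-gene fractional
# completeness instead of counting presence/absence.

#' Precision and recall of a predicted contig set
#'
#' @param predicted ids predicted positive (e.g. binned contigs).
#' @param truth ids truly positive.
#' @param universe all ids under consideration; `predicted` and `truth`
#'   must be subsets.
#' @param weights optional named numeric weights (e.g. contig lengths) for
#'   the base-pair-granularity figures.
#' @return list with `precision`, `recall` (contig granularity; precision
#'   is `NA` when nothing is predicted), `precision_bp`, `recall_bp` (when
#'   weights given) and the confusion `counts` (TP/FP/FN/TN).
#' @export
precision_recall <- function(predicted, truth, universe, weights = NULL) {
  predicted <- unique(as.character(predicted))
  truth <- unique(as.character(truth))
  universe <- unique(as.character(universe))
  if (length(setdiff(predicted, universe)) || length(setdiff(truth, universe))) {
    stop("predicted and truth must be subsets of the universe", call. = FALSE)
  }
  tp <- intersect(predicted, truth)
  fp <- setdiff(predicted, truth)
  fn <- setdiff(truth, predicted)
  tn <- setdiff(universe, union(predicted, truth))
  counts <- c(TP = length(tp), FP = length(fp), FN = length(fn), TN = length(tn))
  out <- list(
    precision = if (length(predicted)) counts[["TP"]] / (counts[["TP"]] + counts[["FP"]]) else NA_real_,
    recall = if (length(truth)) counts[["TP"]] / (counts[["TP"]] + counts[["FN"]]) else 0,
    counts = counts)
  if (!is.null(weights)) {
    w <- function(ids) sum(weights[ids], na.rm = TRUE)
    out$precision_bp <- if (length(predicted)) w(tp) / (w(tp) + w(fp)) else NA_real_
    out$recall_bp <- if (length(truth)) w(tp) / (w(tp) + w(fn)) else 0
  }
  out
}

#' NG50 and LG50 assembly contiguity
#'
#' Contig lengths are sorted descending; NG50 is the length of the contig
#' at which the cumulative sum first reaches half the reference length,
#' LG50 its 1-based rank. Both are `NA` when the assembly total does not
#' reach half the reference.
#'
#' @param lengths contig lengths in bp.
#' @param ref_length reference genome length in bp (>= 1).
#' @return list with `ng50` and `lg50`.
#' @export
ng50_lg50 <- function(lengths, ref_length) {
  if (ref_length < 1) stop("ref_length must be >= 1", call. = FALSE)
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  if (!length(lengths) || sum(lengths) < ref_length / 2) {
    return(list(ng50 = NA_real_, lg50 = NA_integer_))
  }
  i <- which(cumsum(lengths) >= ref_length / 2)[1L]
  list(ng50 = lengths[i], lg50 = i)
}

#' Genome fraction recovered
#'
#' Percent of a source genome's bases covered by the truth intervals of
#' the given contigs; overlapping intervals are counted once.
#'
#' @param contig_ids recovered contig ids.
#' @param truth contig truth table (`contig_id`, `genome_id`, `start`,
#'   `end`).
#' @param genome_len reference genome length in bp.
#' @param genome_id optional restriction to one source genome.
#' @return percent in \[0, 100\].
#' @export
genome_fraction <- function(contig_ids, truth, genome_len, genome_id = NULL) {
  tr <- as.data.table(truth)
  missing_ids <- setdiff(contig_ids, tr$contig_id)
  if (length(missing_ids)) {
    stop(sprintf("contig(s) without a truth row: %s",
                 paste(head(missing_ids, 3L), collapse = ", ")), call. = FALSE)
  }
  tr <- tr[contig_id %in% contig_ids]
  if (!is.null(genome_id)) {
    gid <- genome_id
    tr <- tr[tr$genome_id == gid]
  }
  if (!nrow(tr)) return(0)
  covered <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(tr$start, tr$end))))
  100 * covered / genome_len
}

#' Weighted single-copy-gene completeness
#'
#' For each gene template, completeness is the best fraction of the
#' template recovered in any bin contig, found by local alignment with a
#' tolerance of one mismatch per 100 template bases; the weighted SCG
#' score is the sum of per-gene completeness fractions over all genes.
#'
#' @param bins named character vector of bin contigs.
#' @param templates named character vector of gene template sequences.
#' @param min_match minimum matched template bases for a local alignment to
#'   count as gene evidence (guards against spurious short local matches);
#'   capped at the template length.
#' @return list with `weighted_scg` (sum over genes) and `per_gene`
#'   completeness fractions.
#' @export
weighted_scg <- function(bins, templates, min_match = 100L) {
  if (!length(templates)) stop("empty template set", call. = FALSE)
  subjects <- Biostrings::DNAStringSet(bins)
  per_gene <- vapply(names(templates), function(g) {
    tmpl <- Biostrings::DNAString(templates[[g]])
    tlen <- length(tmpl)
    if (!length(subjects)) return(0)
    best <- 0
    for (i in seq_along(subjects)) {
      aln <- Biostrings::pairwiseAlignment(
        tmpl, subjects[[i]], type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -2, baseOnly = FALSE),
        gapOpening = 5, gapExtension = 2)
      matched <- Biostrings::nmatch(aln)
      aligned <- Biostrings::nchar(Biostrings::alignedPattern(aln))
      # near-exact: at most 1 mismatch/indel per 100 aligned template bases,
      # and a substantive anchor
      if (matched >= min(min_match, tlen) &&
          aligned - matched <= ceiling(aligned / 100)) {
        best <- max(best, matched / tlen)
      }
    }
    min(best, 1)
  }, 0)
  list(weighted_scg = sum(per_gene), per_gene = per_gene)
}

#' Evaluate a bin result against ground truth
#'
#' Convenience wrapper computing the full metric report for one community:
#' contig- and base-level precision/recall of the binned contigs against
#' the planted eukaryote contigs, genome fraction of the nuclear genome,
#' NG50/LG50 of the nuclear bins, and (optionally) weighted SCG
#' completeness.
#'
#' @param br a [bin_result()].
#' @param contigs named character vector of the binning input contigs.
#' @param contig_truth contig truth table.
#' @param euk_genome_id,euk_genome_len nuclear genome id and length.
#' @param scg_templates optional SCG template set for the completeness
#'   score.
#' @return list of metrics.
#' @export
eval_report <- function(br, contigs, contig_truth, euk_genome_id,
                        euk_genome_len, scg_templates = NULL) {
  binned <- c(unlist(br$nuclear_bins, use.names = FALSE), br$mito_bin)
  tr <- as.data.table(contig_truth)
  truth_pos <- tr[category == "EUKARYOTE" & contig_id %in% names(contigs), contig_id]
  weights <- setNames(nchar(contigs), names(contigs))
  pr <- precision_recall(binned, truth_pos, names(contigs), weights = weights)
  nuclear <- unlist(br$nuclear_bins, use.names = FALSE)
  ng <- ng50_lg50(nchar(contigs[nuclear]), euk_genome_len)
  gf <- genome_fraction(binned, tr, euk_genome_len, genome_id = euk_genome_id)
  out <- list(precision = pr$precision, recall = pr$recall,
              precision_bp = pr$precision_bp, recall_bp = pr$recall_bp,
              counts = pr$counts, ng50 = ng$ng50, lg50 = ng$lg50,
              genome_fraction = gf)
  if (!is.null(scg_templates)) {
    out$weighted_scg <- weighted_scg(contigs[nuclear], scg_templates)$weighted_scg
  }
  out
}
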