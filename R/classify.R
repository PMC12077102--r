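# Five-way taxonomic routing of reads and contigs.
#
# Routing is evidence-ordered: a sufficiently long classifier hit decides
# the category; everything else is provisionally UNKNOWN and re-routed by
# the tabular-alignment fallback; whatever survives neither stays UNKNOWN
# and is retained (the EUnk pool) rather than discarded.

#' Routing thresholds
#'
#' Thresholds are inclusive at the stated boundary values. The `strict`
#' profile is the default parameterization: classifier minimum hit length
#' 40 bp for reads and 100 bp for contigs/long sequences; alignment
#' fallback requires e-value <= 0.01, percent identity >= 70 and query
#' coverage >= 30%; contigs shorter than 1,000 bp are dropped before
#' reclassification. The `lenient` profile (e-value 0.1, identity 50,
#' coverage 10) is a documented stand-in preset for permissive searches
#' against databases distant from the sample's environment.
#'
#' @param mode `"read"` (min hit length 40) or `"contig"` (100).
#' @param profile `"strict"` or `"lenient"`.
#' @param min_hit_length,aln_max_evalue,aln_min_pident,aln_min_qcov,min_contig_len
#'   overrides for individual thresholds.
#' @return a `routing_thresholds` list.
#' @export
routing_thresholds <- function(mode = c("read", "contig"),
                               profile = c("strict", "lenient"),
                               min_hit_length = NULL,
                               aln_max_evalue = NULL,
                               aln_min_pident = NULL,
                               aln_min_qcov = NULL,
                               min_contig_len = 1000L) {
  mode <- match.arg(mode)
  profile <- match.arg(profile)
  if (profile == "lenient") {
    warning("the 'lenient' profile values are documented stand-ins, not a calibrated preset",
            call. = FALSE)
  }
  th <- list(
    min_hit_length = if (!is.null(min_hit_length)) as.integer(min_hit_length)
                     else if (mode == "read") 40L else 100L,
    aln_max_evalue = if (!is.null(aln_max_evalue)) aln_max_evalue
                     else if (profile == "strict") 0.01 else 0.1,
    aln_min_pident = if (!is.null(aln_min_pident)) aln_min_pident
                     else if (profile == "strict") 70 else 50,
    aln_min_qcov = if (!is.null(aln_min_qcov)) aln_min_qcov
                   else if (profile == "strict") 30 else 10,
    min_contig_len = as.integer(min_contig_len),
    mode = mode, profile = profile)
  stopifnot(th$min_hit_length >= 1L, th$aln_max_evalue >= 0,
            th$aln_min_pident >= 0, th$aln_min_qcov >= 0)
  structure(th, class = "routing_thresholds")
}

#' Quality-trim and length-filter reads
#'
#' Sliding-window trimming from both ends: bases are clipped while the
#' window mean quality is below `min_qual`; reads shorter than `min_len`
#' after trimming are dropped. A surviving read whose mate was dropped
#' moves to the unpaired output, so three read sets result: two
#' synchronized paired files and one unpaired file.
#'
#' @param reads a read table (see [read_fastq()]); qualities required.
#' @param min_qual minimum window mean Phred quality (default 25).
#' @param min_len minimum post-trim read length in bp (default 40).
#' @param window sliding window width in bases (default 4).
#' @return list with elements `paired` (read table, both mates),
#'   `unpaired` (read table) and `n_dropped`.
#' @export
prepare_reads <- function(reads, min_qual = 25, min_len = 40L, window = 4L) {
  reads <- as.data.table(reads)
  if (!nrow(reads)) {
    return(list(paired = reads, unpaired = reads, n_dropped = 0L))
  }
  if (anyNA(reads$qual)) {
    stop("reads without qualities cannot be quality-trimmed; use the contig/long workflow",
         call. = FALSE)
  }
  cut <- .sliding_trim(reads$qual, as.integer(window), min_qual)
  out <- copy(reads)
  out[, `:=`(seq = substr(seq, cut[, 1], cut[, 2]),
             qual = substr(qual, cut[, 1], cut[, 2]))]
  keep <- nchar(out$seq) >= min_len
  n_dropped <- sum(!keep)
  out <- out[keep]
  if (all(is.na(out$mate))) {
    return(list(paired = out[0], unpaired = out, n_dropped = n_dropped))
  }
  n_mates <- out[!is.na(pair_id), .N, by = pair_id]
  complete <- n_mates[N == 2L, pair_id]
  paired <- out[pair_id %in% complete]
  unpaired <- out[!pair_id %in% complete]
  unpaired[, `:=`(mate = NA_integer_, pair_id = NA_character_)]
  setorder(paired, pair_id, mate)
  list(paired = paired, unpaired = unpaired, n_dropped = n_dropped)
}

# vectorized alignment routing: one row per query that survives the
# thresholds, carrying the best hit's category
aln_route <- function(aln_hits, query_lengths, th, taxmap, acc2tax = NULL) {
  if (is.null(aln_hits) || !nrow(aln_hits)) {
    return(data.table(query_id = character(), category = character()))
  }
  hits <- as.data.table(aln_hits)
  qlen <- query_lengths[hits$query_id]
  if (anyNA(qlen) || any(qlen <= 0)) {
    stop("alignment hits reference queries with unknown or non-positive length",
         call. = FALSE)
  }
  keep <- hits$evalue <= th$aln_max_evalue &
    hits$pident >= th$aln_min_pident &
    100 * hits$aln_length / qlen >= th$aln_min_qcov
  hits <- hits[keep]
  if (!nrow(hits)) {
    return(data.table(query_id = character(), category = character()))
  }
  if (!is.null(acc2tax)) {
    fill <- is.na(hits$subject_taxid)
    hits[fill, subject_taxid := as.integer(acc2tax[subject_id])]
  }
  setorder(hits, query_id, -bitscore, evalue, subject_id)
  best <- hits[, .SD[1L], by = query_id]
  best[, category := ifelse(is.na(subject_taxid), "UNKNOWN",
                            categorize_taxid(subject_taxid, taxmap))]
  best[, .(query_id, category)]
}

#' Route one query by its alignment hits
#'
#' Keeps hits with `evalue <= aln_max_evalue`, `pident >= aln_min_pident`
#' and query coverage `100 * aln_length / query_length >= aln_min_qcov`
#' (all boundaries inclusive); the best survivor by bitscore (ties broken
#' by lower e-value, then lexicographically smaller subject id) supplies
#' the category. No survivor, or a survivor without a resolvable taxid,
#' yields `UNKNOWN`.
#'
#' @param hits alignment hit table, all rows sharing one query.
#' @param query_length query length in bp.
#' @param th a [routing_thresholds()] list.
#' @param taxmap a [taxonomy_map()].
#' @param acc2tax optional named integer vector mapping subject ids to
#'   taxids (acc2tax-style side table), used when `subject_taxid` is absent.
#' @return a single category string.
#' @export
apply_alignment_thresholds <- function(hits, query_length, th, taxmap,
                                       acc2tax = NULL) {
  if (query_length <= 0) stop("query_length must be positive", call. = FALSE)
  if (is.null(hits) || !nrow(hits)) return("UNKNOWN")
  qid <- unique(hits$query_id)
  if (length(qid) != 1L) stop("hits must all share one query", call. = FALSE)
  routed <- aln_route(hits, setNames(query_length, qid), th, taxmap, acc2tax)
  if (!nrow(routed)) "UNKNOWN" else routed$category
}

#' Construct a classified set
#'
#' A classified set is the five-way partition of a batch of sequence ids,
#' with a per-id evidence trail (`rule`) recording which routing rule fired.
#'
#' @param assign `data.table` with columns `id`, `category`, `rule`.
#' @param kind `"read"` or `"contig"`.
#' @param pairs optional `data.table` (`id`, `pair_id`, `mate`) for reads.
#' @export
classified_set <- function(assign, kind = c("read", "contig"), pairs = NULL) {
  kind <- match.arg(kind)
  assign <- as.data.table(assign)
  if (anyDuplicated(assign$id)) stop("duplicate ids in classified set", call. = FALSE)
  bad <- setdiff(unique(assign$category), TAX_CATEGORIES)
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(assign = assign, kind = kind, pairs = pairs),
            class = "classified_set")
}

#' @export
print.classified_set <- function(x, ...) {
  counts <- category_counts(x)
  cat(sprintf("<classified_set> %d %s(s): %s\n", nrow(x$assign), x$kind,
              paste(sprintf("%s=%d", names(counts), counts), collapse = " ")))
  invisible(x)
}

#' Per-category counts of a classified set
#' @param cs a [classified_set()].
#' @return named integer vector over the five categories.
#' @export
category_counts <- function(cs) {
  tab <- table(factor(cs$assign$category, levels = TAX_CATEGORIES))
  setNames(as.integer(tab), TAX_CATEGORIES)
}

#' One round of five-way classification
#'
#' Stage 1: items whose best classifier hit reaches
#' `th$min_hit_length` are categorized by hit taxid; when a classifier
#' reports several equal-score hits (`num_matches > 1`, one row per tied
#' reference) the category is used only if all tied taxids agree on it,
#' otherwise the item stays `UNKNOWN`. Stage 2: items still provisionally
#' `UNKNOWN` are re-routed through the alignment fallback
#' ([apply_alignment_thresholds()] semantics). The result is a partition of
#' the input ids.
#'
#' @param items `data.table` with columns `id` and `query_length` (bp).
#' @param classifier_hits classifier hit table (possibly several tied rows
#'   per query; duplicate `(query_id, ref_id)` rows are an error).
#' @param aln_hits alignment hit table or `NULL` for no fallback.
#' @param th a [routing_thresholds()] list.
#' @param taxmap a [taxonomy_map()].
#' @param item_kind `"read"` or `"contig"`.
#' @param pairs optional pairing table forwarded to the classified set.
#' @param acc2tax optional subject-id to taxid side table for the fallback.
#' @return a [classified_set()].
#' @export
classify_round <- function(items, classifier_hits, aln_hits = NULL, th,
                           taxmap, item_kind = c("read", "contig"),
                           pairs = NULL, acc2tax = NULL) {
  item_kind <- match.arg(item_kind)
  items <- as.data.table(items)
  if (anyDuplicated(items$id)) stop("duplicate item ids", call. = FALSE)
  assign <- data.table(id = items$id, category = "UNKNOWN", rule = "no_evidence")

  if (!is.null(classifier_hits) && nrow(classifier_hits)) {
    ch <- as.data.table(classifier_hits)
    if (anyDuplicated(ch[, .(query_id, ref_id)])) {
      stop("duplicate (query_id, ref_id) rows in classifier hits", call. = FALSE)
    }
    ch <- ch[query_id %in% items$id & taxid != 0L]
    if (nrow(ch)) {
      ch <- ch[ch[, .I[hit_length == max(hit_length)], by = query_id]$V1]
      ch[, category := categorize_taxid(taxid, taxmap)]
      dec <- ch[, .(n_cat = uniqueN(category), category = category[1L],
                    hit_length = hit_length[1L], n_rows = .N), by = query_id]
      dec[, final := ifelse(hit_length < th$min_hit_length, NA_character_,
                     ifelse(n_cat > 1L, "UNKNOWN", category))]
      dec[, rule := ifelse(hit_length < th$min_hit_length, NA_character_,
                    ifelse(n_cat > 1L, "classifier_ambiguous", "classifier"))]
      dec <- dec[!is.na(final)]
      i <- match(dec$query_id, assign$id)
      assign[i, `:=`(category = dec$final, rule = dec$rule)]
    }
  }

  provisional <- assign[category == "UNKNOWN", id]
  if (length(provisional) && !is.null(aln_hits) && nrow(aln_hits)) {
    qlen <- setNames(items$query_length, items$id)
    sub <- as.data.table(aln_hits)[query_id %in% provisional]
    routed <- aln_route(sub, qlen, th, taxmap, acc2tax)
    routed <- routed[category != "UNKNOWN"]
    if (nrow(routed)) {
      i <- match(routed$query_id, assign$id)
      assign[i, `:=`(category = routed$category, rule = "alignment")]
    }
  }
  classified_set(assign, item_kind, pairs)
}

#' Reconcile mate-pair categories
#'
#' Concordant pairs keep their category. A pair with exactly one mate in
#' the retained pool (`EUKARYOTE` or `UNKNOWN`) becomes `UNKNOWN`, keeping
#' the pair together for assembly; a discordant `EUKARYOTE`/`UNKNOWN` pair
#' likewise becomes `UNKNOWN`. Pairs discordant between two excluded
#' categories (e.g. bacterial/viral) keep their per-mate categories — both
#' mates are excluded from the EUnk pool either way.
#'
#' @param cs a [classified_set()] with pairing information.
#' @return a reconciled [classified_set()].
#' @export
reconcile_pairs <- function(cs) {
  if (is.null(cs$pairs)) stop("classified set has no pairing information", call. = FALSE)
  assign <- copy(cs$assign)
  p <- as.data.table(cs$pairs)[!is.na(pair_id)]
  p[, category := assign$category[match(id, assign$id)]]
  eunk <- c("EUKARYOTE", "UNKNOWN")
  dec <- p[, .(n = .N, n_eunk = sum(category %in% eunk),
               concordant = uniqueN(category) == 1L), by = pair_id]
  to_unk <- dec[n == 2L & !concordant & n_eunk >= 1L, pair_id]
  if (length(to_unk)) {
    ids <- p[pair_id %in% to_unk, id]
    i <- match(ids, assign$id)
    assign[i, `:=`(category = "UNKNOWN", rule = "pair_reconciled")]
  }
  classified_set(assign, cs$kind, cs$pairs)
}

#' Select the EUnk pool
#'
#' Returns the ids classified `EUKARYOTE` or `UNKNOWN`, pair-complete for
#' reads (if either mate is selected, both are).
#'
#' @param cs a [classified_set()].
#' @return character vector of ids.
#' @export
select_eunk <- function(cs) {
  sel <- cs$assign[category %in% c("EUKARYOTE", "UNKNOWN"), id]
  if (!is.null(cs$pairs)) {
    p <- as.data.table(cs$pairs)
    sel_pairs <- p[id %in% sel & !is.na(pair_id), unique(pair_id)]
    sel <- union(sel, p[pair_id %in% sel_pairs, id])
  }
  sel
}

#' Two-round short-read workflow
#'
#' Round 1 classifies reads (classifier minimum hit length 40 bp) with the
#' alignment fallback on provisional unknowns, reconciles mate pairs, and
#' pools eukaryote + unknown reads; those are assembled, contigs shorter
#' than `th_contig$min_contig_len` (1,000 bp) are dropped, and round 2
#' reclassifies the contigs (minimum hit length 100 bp). The fallback in
#' round 2 runs on classifier-unknown contigs only (set
#' `reclassify_all = TRUE` to run it on every contig).
#'
#' @param reads read table (after [prepare_reads()] for real FASTQ input).
#' @param db a [build_kmer_index()] database.
#' @param taxmap a [taxonomy_map()].
#' @param assembler function mapping a read table to a named character
#'   vector of contigs (external assembler adapter or the perfect-assembly
#'   fixture from [perfect_assembly_fixture()]).
#' @param th_read,th_contig [routing_thresholds()] for the two rounds.
#' @param aln_hits_reads,aln_hits_contigs optional alignment hit tables for
#'   the fallback stages.
#' @param acc2tax optional subject-id to taxid side table.
#' @param reclassify_all run the round-2 fallback on all contigs instead of
#'   classifier-unknowns only.
#' @return list with `eunk_contigs` (named character), `round1`, `round2`
#'   (classified sets), `counts` (per-round category counts) and
#'   `contigs` (all length-filtered contigs).
#' @export
run_short_workflow <- function(reads, db, taxmap, assembler,
                               th_read = routing_thresholds("read"),
                               th_contig = routing_thresholds("contig"),
                               aln_hits_reads = NULL, aln_hits_contigs = NULL,
                               acc2tax = NULL, reclassify_all = FALSE) {
  if (!is.function(assembler)) {
    stop("no assembler available: supply an external assembler adapter or a fixture assembler",
         call. = FALSE)
  }
  reads <- as.data.table(reads)
  ch <- classify_with_index(reads$seq, db, ids = reads$id)
  pairs <- if (any(!is.na(reads$mate))) reads[, .(id, pair_id, mate)] else NULL
  cs1 <- classify_round(data.table(id = reads$id, query_length = nchar(reads$seq)),
                        ch, aln_hits_reads, th_read, taxmap, "read",
                        pairs = pairs, acc2tax = acc2tax)
  if (!is.null(pairs)) cs1 <- reconcile_pairs(cs1)
  eunk_ids <- select_eunk(cs1)
  out <- list(round1 = cs1, counts = list(round1 = category_counts(cs1)))
  if (!length(eunk_ids)) {
    out$contigs <- character(0)
    out$eunk_contigs <- character(0)
    out$round2 <- NULL
    out$counts$round2 <- setNames(integer(5), TAX_CATEGORIES)
    return(out)
  }
  contigs <- assembler(reads[id %in% eunk_ids])
  contigs <- contigs[nchar(contigs) >= th_contig$min_contig_len]
  out$contigs <- contigs
  if (!length(contigs)) {
    out$eunk_contigs <- character(0)
    out$round2 <- NULL
    out$counts$round2 <- setNames(integer(5), TAX_CATEGORIES)
    return(out)
  }
  res2 <- run_long_workflow(contigs, db, taxmap, th = th_contig,
                            aln_hits = aln_hits_contigs, acc2tax = acc2tax,
                            reclassify_all = reclassify_all)
  out$round2 <- res2$round1
  out$counts$round2 <- res2$counts$round1
  out$eunk_contigs <- res2$eunk_contigs
  out
}

#' One-round long-sequence / contig workflow
#'
#' Filters contigs to `th$min_contig_len`, runs a single classification
#' round with the contig profile (minimum hit length 100 bp) and returns
#' the eukaryote + unknown (EUnk) contigs.
#'
#' @param contigs named character vector of contigs or long reads.
#' @inheritParams run_short_workflow
#' @param th contig-profile [routing_thresholds()].
#' @param aln_hits optional alignment hit table for the fallback.
#' @return list with `eunk_contigs`, `round1` (classified set), `counts`.
#' @export
run_long_workflow <- function(contigs, db, taxmap,
                              th = routing_thresholds("contig"),
                              aln_hits = NULL, acc2tax = NULL,
                              reclassify_all = FALSE) {
  contigs <- contigs[nchar(contigs) >= th$min_contig_len]
  if (!length(contigs)) {
    return(list(eunk_contigs = character(0), round1 = NULL,
                counts = list(round1 = setNames(integer(5), TAX_CATEGORIES))))
  }
  ch <- classify_with_index(contigs, db)
  items <- data.table(id = names(contigs), query_length = nchar(contigs))
  if (reclassify_all && !is.null(aln_hits) && nrow(aln_hits)) {
    # run the fallback on everything: alignment evidence overrides weak
    # classifier calls for non-unknown contigs too
    cs <- classify_round(items, ch, NULL, th, taxmap, "contig")
    routed <- aln_route(as.data.table(aln_hits),
                        setNames(items$query_length, items$id), th, taxmap, acc2tax)
    routed <- routed[category != "UNKNOWN"]
    assign <- copy(cs$assign)
    i <- match(routed$query_id, assign$id)
    take <- !is.na(i)
    assign[i[take], `:=`(category = routed$category[take], rule = "alignment")]
    cs <- classified_set(assign, "contig")
  } else {
    cs <- classify_round(items, ch, aln_hits, th, taxmap, "contig",
                         acc2tax = acc2tax)
  }
  eunk <- select_eunk(cs)
  list(eunk_contigs = contigs[names(contigs) %in% eunk], round1 = cs,
       counts = list(round1 = category_counts(cs)))
}
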