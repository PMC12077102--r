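# Shared fixtures and independent oracles.

suppressMessages(library(data.table))

# minimal rooted taxonomy: 4 superkingdoms, one species each, plus a
# genus-level eukaryote and a mitochondrion node under it
toy_taxonomy <- function() {
  nodes <- data.table(
    taxid  = c(1L, 2L, 2157L, 2759L, 10239L, 101L, 102L, 103L, 104L, 105L, 106L),
    parent = c(1L, 1L, 1L,    1L,    1L,     2L,   2157L, 2759L, 10239L, 103L, 105L),
    rank   = c("no rank", rep("superkingdom", 4L), rep("species", 4L),
               "genus", "no rank"),
    name   = c("root", "Bacteria", "Archaea", "Eukaryota", "Viruses",
               "bact sp.", "arch sp.", "euk sp.", "virus sp.",
               "euk genus", "euk sp. mitochondrion"))
  taxonomy_map(nodes)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# brute-force oracle for the classifier hit_length: per-base coverage count
oracle_hit_length <- function(query, ref, k) {
  canon <- function(s) min(s, rc(s))
  ref_kmers <- unique(vapply(seq_len(nchar(ref) - k + 1L),
                             function(i) canon(substr(ref, i, i + k - 1L)), ""))
  covered <- rep(FALSE, nchar(query))
  for (i in seq_len(max(0L, nchar(query) - k + 1L))) {
    km <- substr(query, i, i + k - 1L)
    if (grepl("N", km, fixed = TRUE)) next
    if (canon(km) %in% ref_kmers) covered[i:(i + k - 1L)] <- TRUE
  }
  sum(covered)
}

# independent brute-force evaluator of the routing rules, coded directly
# from their statement (per item, scalar logic; no shared code with
# classify_round)
oracle_route <- function(item_id, qlen, classifier_hits, aln_hits, th, taxmap) {
  cat_out <- "UNKNOWN"
  ch <- classifier_hits[classifier_hits$query_id == item_id &
                          classifier_hits$taxid != 0, , drop = FALSE]
  if (nrow(ch) > 0) {
    best <- max(ch$hit_length)
    ch <- ch[ch$hit_length == best, , drop = FALSE]
    if (best >= th$min_hit_length) {
      cats <- unique(categorize_taxid(ch$taxid, taxmap))
      if (length(cats) == 1L) cat_out <- cats
    }
  }
  if (cat_out == "UNKNOWN" && !is.null(aln_hits)) {
    ah <- aln_hits[aln_hits$query_id == item_id, , drop = FALSE]
    ah <- ah[ah$evalue <= th$aln_max_evalue & ah$pident >= th$aln_min_pident &
               100 * ah$aln_length / qlen >= th$aln_min_qcov, , drop = FALSE]
    if (nrow(ah) > 0) {
      ah <- ah[order(-ah$bitscore, ah$evalue, ah$subject_id), , drop = FALSE]
      if (!is.na(ah$subject_taxid[1])) {
        cat_out <- categorize_taxid(ah$subject_taxid[1], taxmap)
      }
    }
  }
  cat_out
}

make_classifier_row <- function(query_id, taxid, hit_length, query_length,
                                ref_id = paste0("ref", taxid), num_matches = 1L) {
  data.table(query_id = query_id, ref_id = ref_id, taxid = as.integer(taxid),
             score = as.numeric(hit_length), second_best = 0,
             hit_length = as.integer(hit_length),
             query_length = as.integer(query_length),
             num_matches = as.integer(num_matches))
}

make_m8_row <- function(query_id, subject_id, pident, aln_length, evalue,
                        bitscore, subject_taxid = NA_integer_) {
  data.table(query_id = query_id, subject_id = subject_id, pident = pident,
             aln_length = as.integer(aln_length), mismatch = 0L, gapopen = 0L,
             q_start = 1L, q_end = as.integer(aln_length), s_start = 1L,
             s_end = as.integer(aln_length), evalue = evalue,
             bitscore = bitscore, subject_taxid = as.integer(subject_taxid))
}

# small read table
make_reads <- function(seqs, quals = NULL, ids = NULL, paired = FALSE) {
  n <- length(seqs)
  if (is.null(ids)) ids <- paste0("r", seq_len(n))
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  if (paired) {
    data.table(id = paste0(ids, "/", rep(1:2, length.out = n)), seq = seqs,
               qual = quals, mate = rep(1:2, length.out = n),
               pair_id = ids)
  } else {
    data.table(id = ids, seq = seqs, qual = quals, mate = NA_integer_,
               pair_id = NA_character_)
  }
}

# a small desk community shared by workflow tests (cheap: ~15k reads)
small_mock <- function(seed = 7L) {
  spec <- mock_community_spec(n_background = 4L, background_size = 60000L,
                              total_background_reads = 8000L,
                              euk_genome_size = 60000L, mito_size = 8000L,
                              euk_pool_reads = 6000L,
                              euk_read_levels = c(1000L, 3000L),
                              replicates = 1L, seed = seed)
  gen <- generate_genomes(spec)
  pools <- simulate_pools(gen)
  list(spec = spec, gen = gen, pools = pools)
}
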