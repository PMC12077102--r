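test_that("prepare_reads trims, drops short reads and splits orphaned mates", {
  # all-Q30 read is untouched
  r <- make_reads("ACGTACGTAC", quals = strrep("?", 10))
  prep <- prepare_reads(r, min_len = 5L)
  expect_equal(prep$unpaired$seq, "ACGTACGTAC")

  # trailing low-quality tail is clipped; post-trim length < min_len drops
  q50 <- paste0(strrep("?", 39), strrep("#", 21))  # 39 good bases, 21 at Q2
  r2 <- make_reads(random_dna(60), quals = q50)
  prep2 <- prepare_reads(r2, min_len = 40L)
  expect_equal(nrow(prep2$unpaired), 0L)  # trimmed to 39 < 40: dropped
  prep3 <- prepare_reads(r2, min_len = 39L)
  expect_equal(nchar(prep3$unpaired$seq), 39L)

  # pair where mate 2 is dropped: mate 1 moves to the unpaired output
  seqs <- c(random_dna(60), random_dna(60))
  quals <- c(strrep("?", 60), strrep("#", 60))
  rp <- make_reads(seqs, quals = quals, ids = c("p1", "p1"), paired = TRUE)
  prep4 <- prepare_reads(rp, min_len = 40L)
  expect_equal(nrow(prep4$paired), 0L)
  expect_equal(prep4$unpaired$seq, seqs[1])
  expect_true(is.na(prep4$unpaired$mate))

  # reads without qualities are refused
  rq <- make_reads("ACGT", quals = NA_character_)
  expect_error(prepare_reads(rq), "qualit")
})

test_that("alignment thresholds are inclusive at the stated boundaries", {
  tm <- toy_taxonomy()
  th <- routing_thresholds("read")

  at <- function(pident, cov, evalue) {
    hits <- make_m8_row("q", "s1", pident, round(cov), evalue, 100,
                        subject_taxid = 101L)
    apply_alignment_thresholds(hits, 100L, th, tm)
  }
  expect_equal(at(69.9, 50, 1e-5), "UNKNOWN")     # identity below 70
  expect_equal(at(70.0, 30, 0.01), "BACTERIA")    # all three at the boundary
  expect_equal(at(70.0, 29, 0.01), "UNKNOWN")     # coverage below 30
  expect_equal(at(70.0, 30, 0.011), "UNKNOWN")    # e-value above 0.01
  expect_equal(apply_alignment_thresholds(NULL, 100L, th, tm), "UNKNOWN")
  expect_error(apply_alignment_thresholds(NULL, 0L, th, tm), "positive")
})

test_that("best alignment hit is chosen by bitscore, then e-value, then subject", {
  tm <- toy_taxonomy()
  th <- routing_thresholds("read")
  hits <- rbind(make_m8_row("q", "sB", 90, 80, 1e-10, 200, subject_taxid = 101L),
                make_m8_row("q", "sA", 90, 80, 1e-10, 300, subject_taxid = 103L))
  expect_equal(apply_alignment_thresholds(hits, 100L, th, tm), "EUKARYOTE")
  hits2 <- rbind(make_m8_row("q", "sB", 90, 80, 1e-10, 200, subject_taxid = 101L),
                 make_m8_row("q", "sA", 90, 80, 1e-10, 200, subject_taxid = 103L))
  # equal bitscore and e-value: lexicographically smaller subject wins
  expect_equal(apply_alignment_thresholds(hits2, 100L, th, tm), "EUKARYOTE")
})

test_that("classify_round applies hit-length gates and stays a partition", {
  tm <- toy_taxonomy()
  items <- data.table(id = paste0("i", 1:4), query_length = 150L)
  ch <- rbind(make_classifier_row("i1", 101L, 39L, 150L),   # below 40
              make_classifier_row("i2", 101L, 40L, 150L),   # at 40
              make_classifier_row("i3", 103L, 120L, 150L))
  cs <- classify_round(items, ch, NULL, routing_thresholds("read"), tm, "read")
  a <- setNames(cs$assign$category, cs$assign$id)
  expect_equal(unname(a[c("i1", "i2", "i3", "i4")]),
               c("UNKNOWN", "BACTERIA", "EUKARYOTE", "UNKNOWN"))
  expect_equal(sum(category_counts(cs)), 4L)

  # contig profile: the same 39/40-bp evidence is too weak, 100 bp gates
  ch2 <- rbind(make_classifier_row("c1", 101L, 99L, 1500L),
               make_classifier_row("c2", 101L, 100L, 1500L))
  cs2 <- classify_round(data.table(id = c("c1", "c2"), query_length = 1500L),
                        ch2, NULL, routing_thresholds("contig"), tm, "contig")
  expect_equal(setNames(cs2$assign$category, cs2$assign$id),
               c(c1 = "UNKNOWN", c2 = "BACTERIA"))

  expect_error(classify_round(data.table(id = c("x", "x"), query_length = 10L),
                              NULL, NULL, routing_thresholds("read"), tm, "read"),
               "duplicate")
})

test_that("ambiguous multi-category classifier ties stay UNKNOWN, same-category ties resolve", {
  tm <- toy_taxonomy()
  items <- data.table(id = c("amb", "same"), query_length = 150L)
  ch <- rbind(
    make_classifier_row("amb", 101L, 90L, 150L, ref_id = "rB", num_matches = 2L),
    make_classifier_row("amb", 103L, 90L, 150L, ref_id = "rE", num_matches = 2L),
    make_classifier_row("same", 103L, 90L, 150L, ref_id = "rE1", num_matches = 2L),
    make_classifier_row("same", 105L, 90L, 150L, ref_id = "rE2", num_matches = 2L))
  cs <- classify_round(items, ch, NULL, routing_thresholds("read"), tm, "read")
  a <- setNames(cs$assign$category, cs$assign$id)
  expect_equal(unname(a["amb"]), "UNKNOWN")
  expect_equal(unname(a["same"]), "EUKARYOTE")
})

test_that("routing agrees with the independent brute-force rule evaluator", {
  tm <- toy_taxonomy()
  set.seed(99)
  for (mode in c("read", "contig")) {
    th <- routing_thresholds(mode)
    n <- 120L
    items <- data.table(id = sprintf("%s_%03d", mode, 1:n),
                        query_length = sample(c(100L, 150L, 1500L), n, TRUE))
    ch_rows <- list(); m8_rows <- list()
    for (i in seq_len(n)) {
      if (runif(1) < 0.8) {
        ch_rows[[length(ch_rows) + 1L]] <- make_classifier_row(
          items$id[i], sample(c(0L, 101L, 102L, 103L, 104L, 105L, 888L), 1L),
          sample(0:200, 1L), items$query_length[i])
      }
      for (j in seq_len(sample(0:3, 1L))) {
        m8_rows[[length(m8_rows) + 1L]] <- make_m8_row(
          items$id[i], paste0("s", sample(1:5, 1L)), runif(1, 40, 100),
          sample(10:1500, 1L), 10^runif(1, -30, 0), runif(1, 50, 500),
          subject_taxid = sample(c(NA, 101L, 103L, 104L), 1L))
      }
    }
    ch <- rbindlist(ch_rows)
    m8 <- rbindlist(m8_rows)
    cs <- classify_round(items, ch, m8, th, tm, "read")
    got <- setNames(cs$assign$category, cs$assign$id)
    want <- vapply(seq_len(n), function(i) {
      oracle_route(items$id[i], items$query_length[i], ch, m8, th, tm)
    }, "")
    expect_equal(unname(got[items$id]), want)
    expect_equal(sum(category_counts(cs)), n)  # partition invariant
  }
})

test_that("tightening alignment thresholds only ever grows UNKNOWN", {
  tm <- toy_taxonomy()
  set.seed(55)
  n <- 60L
  items <- data.table(id = sprintf("m%03d", 1:n), query_length = 200L)
  m8 <- rbindlist(lapply(seq_len(n), function(i) {
    make_m8_row(items$id[i], "s1", runif(1, 50, 100), sample(30:200, 1L),
                10^runif(1, -10, 0), runif(1, 50, 300), subject_taxid = 101L)
  }))
  loose <- classify_round(items, NULL, m8, routing_thresholds("read"), tm, "read")
  tight <- classify_round(items, NULL, m8,
                          routing_thresholds("read", aln_min_pident = 90,
                                             aln_min_qcov = 50,
                                             aln_max_evalue = 1e-5), tm, "read")
  for (catg in setdiff(TAX_CATEGORIES, "UNKNOWN")) {
    ids_tight <- tight$assign[category == catg, id]
    ids_loose <- loose$assign[category == catg, id]
    expect_true(all(ids_tight %in% ids_loose))
  }
  # raising min_hit_length 40 -> 100 never moves an item out of UNKNOWN
  ch <- rbindlist(lapply(seq_len(n), function(i) {
    make_classifier_row(items$id[i], 101L, sample(0:150, 1L), 200L)
  }))
  cs40 <- classify_round(items, ch, NULL, routing_thresholds("read"), tm, "read")
  cs100 <- classify_round(items, ch, NULL,
                          routing_thresholds("read", min_hit_length = 100L),
                          tm, "read")
  unk40 <- cs40$assign[category == "UNKNOWN", id]
  unk100 <- cs100$assign[category == "UNKNOWN", id]
  expect_true(all(unk40 %in% unk100))
})

test_that("pair reconciliation keeps EUnk pairs together", {
  tm <- toy_taxonomy()
  mk_cs <- function(c1, c2) {
    assign <- data.table(id = c("p/1", "p/2"), category = c(c1, c2),
                         rule = "classifier")
    classified_set(assign, "read",
                   pairs = data.table(id = c("p/1", "p/2"), pair_id = "p",
                                      mate = 1:2))
  }
  get_cats <- function(cs) sort(unique(reconcile_pairs(cs)$assign$category))
  expect_equal(get_cats(mk_cs("EUKARYOTE", "EUKARYOTE")), "EUKARYOTE")
  expect_equal(get_cats(mk_cs("BACTERIA", "UNKNOWN")), "UNKNOWN")
  expect_equal(get_cats(mk_cs("BACTERIA", "BACTERIA")), "BACTERIA")
  expect_equal(get_cats(mk_cs("EUKARYOTE", "UNKNOWN")), "UNKNOWN")
  # discordant excluded pair keeps per-mate categories
  expect_equal(get_cats(mk_cs("BACTERIA", "VIRUS")), c("BACTERIA", "VIRUS"))
})

test_that("select_eunk returns the pair-complete eukaryote+unknown pool", {
  assign <- data.table(id = paste0("r", 1:6),
                       category = c("EUKARYOTE", "EUKARYOTE", "UNKNOWN",
                                    "UNKNOWN", "BACTERIA", "VIRUS"),
                       rule = "classifier")
  cs <- classified_set(assign, "read")
  sel <- select_eunk(cs)
  expect_setequal(sel, paste0("r", 1:4))
  expect_length(intersect(sel, c("r5", "r6")), 0L)

  all_bact <- classified_set(data.table(id = "x", category = "BACTERIA",
                                        rule = "classifier"), "read")
  expect_length(select_eunk(all_bact), 0L)
})

test_that("short and long workflows agree on identical contig input", {
  mock <- small_mock()
  gen <- mock$gen
  db <- build_mini_db(gen)
  comms <- build_titration_series(mock$pools$background, mock$pools$euk_pool,
                                  c(2000L), 1L, seed = 3L)
  cm <- comms[[1]]
  asm <- make_fixture_assembler(cm$truth, gen$genomes)
  res_s <- run_short_workflow(cm$reads, db, gen$taxmap, asm)
  # long workflow on the round-2 input reproduces the round-2 EUnk set
  res_l <- run_long_workflow(res_s$contigs, db, gen$taxmap)
  expect_setequal(names(res_l$eunk_contigs), names(res_s$eunk_contigs))
  # partition invariant at both rounds
  expect_equal(sum(res_s$counts$round1), nrow(cm$reads))
  expect_equal(sum(res_s$counts$round2), length(res_s$contigs))

  # a sub-1000 bp contig never reaches round 2
  short_ctg <- setNames(random_dna(999), "tiny")
  res_t <- run_long_workflow(short_ctg, db, gen$taxmap)
  expect_length(res_t$eunk_contigs, 0L)

  # a contig with no evidence at all lands in EUnk
  noev <- setNames(random_dna(1500), "mystery")
  res_n <- run_long_workflow(noev, db, gen$taxmap)
  expect_equal(names(res_n$eunk_contigs), "mystery")

  # all-excluded input exits cleanly with empty EUnk
  bact_reads <- cm$reads[cm$truth[grepl("^bg", genome_id)], on = c(id = "read_id"),
                         nomatch = NULL][1:50, .(id, seq, qual, mate, pair_id)]
  res_b <- run_short_workflow(bact_reads, db, gen$taxmap, asm)
  expect_length(res_b$eunk_contigs, 0L)
})
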