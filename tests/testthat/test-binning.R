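test_that("composition vectors are canonical, normalized and strand-symmetric", {
  v <- composition_vector(c(pA = strrep("A", 50)), 4L)
  expect_equal(sum(v != 0), 1L)
  expect_equal(unname(v[1, "AAAA"]), 1.0)  # canonical AAAA/TTTT

  set.seed(8)
  s <- random_dna(400)
  v_f <- composition_vector(c(x = s), c(5L, 6L))
  v_r <- composition_vector(c(x = rc(s)), c(5L, 6L))
  expect_equal(v_f, v_r)

  # block dimensions: canonical k-mer counts (4^k + 4^(k/2)) / 2 for even k,
  # 4^k / 2 for odd k
  expect_equal(ncol(composition_vector(c(x = s), 4L)), 136L)
  expect_equal(ncol(v_f), 512L + 2080L)
  # per-k blocks each sum to 1
  expect_equal(sum(v_f[1, 1:512]), 1, tolerance = 1e-9)
  expect_equal(sum(v_f[1, 513:2592]), 1, tolerance = 1e-9)

  expect_error(composition_vector(c(x = "ACG"), 4L), "at least 4")
})

test_that("clustering recovers a planted two-genome partition and is deterministic", {
  set.seed(31)
  gA <- random_dna(60000, gc = 0.30)
  gB <- random_dna(60000, gc = 0.65)
  cut_contigs <- function(g, prefix) {
    starts <- seq(1, nchar(g) - 1000L, by = 1100L)[1:50]
    setNames(substring(g, starts, starts + 999L), paste0(prefix, 1:50))
  }
  contigs <- c(cut_contigs(gA, "a"), cut_contigs(gB, "b"))
  v <- composition_vector(contigs, 4L)
  ca <- cluster_contigs(v, seed = 1234L, clustering_id = "k4")
  expect_equal(sort(unique(ca$labels)), c("1", "2"))
  truth <- rep(c("A", "B"), each = 50L)
  purity <- max(mean(ca$labels[1:50] == ca$labels[1]),
                mean(ca$labels[51:100] == ca$labels[51]))
  tab <- table(truth, ca$labels)
  expect_gte(sum(apply(tab, 2, max)) / 100, 0.95)

  ca2 <- cluster_contigs(v, seed = 1234L, clustering_id = "k4")
  expect_identical(ca$labels, ca2$labels)

  # degenerate inputs
  two <- cluster_contigs(v[1:2, ], seed = 1L)
  expect_true(length(unique(two$labels)) %in% 1:2)
  same <- composition_vector(c(x = strrep("A", 100), y = strrep("A", 100)), 4L)
  expect_warning(one <- cluster_contigs(same, seed = 1L), "identical")
  expect_equal(unique(one$labels), "1")
})

test_that("depth estimation matches hand arithmetic and the truth-based oracle", {
  set.seed(12)
  ctg <- setNames(random_dna(1000), "c1")
  reads <- make_reads(vapply(1:10, function(i) {
    s <- sample(1:(1000 - 99), 1L)
    substr(ctg, s, s + 99L)
  }, ""))
  d <- estimate_depth(reads, ctg, k = 15L)
  expect_equal(d$mean_depth, 1.0)  # 10 x 100 bp over 1,000 bp

  # no assigned reads: zero depth
  d0 <- estimate_depth(make_reads(random_dna(100)), ctg, k = 15L)
  expect_equal(d0$mean_depth, 0)

  # cross-oracle: k-mer assignment within 10% of truth-interval depth
  mock <- small_mock()
  comms <- build_titration_series(mock$pools$background, mock$pools$euk_pool,
                                  c(3000L), 1L, seed = 9L)
  cm <- comms[[1]]
  pa <- perfect_assembly_fixture(cm$truth, mock$gen$genomes, min_len = 1000L)
  ev <- emit_evidence_fixtures(pa$truth, mock$gen, read_truth = cm$truth)
  est <- estimate_depth(cm$reads, pa$contigs)
  j <- merge(est, ev$depth, by = "contig_id")
  j <- j[mean_depth.y > 1]
  expect_true(all(abs(j$mean_depth.x - j$mean_depth.y) / j$mean_depth.y < 0.10))
})

test_that("marker-call filtering is strict at both thresholds", {
  calls <- data.table(contig_id = c("a", "b", "c"),
                      marker = "SSU",
                      pident = c(95, 90.1, 90),
                      aln_length = c(300L, 301L, 400L),
                      taxon_label = "Eukaryota;x")
  kept <- filter_marker_calls(calls)
  expect_equal(kept$contig_id, "b")  # 300 bp and 90% are excluded
  expect_equal(nrow(filter_marker_calls(calls[0])), 0L)
})

test_that("cluster flagging needs a strict eukaryote majority or a euk SSU", {
  mk_ev <- function(routing, markers = NULL) {
    evidence_bundle(names(routing),
                    routing = data.table(id = names(routing), category = routing),
                    markers = markers, filter_markers = FALSE)
  }
  labels <- setNames(rep("1", 4L), paste0("c", 1:4))
  asgn <- cluster_assignment("k4", labels)

  flagged <- flag_euk_clusters(asgn, mk_ev(c(c1 = "EUKARYOTE", c2 = "EUKARYOTE",
                                             c3 = "EUKARYOTE", c4 = "BACTERIA")))
  expect_true(flagged$euk_flag[["1"]])

  tie <- flag_euk_clusters(asgn, mk_ev(c(c1 = "EUKARYOTE", c2 = "EUKARYOTE",
                                         c3 = "BACTERIA", c4 = "BACTERIA")))
  expect_false(tie$euk_flag[["1"]])  # 2 vs 2 is not a strict majority

  # unknown-only cluster rescued by a eukaryotic SSU marker call
  ssu <- data.table(contig_id = "c2", marker = "SSU", pident = 99,
                    aln_length = 1200L, taxon_label = "Eukaryota;x")
  dark <- flag_euk_clusters(asgn, mk_ev(setNames(rep("UNKNOWN", 4), paste0("c", 1:4)),
                                        markers = ssu))
  expect_true(dark$euk_flag[["1"]])
  no_ssu <- flag_euk_clusters(asgn, mk_ev(setNames(rep("UNKNOWN", 4), paste0("c", 1:4))))
  expect_false(no_ssu$euk_flag[["1"]])
})

test_that("consensus membership equals brute force over all flag patterns", {
  ids <- sprintf("c%d", 1:8)
  # every contig gets one of the 2^3 in-flagged-cluster patterns
  patterns <- expand.grid(k4 = c(TRUE, FALSE), k5 = c(TRUE, FALSE),
                          k56 = c(TRUE, FALSE))
  assignments <- lapply(c("k4", "k5", "k56"), function(cl) {
    lab <- ifelse(patterns[[cl]], "euk", "other")
    cluster_assignment(cl, setNames(lab, ids),
                       euk_flag = c(euk = TRUE, other = FALSE))
  })
  got <- consensus_membership(assignments)
  want <- ids[rowSums(patterns) >= 2L]
  expect_setequal(got, want)
  expect_true("c1" %in% got)                  # flagged in all three
  expect_true(ids[which(patterns$k4 & patterns$k5 & !patterns$k56)] %in% got)
  expect_false(ids[which(patterns$k56 & !patterns$k4 & !patterns$k5)] %in% got)
  expect_error(consensus_membership(assignments[1:2]), "three")
})

test_that("inclusion criteria reject at the stated boundaries", {
  ids <- paste0("c", 1:6)
  depth <- data.table(contig_id = ids, contig_len = 5000L,
                      mean_depth = c(20, 21, 19, 10, 10, 10), depth_var = 0)
  nt <- rbind(make_m8_row("c4", "nt|bact", 91, 1200L, 1e-40, 900, subject_taxid = 101L),
              make_m8_row("c5", "nt|bact", 91, 800L, 1e-40, 700, subject_taxid = 101L),
              make_m8_row("c6", "nt|bact", 90, 1200L, 1e-40, 900, subject_taxid = 101L))
  ev <- evidence_bundle(ids, depth = depth, nt_hits = nt, taxmap = toy_taxonomy(),
                        routing = data.table(id = ids, category = "EUKARYOTE"))
  res <- apply_inclusion_criteria(ids, ev, ssu_cap = 20)
  rej <- setNames(res$rejected$reason, res$rejected$contig_id)
  expect_equal(unname(rej["c2"]), "DEPTH_GT_SSU")     # 21 > 20
  expect_false("c1" %in% names(rej))                  # exactly at the cap: kept
  expect_equal(unname(rej["c4"]), "PROK_HIT")         # 91% x 1,200 bp
  expect_false("c5" %in% names(rej))                  # 800 bp fails the length arm
  expect_false("c6" %in% names(rej))                  # 90% fails the identity arm
  expect_setequal(res$retained, c("c1", "c3", "c5", "c6"))

  expect_warning(apply_inclusion_criteria(ids, ev, ssu_cap = NULL), "skipped")
})

test_that("criterion 4: conflicting taxonomy rejects, no-evidence retains", {
  ids <- c("euk_lab", "dark", "prok_lab")
  ev <- evidence_bundle(ids,
                        depth = data.table(contig_id = ids, contig_len = 2000L,
                                           mean_depth = 1, depth_var = 0),
                        nt_hits = make_m8_row("prok_lab", "nt|b", 85, 500L,
                                              1e-30, 400, subject_taxid = 101L),
                        taxmap = toy_taxonomy(),
                        routing = data.table(id = ids,
                                             category = c("EUKARYOTE", "UNKNOWN",
                                                          "UNKNOWN")))
  res <- suppressWarnings(apply_inclusion_criteria(ids, ev))
  expect_setequal(res$retained, c("euk_lab", "dark"))
  expect_equal(res$rejected$contig_id, "prok_lab")
  expect_equal(res$rejected$reason, "CONFLICTING_TAXONOMY")
})

test_that("mitochondrial flagging needs both the marker and the mito best hit", {
  ids <- c("both", "marker_only", "hit_only")
  markers <- data.table(contig_id = c("both", "marker_only"), marker = "MITO",
                        pident = 99, aln_length = 900L,
                        taxon_label = "Eukaryota;x;mitochondrion")
  nt <- rbind(make_m8_row("both", "nt|mito", 97, 900L, 1e-40, 800, subject_taxid = 106L),
              make_m8_row("hit_only", "nt|mito", 97, 900L, 1e-40, 800, subject_taxid = 106L))
  ev <- evidence_bundle(ids, markers = markers, nt_hits = nt,
                        taxmap = toy_taxonomy(), mito_refs = "nt|mito")
  expect_equal(flag_mitochondrial(ids, ev), "both")
  ev_none <- evidence_bundle(ids, taxmap = toy_taxonomy())
  expect_length(flag_mitochondrial(ids, ev_none), 0L)
})

test_that("run_binning partitions its input with one reason per rejection", {
  mock <- small_mock()
  gen <- mock$gen
  comms <- build_titration_series(mock$pools$background, mock$pools$euk_pool,
                                  c(3000L), 1L, seed = 5L)
  cm <- comms[[1]]
  pa <- perfect_assembly_fixture(cm$truth, gen$genomes, min_len = 1000L)
  evt <- emit_evidence_fixtures(pa$truth, gen, read_truth = cm$truth, seed = 2L)
  ev <- evidence_bundle(names(pa$contigs), depth = evt$depth,
                        markers = evt$markers, nt_hits = evt$nt_hits,
                        taxmap = gen$taxmap, mito_refs = gen$mito_refs,
                        routing = data.table(id = pa$truth$contig_id,
                                             category = pa$truth$category))
  br <- suppressWarnings(run_binning(pa$contigs, ev, seed = 99L))
  members <- c(unlist(br$nuclear_bins, use.names = FALSE), br$mito_bin,
               br$rejected$contig_id)
  expect_setequal(members, names(pa$contigs))
  expect_false(anyDuplicated(members) > 0)
  expect_equal(anyDuplicated(br$rejected$contig_id), 0L)
  expect_true(all(br$rejected$reason %in%
                    c("DEPTH_GT_SSU", "PROK_HIT", "CONSENSUS_LT2",
                      "CONFLICTING_TAXONOMY")))
  # mito contigs all carry MITO markers, and the two bin kinds are disjoint
  expect_true(all(br$mito_bin %in% ev$markers[marker == "MITO", contig_id]))
  expect_length(intersect(br$mito_bin, unlist(br$nuclear_bins)), 0L)

  # no nuclear contig violates the depth cap or prokaryote-hit rule post hoc
  ssu_ids <- ev$markers[marker == "SSU", contig_id]
  nuc <- unlist(br$nuclear_bins, use.names = FALSE)
  if (length(ssu_ids)) {
    depth <- setNames(ev$depth$mean_depth, ev$depth$contig_id)
    cap <- max(depth[intersect(ssu_ids, c(nuc, br$rejected$contig_id))])
    expect_true(all(depth[nuc] <= cap))
  }
  prok <- ev$nt_best[category %in% c("ARCHAEA", "BACTERIA", "VIRUS") &
                       pident > 90 & aln_length >= 1000L, contig_id]
  expect_length(intersect(nuc, prok), 0L)

  # determinism: same seed, same result
  br2 <- suppressWarnings(run_binning(pa$contigs, ev, seed = 99L))
  expect_identical(bin_membership(br), bin_membership(br2))
})
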