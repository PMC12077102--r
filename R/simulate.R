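# Mock-community simulation with complete ground truth.
#
# The benchmark design: a staggered background of prokaryote genomes
# (log-spaced molar abundances) plus titrated amounts of reads from one or
# more eukaryote genomes, in several levels and replicates. Genomes are
# drawn from genome-specific second-order Markov composition models so
# composition clustering is learnable; eukaryote genomes carry planted
# SSU/LSU, mitochondrial and single-copy-gene segments copied from the
# bundled synthetic marker templates.

#' Mock community specification
#'
#' The default parameterization is the desk-scale study condition: 10
#' background genomes of 500 kb each (5 Mb total) mixed in staggered molar
#' amounts spanning three orders of magnitude, 200,000 background reads, a
#' 200 kb eukaryote genome (GC 0.30) with a 15 kb mitochondrial replicon at
#' 6-fold molar excess, an rDNA (SSU+LSU) locus sampled at 10-fold depth
#' (emulating a collapsed multi-copy rDNA array), 10 planted single-copy
#' genes, and a titration of {2k, 5k, 10k, 20k} eukaryote reads in 2
#' replicates. Reads are 150 bp pairs from a normal insert (350 +/- 30 bp)
#' with per-base substitution errors at 0.002 and constant Q30 qualities.
#'
#' @param n_background number of background genomes.
#' @param background_size bp per background genome (recycled).
#' @param background_gc GC content per background genome (recycled;
#'   defaults to an even spread over 0.35..0.65).
#' @param abundance_orders orders of magnitude spanned by the staggered
#'   log-spaced molar abundances.
#' @param total_background_reads background reads (2 reads per pair).
#' @param euk_genome_size,euk_gc eukaryote nuclear genome size and GC.
#' @param mito_size,mito_copy_number mitochondrial replicon size and molar
#'   copy number relative to the nuclear genome.
#' @param ssu_copy_number sampling multiplier over the rDNA locus.
#' @param n_scg number of planted single-copy genes.
#' @param euk_pool_reads size of the eukaryote read pool the titration
#'   samples from (must be >= max level).
#' @param euk_read_levels ascending eukaryote read counts of the titration.
#' @param replicates replicates per titration level.
#' @param read_length,insert_mean,insert_sd,error_rate read simulation
#'   parameters.
#' @param seed default RNG seed for the generators.
#' @return a `mock_community_spec` list.
#' @export
mock_community_spec <- function(n_background = 10L,
                                background_size = 500000L,
                                background_gc = NULL,
                                abundance_orders = 3,
                                total_background_reads = 200000L,
                                euk_genome_size = 200000L,
                                euk_gc = 0.30,
                                mito_size = 15000L,
                                mito_copy_number = 6,
                                ssu_copy_number = 10,
                                n_scg = 10L,
                                euk_pool_reads = 40000L,
                                euk_read_levels = c(2000L, 5000L, 10000L, 20000L),
                                replicates = 2L,
                                read_length = 150L,
                                insert_mean = 350,
                                insert_sd = 30,
                                error_rate = 0.002,
                                seed = 1234L) {
  if (is.null(background_gc)) {
    background_gc <- seq(0.35, 0.65, length.out = n_background)
  }
  spec <- list(n_background = as.integer(n_background),
               background_size = rep_len(as.integer(background_size), n_background),
               background_gc = rep_len(background_gc, n_background),
               abundance_orders = abundance_orders,
               total_background_reads = as.integer(total_background_reads),
               euk_genome_size = as.integer(euk_genome_size),
               euk_gc = euk_gc,
               mito_size = as.integer(mito_size),
               mito_copy_number = mito_copy_number,
               ssu_copy_number = ssu_copy_number,
               n_scg = as.integer(n_scg),
               euk_pool_reads = as.integer(euk_pool_reads),
               euk_read_levels = as.integer(euk_read_levels),
               replicates = as.integer(replicates),
               read_length = as.integer(read_length),
               insert_mean = insert_mean, insert_sd = insert_sd,
               error_rate = error_rate, seed = as.integer(seed))
  stopifnot(!is.unsorted(spec$euk_read_levels), spec$replicates >= 1L,
            spec$error_rate >= 0, spec$error_rate <= 0.1,
            spec$euk_pool_reads >= max(spec$euk_read_levels))
  structure(spec, class = "mock_community_spec")
}

#' Bundled synthetic marker templates
#'
#' Synthetic, tagged template sequences standing in for SSU/LSU rRNA,
#' mitochondrial and single-copy-gene references; tests match them by
#' identity, not biology.
#'
#' @return named character vector of template sequences.
#' @export
marker_templates <- function() {
  read_fasta(system.file("extdata", "marker_templates.fa", package = "eukmag",
                         mustWork = TRUE))
}

# order-2 Markov model with per-context GC pinned at `gc`, dinucleotide
# bias drawn in log space (distinct per genome)
random_markov_model <- function(gc, bias_sd = 0.3) {
  base <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  trans <- matrix(0, 16L, 4L)
  for (ctx in 1:16) {
    w <- base * exp(rnorm(4L, 0, bias_sd))
    # pin per-context GC so the realized genome GC matches the target
    w[c(2L, 3L)] <- gc * w[c(2L, 3L)] / sum(w[c(2L, 3L)])
    w[c(1L, 4L)] <- (1 - gc) * w[c(1L, 4L)] / sum(w[c(1L, 4L)])
    trans[ctx, ] <- w
  }
  init <- as.vector(outer(base, base))  # P(first dinucleotide), column-major
  init <- init / sum(init)
  list(init = init, trans = trans)
}

plant <- function(genome, segment, start) {
  paste0(substr(genome, 1L, start - 1L), segment,
         substr(genome, start + nchar(segment), nchar(genome)))
}

#' Generate mock-community genomes, taxonomy and planted features
#'
#' Background genomes are pure Markov sequences; the eukaryote genome gets
#' one rDNA locus (SSU then LSU, sampled at `ssu_copy_number`-fold depth)
#' and `n_scg` dispersed single-copy genes; the mitochondrial replicon gets
#' the MITO template. A minimal rooted taxonomy covering all genomes is
#' built alongside.
#'
#' @param spec a [mock_community_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return list with `genomes` (named character), `taxids` (named integer),
#'   `taxmap` ([taxonomy_map()]), `features`
#'   (`data.table(genome_id, feature, start, end, copy_number)`),
#'   `mito_refs` (nt subject ids that are mitochondrial), and `spec`.
#' @export
generate_genomes <- function(spec = mock_community_spec(), seed = spec$seed) {
  set.seed(seed)
  tmpl <- marker_templates()
  genomes <- character(0)
  features <- list()

  bg_ids <- sprintf("bg%02d", seq_len(spec$n_background))
  for (i in seq_len(spec$n_background)) {
    m <- random_markov_model(spec$background_gc[i])
    genomes[bg_ids[i]] <- .markov_sequence(spec$background_size[i], m$init, m$trans)
  }

  m <- random_markov_model(spec$euk_gc)
  euk <- .markov_sequence(spec$euk_genome_size, m$init, m$trans)
  rdna <- paste0(tmpl[["SSU_synth"]], tmpl[["LSU_synth"]])
  scg_ids <- sprintf("SCG%02d", seq_len(spec$n_scg))
  seg_lens <- c(nchar(rdna), nchar(tmpl[scg_ids]))
  # dispersed non-overlapping loci for the rDNA unit and the SCGs
  slots <- floor(seq(1, spec$euk_genome_size - max(seg_lens) - 1,
                     length.out = spec$n_scg + 2L))
  ord <- sample(seq_len(spec$n_scg + 1L))  # which segment goes in which slot
  starts <- slots[seq_len(spec$n_scg + 1L)] +
    sample.int(max(1L, min(diff(slots)) - max(seg_lens)), spec$n_scg + 1L,
               replace = TRUE)
  seg_names <- c("rDNA", scg_ids)[ord]
  for (j in seq_along(seg_names)) {
    nm <- seg_names[j]
    segment <- if (nm == "rDNA") rdna else tmpl[[nm]]
    euk <- plant(euk, segment, starts[j])
    if (nm == "rDNA") {
      features[[length(features) + 1L]] <- data.table(
        genome_id = "euk1", feature = c("SSU", "LSU"),
        start = c(starts[j], starts[j] + nchar(tmpl[["SSU_synth"]])),
        end = c(starts[j] + nchar(tmpl[["SSU_synth"]]) - 1L,
                starts[j] + nchar(rdna) - 1L),
        copy_number = spec$ssu_copy_number)
    } else {
      features[[length(features) + 1L]] <- data.table(
        genome_id = "euk1", feature = nm, start = starts[j],
        end = starts[j] + nchar(segment) - 1L, copy_number = 1)
    }
  }
  genomes[["euk1"]] <- euk

  mm <- random_markov_model(0.35)
  mito <- .markov_sequence(spec$mito_size, mm$init, mm$trans)
  mstart <- sample.int(spec$mito_size - nchar(tmpl[["MITO_synth"]]) - 1L, 1L)
  genomes[["euk1_mito"]] <- plant(mito, tmpl[["MITO_synth"]], mstart)
  features[[length(features) + 1L]] <- data.table(
    genome_id = "euk1_mito", feature = "MITO", start = mstart,
    end = mstart + nchar(tmpl[["MITO_synth"]]) - 1L, copy_number = 1)

  taxids <- c(setNames(1000L + seq_len(spec$n_background), bg_ids),
              euk1 = 2001L, euk1_mito = 2002L)
  nodes <- rbind(
    data.table(taxid = 1L, parent = 1L, rank = "no rank", name = "root"),
    data.table(taxid = c(2L, 2157L, 2759L, 10239L), parent = 1L,
               rank = "superkingdom",
               name = c("Bacteria", "Archaea", "Eukaryota", "Viruses")),
    data.table(taxid = taxids[bg_ids], parent = 2L, rank = "species",
               name = paste0("synthetic bacterium ", bg_ids)),
    data.table(taxid = 2001L, parent = 2759L, rank = "species",
               name = "synthetic eukaryote euk1"),
    data.table(taxid = 2002L, parent = 2001L, rank = "no rank",
               name = "synthetic eukaryote euk1 mitochondrion"))

  list(genomes = genomes, taxids = taxids, taxmap = taxonomy_map(nodes),
       features = rbindlist(features), mito_refs = "nt|euk1_mito",
       spec = spec)
}

#' Build the mini classifier database for a mock community
#'
#' Indexes one contiguous fragment per genome covering `db_fraction` of its
#' length (a complete reference collection is unrealistic; the uncovered
#' remainder feeds the Unknown route). `exclude` drops genomes from the
#' database — the reference-free ablation.
#'
#' @param gen output of [generate_genomes()].
#' @param db_fraction fraction of each genome indexed.
#' @param k index k-mer size.
#' @param exclude genome ids to leave out of the database.
#' @return a [build_kmer_index()] database.
#' @export
build_mini_db <- function(gen, db_fraction = 0.85, k = 31L, exclude = NULL) {
  ids <- setdiff(names(gen$genomes), exclude)
  if (!length(ids)) stop("no genomes left for the database", call. = FALSE)
  refs <- vapply(ids, function(g) {
    s <- gen$genomes[[g]]
    substr(s, 1L, max(k, floor(nchar(s) * db_fraction)))
  }, "")
  names(refs) <- paste0("ref|", ids)
  build_kmer_index(refs, setNames(gen$taxids[ids], names(refs)), k = k)
}

# sample fragment start positions for one genome, honoring feature
# sampling multipliers (collapsed-repeat emulation)
sample_starts <- function(n, glen, ins, feats) {
  lo <- pmax(1L, glen - ins + 1L)
  starts <- 1L + floor(runif(n) * lo)
  if (!is.null(feats) && nrow(feats)) {
    extra_w <- (feats$copy_number - 1) * (feats$end - feats$start + 1L)
    p_extra <- sum(extra_w) / (glen + sum(extra_w))
    redo <- runif(n) < p_extra
    if (any(redo)) {
      fi <- sample.int(nrow(feats), sum(redo), replace = TRUE,
                       prob = extra_w / sum(extra_w))
      ins_r <- if (length(ins) > 1L) ins[redo] else ins
      fs <- pmax(1L, feats$start[fi] - ins_r + 1L)
      fe <- pmax(fs, pmin(feats$end[fi], glen - ins_r + 1L))
      starts[redo] <- fs + floor(runif(sum(redo)) * (fe - fs + 1L))
    }
  }
  pmin(starts, lo)
}

#' Simulate paired reads from a set of genomes
#'
#' Read pairs are apportioned to genomes by a multinomial over
#' `molar weight x genome length`, inserts are normal, per-base
#' substitution errors occur at `spec$error_rate`, and qualities are
#' constant Q30. Every read gets a truth row recording its source genome,
#' category and genome coordinates.
#'
#' @param gen output of [generate_genomes()].
#' @param n_reads total reads to emit (2 per pair).
#' @param weights named molar weights per genome id.
#' @param spec a [mock_community_spec()] (read length, insert, error rate).
#' @param prefix read-id prefix.
#' @param seed RNG seed.
#' @return list with `reads` (read table) and `truth`
#'   (`data.table(read_id, genome_id, category, start, end)`).
#' @export
simulate_reads <- function(gen, n_reads, weights, spec = gen$spec,
                           prefix = "r", seed = spec$seed) {
  set.seed(seed)
  n_pairs <- n_reads %/% 2L
  gids <- names(weights)
  glens <- nchar(gen$genomes[gids])
  rl <- spec$read_length
  if (any(glens < spec$insert_mean + 4 * spec$insert_sd)) {
    stop("genome shorter than the insert size distribution", call. = FALSE)
  }
  p <- weights * glens
  counts <- as.vector(stats::rmultinom(1L, n_pairs, p / sum(p)))
  cat_of <- categorize_taxid(gen$taxids[gids], gen$taxmap)

  recs <- vector("list", length(gids))
  for (i in seq_along(gids)) {
    n <- counts[i]
    if (n == 0L) next
    g <- gen$genomes[[gids[i]]]
    ins <- pmax(rl, pmin(glens[i],
                         as.integer(round(rnorm(n, spec$insert_mean, spec$insert_sd)))))
    feats <- gen$features[genome_id == gids[i] & copy_number > 1]
    s <- sample_starts(n, glens[i], ins, feats)
    e <- pmin(s + ins - 1L, glens[i])
    r1 <- substr(rep(g, n), s, s + rl - 1L)
    r2 <- revcomp(substr(rep(g, n), e - rl + 1L, e))
    # random orientation: half the pairs lead with the reverse-strand mate
    flip <- runif(n) < 0.5
    tmp <- r1[flip]; r1[flip] <- r2[flip]; r2[flip] <- tmp
    recs[[i]] <- data.table(genome_id = gids[i], category = cat_of[i],
                            start = s, end = e, flip = flip, r1 = r1, r2 = r2)
  }
  dt <- rbindlist(recs)
  if (!nrow(dt)) {
    return(list(reads = data.table(id = character(), seq = character(),
                                   qual = character(), mate = integer(),
                                   pair_id = character()),
                truth = data.table(read_id = character(), genome_id = character(),
                                   category = character(), start = integer(),
                                   end = integer())))
  }
  dt[, pid := sprintf("%s%07d", prefix, .I)]
  seqs <- .mutate_seqs(c(dt$r1, dt$r2), spec$error_rate)
  qual <- strrep("?", rl)  # constant Q30
  reads <- data.table(id = c(paste0(dt$pid, "/1"), paste0(dt$pid, "/2")),
                      seq = seqs, qual = qual,
                      mate = rep(1:2, each = nrow(dt)),
                      pair_id = rep(dt$pid, 2L))
  left_s <- dt$start; left_e <- dt$start + rl - 1L
  right_s <- dt$end - rl + 1L; right_e <- dt$end
  truth <- data.table(read_id = reads$id,
                      genome_id = rep(dt$genome_id, 2L),
                      category = rep(dt$category, 2L),
                      start = c(ifelse(dt$flip, right_s, left_s),
                                ifelse(dt$flip, left_s, right_s)),
                      end = c(ifelse(dt$flip, right_e, left_e),
                              ifelse(dt$flip, left_e, right_e)))
  list(reads = reads, truth = truth)
}

#' Staggered molar weights for the background genomes
#'
#' Log-spaced over `spec$abundance_orders` orders of magnitude.
#'
#' @param gen output of [generate_genomes()].
#' @return named numeric weights over the background genomes.
#' @export
staggered_weights <- function(gen) {
  bg <- grep("^bg", names(gen$genomes), value = TRUE)
  setNames(10^seq(0, -gen$spec$abundance_orders, length.out = length(bg)), bg)
}

#' Simulate the background and eukaryote read pools
#'
#' Background: `total_background_reads` from the staggered prokaryote mix.
#' Eukaryote pool: `euk_pool_reads` from the nuclear genome plus its
#' mitochondrial replicon at `mito_copy_number`-fold molar excess.
#'
#' @param gen output of [generate_genomes()].
#' @param seed RNG seed.
#' @return list with `background` and `euk_pool`, each a
#'   [simulate_reads()] result.
#' @export
simulate_pools <- function(gen, seed = gen$spec$seed) {
  spec <- gen$spec
  background <- simulate_reads(gen, spec$total_background_reads,
                               staggered_weights(gen), spec,
                               prefix = "bg", seed = seed)
  mito_w <- spec$mito_copy_number  # molar; weight x length handled downstream
  euk_pool <- simulate_reads(gen, spec$euk_pool_reads,
                             c(euk1 = 1, euk1_mito = mito_w), spec,
                             prefix = "ek", seed = seed + 1L)
  list(background = background, euk_pool = euk_pool)
}

#' Build the titration series of mock communities
#'
#' For each level x replicate, samples `level` eukaryote reads
#' (pair-complete, without replacement) from the pool and concatenates
#' them with the full background.
#'
#' @param background,euk_pool [simulate_reads()] results.
#' @param levels ascending eukaryote read counts; a level of 0 yields the
#'   background alone.
#' @param replicates replicates per level.
#' @param seed RNG seed.
#' @return list of communities, each with `level`, `replicate`, `reads`,
#'   `truth`.
#' @export
build_titration_series <- function(background, euk_pool, levels,
                                   replicates = 2L, seed = 1L) {
  set.seed(seed)
  pool_pairs <- unique(euk_pool$reads$pair_id)
  out <- list()
  for (lv in as.integer(levels)) {
    n_pairs <- lv %/% 2L
    if (n_pairs > length(pool_pairs)) {
      stop(sprintf("titration level %d exceeds the eukaryote pool (%d reads)",
                   lv, 2L * length(pool_pairs)), call. = FALSE)
    }
    for (rep_i in seq_len(replicates)) {
      take <- if (n_pairs > 0L) sample(pool_pairs, n_pairs) else character(0)
      er <- euk_pool$reads[pair_id %in% take]
      et <- euk_pool$truth[read_id %in% er$id]
      out[[length(out) + 1L]] <- list(
        level = lv, replicate = rep_i,
        reads = rbind(background$reads, er),
        truth = rbind(background$truth, et))
    }
  }
  out
}

#' Perfect-assembly fixture
#'
#' The assembler stand-in for desk-scale tests: each genome's read-covered
#' intervals (union of the truth intervals of the supplied reads) become
#' contigs, split at coverage gaps and filtered at `min_len`.
#'
#' @param truth read truth table (`read_id`, `genome_id`, `category`,
#'   `start`, `end`).
#' @param genomes named character vector of source genomes.
#' @param min_len minimum contig length emitted.
#' @param read_ids optional subset of reads to assemble.
#' @return list with `contigs` (named character) and `truth`
#'   (`data.table(contig_id, genome_id, category, start, end)`).
#' @export
perfect_assembly_fixture <- function(truth, genomes, min_len = 1000L,
                                     read_ids = NULL) {
  tr <- as.data.table(truth)
  if (!is.null(read_ids)) tr <- tr[read_id %in% read_ids]
  contigs <- character(0)
  rows <- list()
  for (g in sort(unique(tr$genome_id))) {
    sub <- tr[genome_id == g]
    red <- IRanges::reduce(IRanges::IRanges(start = sub$start, end = sub$end))
    red <- red[IRanges::width(red) >= min_len]
    if (!length(red)) next
    ids <- sprintf("ctg_%s_%03d", g, seq_along(red))
    contigs[ids] <- substr(rep(genomes[[g]], length(red)),
                           IRanges::start(red), IRanges::end(red))
    rows[[length(rows) + 1L]] <- data.table(contig_id = ids, genome_id = g,
                                            category = sub$category[1L],
                                            start = IRanges::start(red),
                                            end = IRanges::end(red))
  }
  list(contigs = contigs,
       truth = if (length(rows)) rbindlist(rows) else
         data.table(contig_id = character(), genome_id = character(),
                    category = character(), start = integer(), end = integer()))
}

#' Fixture assembler closure
#'
#' Wraps [perfect_assembly_fixture()] into the assembler interface of
#' [run_short_workflow()]: given a read table, assembles exactly those
#' reads by their truth intervals.
#'
#' @param truth full read truth table.
#' @param genomes named character vector of genomes.
#' @param min_len minimum contig length.
#' @return function(read table) -> named character contigs.
#' @export
make_fixture_assembler <- function(truth, genomes, min_len = 200L) {
  force(truth); force(genomes); force(min_len)
  function(reads) {
    perfect_assembly_fixture(truth, genomes, min_len = min_len,
                             read_ids = reads$id)$contigs
  }
}

#' Emit format-valid evidence tables consistent with truth
#'
#' Generates the classifier, m8 nucleotide-hit, depth and marker tables for
#' a set of contigs, consistent with their ground-truth origin, with
#' configurable label-noise and missingness rates — so binning is testable
#' without running the classification workflow or any external caller.
#'
#' @param contig_truth contig truth table from [perfect_assembly_fixture()].
#' @param gen output of [generate_genomes()].
#' @param read_truth optional read truth table used to compute true depth
#'   (depth table omitted when `NULL`).
#' @param noise probability that a contig's classifier/nt labels are
#'   swapped to a random wrong genome.
#' @param missingness probability that a contig has no classifier/nt/marker
#'   evidence at all.
#' @param seed RNG seed.
#' @return list with `classifier`, `nt_hits`, `depth`, `markers` tables.
#' @export
emit_evidence_fixtures <- function(contig_truth, gen, read_truth = NULL,
                                   noise = 0, missingness = 0, seed = 1L) {
  set.seed(seed)
  ct <- as.data.table(contig_truth)
  n <- nrow(ct)
  len <- ct$end - ct$start + 1L
  src <- ct$genome_id
  miss <- runif(n) < missingness
  noisy <- runif(n) < noise & !miss
  if (any(noisy)) {
    others <- vapply(src[noisy], function(g) {
      sample(setdiff(names(gen$genomes), g), 1L)
    }, "")
    src[noisy] <- others
  }
  taxid <- gen$taxids[src]

  classifier <- data.table(query_id = ct$contig_id, ref_id = paste0("ref|", src),
                           taxid = unname(taxid),
                           score = as.numeric(pmax(0L, len - 30L)),
                           second_best = 0,
                           hit_length = pmax(0L, as.integer(round(0.8 * len))),
                           query_length = len, num_matches = 1L)[!miss]

  nt_hits <- data.table(query_id = ct$contig_id,
                        subject_id = paste0("nt|", src),
                        pident = 97.0, aln_length = len,
                        mismatch = as.integer(round(0.03 * len)), gapopen = 0L,
                        q_start = 1L, q_end = len, s_start = 1L, s_end = len,
                        evalue = 1e-50, bitscore = round(1.9 * len, 1),
                        subject_taxid = unname(as.integer(taxid)))[!miss]

  depth <- NULL
  if (!is.null(read_truth)) {
    rt <- as.data.table(read_truth)
    depth_rows <- lapply(seq_len(n), function(i) {
      sub <- rt[genome_id == ct$genome_id[i]]
      ov <- IRanges::restrict(IRanges::IRanges(sub$start, sub$end),
                              start = ct$start[i], end = ct$end[i])
      data.table(contig_id = ct$contig_id[i], contig_len = len[i],
                 mean_depth = sum(IRanges::width(ov)) / len[i], depth_var = 0)
    })
    depth <- rbindlist(depth_rows)
  }

  mrows <- list()
  true_src <- ct$genome_id  # markers reflect the actual planted segments
  for (i in seq_len(n)) {
    if (miss[i]) next
    f <- gen$features[genome_id == true_src[i] & feature %in% c("SSU", "LSU", "MITO")]
    if (!nrow(f)) next
    ov_start <- pmax(f$start, ct$start[i])
    ov_end <- pmin(f$end, ct$end[i])
    keep <- ov_end - ov_start + 1L > 300L
    if (!any(keep)) next
    lab <- ifelse(f$feature[keep] == "MITO",
                  "Eukaryota;euk1;mitochondrion", "Eukaryota;euk1")
    mrows[[length(mrows) + 1L]] <- data.table(
      contig_id = ct$contig_id[i], marker = f$feature[keep], pident = 99.0,
      aln_length = as.integer(ov_end - ov_start + 1L)[keep], taxon_label = lab)
  }
  markers <- if (length(mrows)) rbindlist(mrows) else
    data.table(contig_id = character(), marker = character(), pident = numeric(),
               aln_length = integer(), taxon_label = character())

  list(classifier = classifier, nt_hits = nt_hits, depth = depth,
       markers = markers)
}
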