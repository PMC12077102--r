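# Pipeline wiring: validated configuration, subcommand dispatch, manifest.
#
# Subcommands compose the module functions over files; external tools
# (assembler, aligner, marker caller) are adapters discovered via the
# configuration, never hard dependencies — every adapter has a
# fixture-based stand-in so the whole pipeline runs with zero external
# binaries.

PIPELINE_KEYS <- c(
  "out_dir", "seed", "threads", "profile",
  "min_hit_length_read", "min_hit_length_contig",
  "evalue", "pident", "qcov", "min_contig_len",
  "min_qual", "min_read_len", "trim_window",
  "db_fasta", "db_taxids", "taxonomy",
  "reads_1", "reads_2", "contigs",
  "aln_hits_reads", "aln_hits_contigs",
  "depth", "markers", "nt_hits", "clusters", "mito_refs",
  "truth", "genomes", "assembler_cmd",
  "bins_dir", "ref_length", "scg_fasta",
  "sim_spec")

#' Pipeline configuration
#'
#' Builds and validates the configuration consumed by [run_pipeline()].
#' Unknown keys are rejected by name.
#'
#' @param ... configuration keys (see `eukmag:::PIPELINE_KEYS`).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1L && is.list(cfg[[1]]) && is.null(names(cfg))) cfg <- cfg[[1]]
  bad <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(bad)) {
    stop(sprintf("invalid config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  defaults <- list(out_dir = "eukmag_out", seed = 1234L, threads = 1L,
                   profile = "strict", min_contig_len = 1000L,
                   min_qual = 25, min_read_len = 40L, trim_window = 4L)
  cfg <- utils::modifyList(defaults, cfg)
  cfg$seed <- as.integer(cfg$seed)
  stopifnot(cfg$profile %in% c("strict", "lenient"))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring the [pipeline_config()] keys.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

config_thresholds <- function(cfg, mode) {
  routing_thresholds(mode = mode,
                     profile = cfg$profile,
                     min_hit_length = if (mode == "read") cfg$min_hit_length_read
                                      else cfg$min_hit_length_contig,
                     aln_max_evalue = cfg$evalue,
                     aln_min_pident = cfg$pident,
                     aln_min_qcov = cfg$qcov,
                     min_contig_len = cfg$min_contig_len)
}

write_manifest <- function(cfg, subcommand, outputs) {
  tmp <- tempfile()
  saveRDS(unclass(cfg), tmp)
  manifest <- list(subcommand = subcommand,
                   package = "eukmag",
                   version = as.character(utils::packageVersion("eukmag")),
                   seed = cfg$seed,
                   config = unclass(cfg),
                   config_md5 = unname(tools::md5sum(tmp)),
                   outputs = outputs)
  unlink(tmp)
  path <- file.path(cfg$out_dir, paste0("manifest_", subcommand, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}

load_db_from_config <- function(cfg) {
  if (is.null(cfg$db_fasta) || is.null(cfg$db_taxids)) {
    stop("classification requires 'db_fasta' and 'db_taxids' in the config",
         call. = FALSE)
  }
  refs <- read_fasta(cfg$db_fasta)
  tx <- fread(cfg$db_taxids, sep = "\t", header = TRUE)
  build_kmer_index(refs, setNames(as.integer(tx$taxid), tx$ref_id))
}

load_assembler_from_config <- function(cfg) {
  if (!is.null(cfg$assembler_cmd)) {
    cmd <- cfg$assembler_cmd
    return(function(reads) {
      dir <- tempfile("asm"); dir.create(dir)
      r1 <- file.path(dir, "r1.fastq"); r2 <- file.path(dir, "r2.fastq")
      write_fastq(reads, r1, r2)
      out_fa <- file.path(dir, "contigs.fasta")
      status <- system(sprintf(cmd, r1, r2, out_fa))
      if (status != 0L || !file.exists(out_fa)) {
        stop("external assembler adapter failed: ", cmd, call. = FALSE)
      }
      read_fasta(out_fa)
    })
  }
  if (!is.null(cfg$truth) && !is.null(cfg$genomes)) {
    truth <- fread(cfg$truth, sep = "\t", header = TRUE)
    genomes <- read_fasta(cfg$genomes)
    return(make_fixture_assembler(truth, genomes))
  }
  stop(paste("no assembler configured for stage 'assembly': set 'assembler_cmd'",
             "or provide 'truth' + 'genomes' for the fixture assembler"),
       call. = FALSE)
}

#' Run a pipeline subcommand
#'
#' Subcommands: `simulate` (write a mock community set), `read_prep`
#' (quality trim/split), `short` (two-round read workflow), `long`
#' (one-round contig workflow), `bin` (consensus binning), `evaluate`
#' (metrics against truth), `db-build` (validate and stage a mini
#' database). Every run writes a manifest (config, its hash, seed,
#' package version, outputs) under `out_dir`.
#'
#' @param subcommand one of the above.
#' @param config a [pipeline_config()].
#' @return invisibly, a list of produced artifact paths.
#' @export
run_pipeline <- function(subcommand = c("simulate", "read_prep", "short",
                                        "long", "bin", "evaluate", "db-build"),
                         config) {
  subcommand <- match.arg(subcommand)
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(subcommand,
    "simulate" = pipe_simulate(cfg),
    "read_prep" = pipe_read_prep(cfg),
    "short" = pipe_short(cfg),
    "long" = pipe_long(cfg),
    "bin" = pipe_bin(cfg),
    "evaluate" = pipe_evaluate(cfg),
    "db-build" = pipe_db_build(cfg))
  out$manifest <- write_manifest(cfg, subcommand, out)
  invisible(out)
}

pipe_simulate <- function(cfg) {
  spec <- do.call(mock_community_spec, as.list(cfg$sim_spec %||% list()))
  gen <- generate_genomes(spec, seed = cfg$seed)
  pools <- simulate_pools(gen, seed = cfg$seed)
  comms <- build_titration_series(pools$background, pools$euk_pool,
                                  spec$euk_read_levels, spec$replicates,
                                  seed = cfg$seed)
  d <- cfg$out_dir
  paths <- list(genomes = file.path(d, "genomes.fasta"),
                taxonomy = file.path(d, "taxonomy.tsv"),
                features = file.path(d, "features.tsv"))
  write_fasta(gen$genomes, paths$genomes)
  fwrite(gen$taxmap$nodes, paths$taxonomy, sep = "\t")
  fwrite(gen$features, paths$features, sep = "\t")
  for (cm in comms) {
    tag <- sprintf("lvl%d_rep%d", cm$level, cm$replicate)
    write_fastq(cm$reads, file.path(d, paste0(tag, "_R1.fastq")),
                file.path(d, paste0(tag, "_R2.fastq")))
    fwrite(cm$truth, file.path(d, paste0(tag, "_truth.tsv")), sep = "\t")
    paths[[tag]] <- file.path(d, paste0(tag, "_truth.tsv"))
  }
  paths
}

pipe_read_prep <- function(cfg) {
  reads <- read_fastq(cfg$reads_1, cfg$reads_2)
  prep <- prepare_reads(reads, min_qual = cfg$min_qual,
                        min_len = cfg$min_read_len, window = cfg$trim_window)
  d <- cfg$out_dir
  paths <- list(r1 = file.path(d, "prep_R1.fastq"),
                r2 = file.path(d, "prep_R2.fastq"),
                unpaired = file.path(d, "prep_unpaired.fastq"))
  write_fastq(prep$paired, paths$r1, paths$r2)
  write_fastq(prep$unpaired, paths$unpaired)
  paths
}

pipe_short <- function(cfg) {
  reads <- read_fastq(cfg$reads_1, cfg$reads_2)
  db <- load_db_from_config(cfg)
  taxmap <- read_taxonomy(cfg$taxonomy)
  assembler <- load_assembler_from_config(cfg)
  aln_r <- if (!is.null(cfg$aln_hits_reads)) read_tabular_hits(cfg$aln_hits_reads, "m8")
  aln_c <- if (!is.null(cfg$aln_hits_contigs)) read_tabular_hits(cfg$aln_hits_contigs, "m8")
  res <- run_short_workflow(reads, db, taxmap, assembler,
                            th_read = config_thresholds(cfg, "read"),
                            th_contig = config_thresholds(cfg, "contig"),
                            aln_hits_reads = aln_r, aln_hits_contigs = aln_c)
  d <- cfg$out_dir
  paths <- list(eunk = file.path(d, "eunk_contigs.fasta"),
                counts = file.path(d, "category_counts.tsv"))
  write_fasta(res$eunk_contigs, paths$eunk)
  counts <- rbind(data.table(round = "round1", category = TAX_CATEGORIES,
                             n = res$counts$round1),
                  data.table(round = "round2", category = TAX_CATEGORIES,
                             n = res$counts$round2))
  fwrite(counts, paths$counts, sep = "\t")
  paths
}

pipe_long <- function(cfg) {
  contigs <- read_fasta(cfg$contigs)
  db <- load_db_from_config(cfg)
  taxmap <- read_taxonomy(cfg$taxonomy)
  aln <- if (!is.null(cfg$aln_hits_contigs)) read_tabular_hits(cfg$aln_hits_contigs, "m8")
  res <- run_long_workflow(contigs, db, taxmap,
                           th = config_thresholds(cfg, "contig"),
                           aln_hits = aln)
  d <- cfg$out_dir
  paths <- list(eunk = file.path(d, "eunk_contigs.fasta"),
                counts = file.path(d, "category_counts.tsv"))
  write_fasta(res$eunk_contigs, paths$eunk)
  fwrite(data.table(round = "round1", category = TAX_CATEGORIES,
                    n = res$counts$round1), paths$counts, sep = "\t")
  paths
}

pipe_bin <- function(cfg) {
  contigs <- read_fasta(cfg$contigs)
  taxmap <- if (!is.null(cfg$taxonomy)) read_taxonomy(cfg$taxonomy)
  depth <- if (!is.null(cfg$depth)) {
    read_depth_table(cfg$depth)
  } else if (!is.null(cfg$reads_1)) {
    estimate_depth(read_fastq(cfg$reads_1, cfg$reads_2), contigs)
  } else {
    stop("binning requires 'depth' or 'reads_1' in the config", call. = FALSE)
  }
  markers <- if (!is.null(cfg$markers)) read_marker_table(cfg$markers)
  nt_hits <- if (!is.null(cfg$nt_hits)) read_tabular_hits(cfg$nt_hits, "m8")
  ev <- evidence_bundle(names(contigs), depth = depth, markers = markers,
                        nt_hits = nt_hits, taxmap = taxmap,
                        mito_refs = cfg$mito_refs %||% character(0))
  assignments <- if (!is.null(cfg$clusters)) {
    stopifnot(length(cfg$clusters) == 3L)
    mapply(read_cluster_tsv, cfg$clusters, c("k4", "k5", "k56"),
           SIMPLIFY = FALSE)
  }
  br <- run_binning(contigs, ev, assignments = assignments, seed = cfg$seed)
  d <- cfg$out_dir
  paths <- list(membership = file.path(d, "bin_membership.tsv"))
  write_bin_membership(bin_membership(br), paths$membership)
  for (b in names(br$nuclear_bins)) {
    paths[[b]] <- file.path(d, paste0(b, ".fasta"))
    write_fasta(contigs[br$nuclear_bins[[b]]], paths[[b]])
  }
  if (length(br$mito_bin)) {
    paths$mito <- file.path(d, "mito.fasta")
    write_fasta(contigs[br$mito_bin], paths$mito)
  }
  paths
}

pipe_evaluate <- function(cfg) {
  membership <- read_bin_membership(file.path(cfg$bins_dir, "bin_membership.tsv"))
  truth <- fread(cfg$truth, sep = "\t", header = TRUE)
  binned <- membership[bin_id != "unbinned", contig_id]
  truth_pos <- truth[category == "EUKARYOTE", contig_id]
  pr <- precision_recall(binned, truth_pos, truth$contig_id)
  report <- list(precision = pr$precision, recall = pr$recall,
                 counts = as.list(pr$counts))
  if (!is.null(cfg$ref_length)) {
    lens <- truth[contig_id %in% binned, end - start + 1L]
    ng <- ng50_lg50(lens, cfg$ref_length)
    report$ng50 <- ng$ng50
    report$lg50 <- ng$lg50
  }
  d <- cfg$out_dir
  paths <- list(report = file.path(d, "eval_report.json"))
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths
}

pipe_db_build <- function(cfg) {
  db <- load_db_from_config(cfg)
  d <- cfg$out_dir
  paths <- list(db_fasta = file.path(d, "db.fasta"),
                db_taxids = file.path(d, "db_taxids.tsv"),
                stats = file.path(d, "db_stats.json"))
  file.copy(cfg$db_fasta, paths$db_fasta, overwrite = TRUE)
  file.copy(cfg$db_taxids, paths$db_taxids, overwrite = TRUE)
  jsonlite::write_json(list(n_refs = length(db$ref_ids), k = db$k,
                            n_kmers = db$n_kmers),
                       paths$stats, auto_unbox = TRUE, digits = NA)
  paths
}

`%||%` <- function(a, b) if (is.null(a)) b else a
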