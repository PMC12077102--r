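# Supervised consensus binning.
#
# Three composition clusterings (4-mer, 5-mer, concatenated 5+6-mer) are
# combined with read-depth, rRNA/mitochondrial marker calls and
# nucleotide-alignment taxonomy. A contig enters the nuclear bin(s) only if
# it sits in a eukaryote-flagged cluster in at least two of the three
# clusterings, its depth does not exceed that of the SSU rRNA contig, its
# best nucleotide hit is not a strong prokaryote/virus match (>90% identity
# over >=1,000 aligned bp), and no evidence source contradicts a eukaryotic
# origin. Contigs with both a mitochondrial marker and a mitochondrial
# best hit form the mitochondrial bin, exempt from the depth cap.

#' Canonical k-mer composition vectors
#'
#' Strand-symmetric (canonical) k-mer frequencies; k-mers containing `N`
#' are skipped; each k block is L1-normalized independently, then blocks
#' are concatenated (so the `c(5, 6)` k-set is the mixed-k composition
#' space of the 5-6-mer clustering).
#'
#' @param contigs named character vector of contigs.
#' @param kset integer vector of k values (e.g. `4`, `5`, `c(5, 6)`).
#' @return numeric matrix, one row per contig.
#' @export
composition_vector <- function(contigs, kset) {
  if (any(nchar(contigs) < max(kset))) {
    stop(sprintf("all contigs must be at least %d bp for this k-set", max(kset)),
         call. = FALSE)
  }
  blocks <- lapply(as.integer(kset), function(k) {
    .canonical_kmer_freq(unname(contigs), k)
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- names(contigs)
  out
}

#' Construct a cluster assignment
#'
#' @param clustering_id one of `"k4"`, `"k5"`, `"k56"` (or any label for
#'   externally supplied clusterings).
#' @param labels named integer/character vector: contig id -> cluster label.
#' @param euk_flag optional named logical vector over cluster labels.
#' @export
cluster_assignment <- function(clustering_id, labels, euk_flag = NULL) {
  labels <- setNames(as.character(labels), names(labels))
  clusters <- sort(unique(labels))
  if (is.null(euk_flag)) euk_flag <- setNames(rep(FALSE, length(clusters)), clusters)
  structure(list(clustering_id = clustering_id, labels = labels,
                 euk_flag = euk_flag),
            class = "cluster_assignment")
}

#' Read externally produced cluster assignments from TSV
#'
#' TSV with header `contig_id cluster`, one file per clustering; lets real
#' binner output stand in for the built-in clusterer.
#'
#' @param path TSV file.
#' @param clustering_id label for the clustering.
#' @export
read_cluster_tsv <- function(path, clustering_id) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  cluster_assignment(clustering_id, setNames(dt$cluster, dt$contig_id))
}

#' Cluster contigs by composition
#'
#' The built-in stand-in for an external composition binner: features are
#' standardized, projected onto at most 10 principal components, and
#' partitioned by k-medoids, with the cluster count chosen by average
#' silhouette width over `k in 2..min(10, n-1)` (unless fixed). The
#' procedure is deterministic for a given input and seed.
#'
#' @param vectors composition matrix from [composition_vector()].
#' @param n_clusters optional fixed cluster count.
#' @param seed RNG seed (default 1234).
#' @param clustering_id label for the resulting assignment.
#' @return a [cluster_assignment()].
#' @export
cluster_contigs <- function(vectors, n_clusters = NULL, seed = 1234L,
                            clustering_id = "k") {
  n <- nrow(vectors)
  if (n < 2L) stop("clustering needs at least 2 contigs", call. = FALSE)
  ids <- rownames(vectors)
  sds <- apply(vectors, 2L, sd)
  if (all(sds == 0)) {
    warning("all composition vectors identical; returning a single cluster",
            call. = FALSE)
    return(cluster_assignment(clustering_id, setNames(rep("1", n), ids)))
  }
  if (n == 2L) {
    # pam needs k < n; two distinct contigs become two singletons
    return(cluster_assignment(clustering_id, setNames(c("1", "2"), ids)))
  }
  x <- scale(vectors[, sds > 0, drop = FALSE])
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  d <- min(10L, ncol(pc$x))
  proj <- pc$x[, seq_len(d), drop = FALSE]
  withr_seed <- function(expr) {
    if (exists(".Random.seed", globalenv())) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, globalenv()))
    }
    set.seed(seed)
    expr
  }
  fit_k <- function(k) cluster::pam(proj, k = k, pamonce = 5)
  if (!is.null(n_clusters)) {
    fit <- withr_seed(fit_k(as.integer(n_clusters)))
  } else {
    ks <- 2L:min(10L, n - 1L)
    fits <- withr_seed(lapply(ks, fit_k))
    sil <- vapply(fits, function(f) {
      if (is.null(f$silinfo)) -1 else f$silinfo$avg.width
    }, 0)
    fit <- fits[[which.max(sil)]]
  }
  cluster_assignment(clustering_id, setNames(as.character(fit$clustering), ids))
}

#' Estimate contig read depth with the k-mer assigner
#'
#' Each read is assigned to the contig maximizing k-mer coverage; reads
#' tied between contigs or matching nothing are dropped. The mean depth of
#' a contig is the summed length of its assigned reads divided by the
#' contig length — the same quantity a jgi depth table reports.
#'
#' @param reads read table.
#' @param contigs named character vector of contigs.
#' @param k k-mer size for the assignment index.
#' @return depth `data.table` (`contig_id`, `contig_len`, `mean_depth`,
#'   `depth_var`).
#' @export
estimate_depth <- function(reads, contigs, k = 31L) {
  out <- data.table(contig_id = names(contigs),
                    contig_len = unname(nchar(contigs)),
                    mean_depth = 0, depth_var = 0)
  if (nrow(reads) && length(contigs)) {
    db <- build_kmer_index(contigs, taxids = setNames(rep(1L, length(contigs)),
                                                      names(contigs)), k = k)
    hits <- classify_with_index(reads$seq, db, ids = reads$id)
    hits <- hits[num_matches == 1L]
    assigned <- hits[, .(bases = sum(as.numeric(query_length))), by = ref_id]
    i <- match(assigned$ref_id, out$contig_id)
    out[i[!is.na(i)], mean_depth := assigned$bases[!is.na(i)] / contig_len]
  }
  out[]
}

#' Filter raw marker calls
#'
#' Keeps calls with aligned length strictly greater than 300 bp and
#' identity strictly greater than 90%.
#'
#' @param calls marker-call `data.table` (see [read_marker_table()]).
#' @return filtered `data.table`.
#' @export
filter_marker_calls <- function(calls) {
  as.data.table(calls)[aln_length > 300L & pident > 90]
}

marker_is_euk <- function(taxon_label) {
  grepl("Eukary", taxon_label, ignore.case = TRUE)
}

#' Bundle the binning evidence layers
#'
#' Normalizes the four evidence layers the inclusion criteria consume:
#' per-contig depth (0 when absent), filtered marker calls, the best
#' nucleotide-alignment hit per contig with its routing category, and the
#' category assigned by the classification workflow.
#'
#' @param contig_ids character vector of all contigs under consideration.
#' @param depth depth table ([read_depth_table()] / [estimate_depth()]).
#' @param markers raw marker-call table; filtered through
#'   [filter_marker_calls()] unless `filter_markers = FALSE`.
#' @param nt_hits m8 alignment table of the contigs against a nucleotide
#'   reference collection.
#' @param routing a [classified_set()] or `data.table` (`id`, `category`).
#' @param taxmap [taxonomy_map()] used to categorize nucleotide hits.
#' @param mito_refs character vector of subject ids (and/or taxids) that are
#'   mitochondrial references.
#' @param acc2tax optional subject-id to taxid side table.
#' @param filter_markers apply the marker thresholds (default `TRUE`).
#' @return an `evidence_bundle` object.
#' @export
evidence_bundle <- function(contig_ids, depth = NULL, markers = NULL,
                            nt_hits = NULL, routing = NULL, taxmap = NULL,
                            mito_refs = character(0), acc2tax = NULL,
                            filter_markers = TRUE) {
  contig_ids <- as.character(contig_ids)
  d <- data.table(contig_id = contig_ids, contig_len = NA_integer_,
                  mean_depth = 0, depth_var = 0)
  if (!is.null(depth)) {
    depth <- as.data.table(depth)
    i <- match(contig_ids, depth$contig_id)
    d[!is.na(i), `:=`(contig_len = depth$contig_len[i[!is.na(i)]],
                      mean_depth = depth$mean_depth[i[!is.na(i)]],
                      depth_var = depth$depth_var[i[!is.na(i)]])]
  }
  mk <- if (is.null(markers)) {
    data.table(contig_id = character(), marker = character(), pident = numeric(),
               aln_length = integer(), taxon_label = character())
  } else {
    m <- as.data.table(markers)
    if (filter_markers) filter_marker_calls(m) else m
  }
  mk <- mk[contig_id %in% contig_ids]

  best <- data.table(contig_id = character(), subject_id = character(),
                     pident = numeric(), aln_length = integer(),
                     category = character(), mito = logical())
  if (!is.null(nt_hits) && nrow(nt_hits)) {
    h <- as.data.table(nt_hits)[query_id %in% contig_ids]
    if (nrow(h)) {
      setorder(h, query_id, -bitscore, evalue, subject_id)
      h <- h[, .SD[1L], by = query_id]
      if (!is.null(acc2tax)) {
        fill <- is.na(h$subject_taxid)
        h[fill, subject_taxid := as.integer(acc2tax[subject_id])]
      }
      cat <- if (is.null(taxmap)) rep("UNKNOWN", nrow(h)) else
        ifelse(is.na(h$subject_taxid), "UNKNOWN",
               categorize_taxid(h$subject_taxid, taxmap))
      best <- data.table(contig_id = h$query_id, subject_id = h$subject_id,
                         pident = h$pident, aln_length = h$aln_length,
                         category = cat,
                         mito = h$subject_id %in% mito_refs |
                                as.character(h$subject_taxid) %in% as.character(mito_refs))
    }
  }
  rt <- data.table(contig_id = contig_ids, category = "UNKNOWN")
  if (!is.null(routing)) {
    ra <- if (inherits(routing, "classified_set")) routing$assign else as.data.table(routing)
    i <- match(contig_ids, ra$id)
    rt[!is.na(i), category := ra$category[i[!is.na(i)]]]
  }
  structure(list(contig_ids = contig_ids, depth = d, markers = mk,
                 nt_best = best, routing = rt),
            class = "evidence_bundle")
}

# per-contig taxonomic label used for cluster flagging and criterion 4:
# routing category when informative, else the best nucleotide hit category
contig_labels <- function(evidence) {
  lab <- setNames(evidence$routing$category, evidence$routing$contig_id)
  unk <- lab == "UNKNOWN"
  i <- match(names(lab)[unk], evidence$nt_best$contig_id)
  lab[unk][!is.na(i)] <- evidence$nt_best$category[i[!is.na(i)]]
  lab
}

#' Flag potential eukaryotic clusters
#'
#' A cluster is flagged eukaryotic iff a strict majority of its
#' taxonomically labeled contigs (routing category, falling back to the
#' best nucleotide hit; `UNKNOWN` is uninformative) are `EUKARYOTE`, or it
#' contains a contig with a eukaryotic SSU marker call. Clusters with no
#' labeled contigs stay unflagged.
#'
#' @param assignment a [cluster_assignment()].
#' @param evidence an [evidence_bundle()].
#' @return the assignment with `euk_flag` set.
#' @export
flag_euk_clusters <- function(assignment, evidence) {
  lab <- contig_labels(evidence)
  ssu_euk <- evidence$markers[marker == "SSU" & marker_is_euk(taxon_label), contig_id]
  clusters <- sort(unique(assignment$labels))
  flag <- vapply(clusters, function(cl) {
    ids <- names(assignment$labels)[assignment$labels == cl]
    l <- lab[ids]
    l <- l[!is.na(l) & l != "UNKNOWN"]
    majority <- length(l) > 0 && sum(l == "EUKARYOTE") * 2L > length(l)
    majority || any(ids %in% ssu_euk)
  }, TRUE)
  cluster_assignment(assignment$clustering_id, assignment$labels,
                     setNames(flag, clusters))
}

#' Consensus membership across the three clusterings
#'
#' @param assignments list of exactly three flagged [cluster_assignment()]s.
#' @return character vector of contig ids sitting in a eukaryote-flagged
#'   cluster in at least two of the three clusterings.
#' @export
consensus_membership <- function(assignments) {
  if (length(assignments) != 3L) {
    stop("consensus requires exactly three clusterings", call. = FALSE)
  }
  votes <- lapply(assignments, function(a) {
    flagged <- names(a$euk_flag)[a$euk_flag]
    names(a$labels)[a$labels %in% flagged]
  })
  tab <- table(unlist(votes))
  names(tab)[tab >= 2L]
}

#' Flag mitochondrial contigs
#'
#' A contig joins the mitochondrial bin iff it has a `MITO` marker call AND
#' its best nucleotide hit is to a mitochondrial reference (the conjunction
#' of the two evidence sources). The mitochondrial bin is exempt from the
#' SSU depth cap.
#'
#' @param candidates character vector of contig ids to consider.
#' @param evidence an [evidence_bundle()].
#' @return character vector of mitochondrial contig ids.
#' @export
flag_mitochondrial <- function(candidates, evidence) {
  has_marker <- unique(evidence$markers[marker == "MITO", contig_id])
  mito_hit <- evidence$nt_best[mito == TRUE, contig_id]
  intersect(candidates, intersect(has_marker, mito_hit))
}

#' Apply the inclusion criteria to consensus candidates
#'
#' Rejects candidates whose depth strictly exceeds the SSU cap
#' (`DEPTH_GT_SSU`), whose best nucleotide hit is a prokaryote or virus
#' with identity > 90% AND aligned length >= 1,000 bp (`PROK_HIT`), or
#' whose evidence is taxonomically labeled but never eukaryotic
#' (`CONFLICTING_TAXONOMY`); contigs eukaryotic by any evidence source, or
#' entirely unlabeled, are retained.
#'
#' @param candidates character vector of contig ids (the consensus set).
#' @param evidence an [evidence_bundle()].
#' @param ssu_cap maximum mean depth among SSU-marker contigs of the
#'   candidate set; `NULL` skips the depth criterion with a warning.
#' @return list with `retained` (ids) and `rejected`
#'   (`data.table(contig_id, reason)`).
#' @export
apply_inclusion_criteria <- function(candidates, evidence, ssu_cap = NULL) {
  rejected <- data.table(contig_id = character(), reason = character())
  keep <- candidates

  if (is.null(ssu_cap)) {
    warning("no SSU-marker contig among candidates; depth-cap criterion skipped",
            call. = FALSE)
  } else {
    depth <- setNames(evidence$depth$mean_depth, evidence$depth$contig_id)
    bad <- keep[depth[keep] > ssu_cap]
    if (length(bad)) {
      rejected <- rbind(rejected, data.table(contig_id = bad, reason = "DEPTH_GT_SSU"))
      keep <- setdiff(keep, bad)
    }
  }

  nb <- evidence$nt_best
  prok <- nb[category %in% c("ARCHAEA", "BACTERIA", "VIRUS") &
             pident > 90 & aln_length >= 1000L, contig_id]
  bad <- intersect(keep, prok)
  if (length(bad)) {
    rejected <- rbind(rejected, data.table(contig_id = bad, reason = "PROK_HIT"))
    keep <- setdiff(keep, bad)
  }

  lab <- contig_labels(evidence)
  euk_marker <- unique(evidence$markers[marker_is_euk(taxon_label), contig_id])
  labeled <- !is.na(lab[keep]) & lab[keep] != "UNKNOWN"
  eukaryotic <- lab[keep] == "EUKARYOTE" | keep %in% euk_marker
  has_nonneuk_marker <- keep %in% unique(evidence$markers$contig_id) & !(keep %in% euk_marker)
  conflict <- keep[(labeled | has_nonneuk_marker) & !eukaryotic]
  if (length(conflict)) {
    rejected <- rbind(rejected, data.table(contig_id = conflict,
                                           reason = "CONFLICTING_TAXONOMY"))
    keep <- setdiff(keep, conflict)
  }
  list(retained = keep, rejected = rejected)
}

#' Construct a bin result
#'
#' @param nuclear_bins named list of contig-id vectors.
#' @param mito_bin character vector of mitochondrial contig ids.
#' @param rejected `data.table(contig_id, reason)`.
#' @param input_ids all contig ids the binning saw (partition check).
#' @export
bin_result <- function(nuclear_bins, mito_bin, rejected, input_ids) {
  all_binned <- c(unlist(nuclear_bins, use.names = FALSE), mito_bin,
                  rejected$contig_id)
  if (anyDuplicated(all_binned) || !setequal(all_binned, input_ids)) {
    stop("bin result does not partition the input contigs", call. = FALSE)
  }
  bad <- setdiff(unique(rejected$reason), BIN_REASONS)
  if (length(bad)) stop("unknown rejection reason: ", bad[1], call. = FALSE)
  structure(list(nuclear_bins = nuclear_bins, mito_bin = mito_bin,
                 rejected = rejected),
            class = "bin_result")
}

#' @export
print.bin_result <- function(x, ...) {
  cat(sprintf("<bin_result> %d nuclear bin(s) (%d contig(s)), %d mitochondrial contig(s), %d rejected\n",
              length(x$nuclear_bins), length(unlist(x$nuclear_bins)),
              length(x$mito_bin), nrow(x$rejected)))
  if (nrow(x$rejected)) {
    tab <- table(x$rejected$reason)
    cat("  rejections:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Flatten a bin result into a membership table
#'
#' @param br a [bin_result()].
#' @return `data.table(contig_id, bin_id, reason)`; rejected contigs have
#'   `bin_id = "unbinned"` and their reason code.
#' @export
bin_membership <- function(br) {
  rows <- list()
  for (b in names(br$nuclear_bins)) {
    if (length(br$nuclear_bins[[b]])) {
      rows[[length(rows) + 1L]] <- data.table(contig_id = br$nuclear_bins[[b]],
                                              bin_id = b, reason = "")
    }
  }
  if (length(br$mito_bin)) {
    rows[[length(rows) + 1L]] <- data.table(contig_id = br$mito_bin,
                                            bin_id = "mito", reason = "")
  }
  if (nrow(br$rejected)) {
    rows[[length(rows) + 1L]] <- data.table(contig_id = br$rejected$contig_id,
                                            bin_id = "unbinned",
                                            reason = br$rejected$reason)
  }
  if (!length(rows)) return(data.table(contig_id = character(),
                                       bin_id = character(), reason = character()))
  rbindlist(rows)
}

# group retained contigs into nuclear bins: contigs sharing a flagged
# cluster in >=2 of the 3 clusterings are connected; components are bins
group_nuclear_bins <- function(retained, assignments) {
  if (!length(retained)) return(list())
  if (is.null(assignments)) return(list(bin1 = retained))
  pair_counts <- new.env(parent = emptyenv())
  for (a in assignments) {
    flagged <- names(a$euk_flag)[a$euk_flag]
    for (cl in flagged) {
      ids <- sort(intersect(names(a$labels)[a$labels == cl], retained))
      if (length(ids) < 2L) next
      pr <- utils::combn(ids, 2L)
      keys <- paste(pr[1L, ], pr[2L, ], sep = "\r")
      for (k in keys) {
        assign(k, (get0(k, envir = pair_counts, ifnotfound = 0L)) + 1L,
               envir = pair_counts)
      }
    }
  }
  keys <- ls(pair_counts)
  counts <- vapply(keys, get, 0L, envir = pair_counts)
  edges <- do.call(rbind, strsplit(keys[counts >= 2L], "\r", fixed = TRUE))
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(retained)
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)
  groups <- split(retained, comp$membership[retained])
  groups <- groups[order(-vapply(groups, length, 0L),
                         vapply(groups, function(x) sort(x)[1L], ""))]
  setNames(groups, paste0("bin", seq_along(groups)))
}

#' Run the full binning workflow
#'
#' Computes (or accepts) the three composition clusterings, flags
#' eukaryotic clusters, takes the 2-of-3 consensus, separates the
#' mitochondrial bin (marker AND mitochondrial best hit; exempt from the
#' depth cap and the cluster consensus, since organelle composition and
#' depth differ from the nuclear genome by design), applies the depth-cap
#' / prokaryote-hit / taxonomy-conflict criteria, and groups the retained
#' contigs into nuclear bins by their shared flagged clusters.
#'
#' @param contigs named character vector of contigs (the EUnk set).
#' @param evidence an [evidence_bundle()] covering these contigs.
#' @param assignments optional list of three [cluster_assignment()]s
#'   (e.g. external binner output); computed from `contigs` when `NULL`.
#' @param seed RNG seed for the clusterings.
#' @param ssu_cap depth cap override; computed from the candidates' SSU
#'   contigs when `NULL`.
#' @return a [bin_result()].
#' @export
run_binning <- function(contigs, evidence, assignments = NULL, seed = 1234L,
                        ssu_cap = NULL) {
  ids <- names(contigs)
  if (is.null(assignments)) {
    ksets <- list(k4 = 4L, k5 = 5L, k56 = c(5L, 6L))
    assignments <- lapply(names(ksets), function(nm) {
      cluster_contigs(composition_vector(contigs, ksets[[nm]]),
                      seed = seed, clustering_id = nm)
    })
  }
  assignments <- lapply(assignments, flag_euk_clusters, evidence = evidence)
  consensus <- consensus_membership(assignments)

  mito <- flag_mitochondrial(ids, evidence)
  candidates <- setdiff(intersect(ids, consensus), mito)
  out_of_consensus <- setdiff(ids, c(consensus, mito))

  if (is.null(ssu_cap)) {
    ssu_ids <- intersect(unique(evidence$markers[marker == "SSU", contig_id]),
                         candidates)
    if (length(ssu_ids)) {
      depth <- setNames(evidence$depth$mean_depth, evidence$depth$contig_id)
      ssu_cap <- max(depth[ssu_ids])
    }
  }
  crit <- apply_inclusion_criteria(candidates, evidence, ssu_cap = ssu_cap)
  rejected <- rbind(crit$rejected,
                    data.table(contig_id = out_of_consensus,
                               reason = if (length(out_of_consensus)) "CONSENSUS_LT2" else character(0)))
  nuclear <- group_nuclear_bins(crit$retained, assignments)
  bin_result(nuclear, mito, rejected, ids)
}
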