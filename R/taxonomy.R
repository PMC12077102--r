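# Taxonomy handling and the built-in mini k-mer classifier.
#
# The classifier reproduces the semantics of k-mer LCA read classifiers
# (hit_length = query bases covered by matching k-mers, in bp) so that its
# output flows through the same routing thresholds as real classifier
# tables, without any external database.

SUPERKINGDOM_CATEGORY <- c(Archaea = "ARCHAEA", Bacteria = "BACTERIA",
                           Viruses = "VIRUS", Eukaryota = "EUKARYOTE")

#' Build a taxonomy map
#'
#' @param nodes `data.frame` with columns `taxid`, `parent`, `rank`, `name`.
#'   Must contain a root node (its own parent). Category mapping walks the
#'   parent chain to a `superkingdom`-ranked node named `Archaea`,
#'   `Bacteria`, `Viruses` or `Eukaryota`.
#' @return a `taxonomy_map` object.
#' @export
taxonomy_map <- function(nodes) {
  nodes <- as.data.table(nodes)[, .(taxid = as.integer(taxid),
                                    parent = as.integer(parent),
                                    rank = as.character(rank),
                                    name = as.character(name))]
  if (anyDuplicated(nodes$taxid)) stop("duplicate taxids in taxonomy", call. = FALSE)
  obj <- structure(list(nodes = nodes, cache = new.env(parent = emptyenv())),
                   class = "taxonomy_map")
  # validate rootedness / acyclicity by categorizing everything once
  invisible(category_table(obj))
  obj
}

#' Read a taxonomy from NCBI-style dump subsets or a flat TSV
#'
#' With one argument, expects a flat TSV with header
#' `taxid parent rank name`. With two, expects `nodes` / `names` dump
#' subsets (`taxid | parent | rank`, `taxid | name`).
#'
#' @param nodes path to the flat TSV or nodes dump subset.
#' @param names optional path to the names dump subset.
#' @return a `taxonomy_map`.
#' @export
read_taxonomy <- function(nodes, names = NULL) {
  if (is.null(names)) {
    dt <- fread(nodes, sep = "\t", header = TRUE)
    return(taxonomy_map(dt))
  }
  nd <- fread(nodes, sep = "|", header = FALSE, strip.white = TRUE)
  nm <- fread(names, sep = "|", header = FALSE, strip.white = TRUE)
  dt <- data.table(taxid = as.integer(nd$V1), parent = as.integer(nd$V2),
                   rank = trimws(as.character(nd$V3)))
  nm <- data.table(taxid = as.integer(nm$V1), name = trimws(as.character(nm$V2)))
  dt <- nm[dt, on = "taxid"]
  taxonomy_map(dt[, .(taxid, parent, rank, name)])
}

#' @export
print.taxonomy_map <- function(x, ...) {
  cat(sprintf("<taxonomy_map> %d taxa, %d superkingdoms\n", nrow(x$nodes),
              sum(x$nodes$rank == "superkingdom")))
  invisible(x)
}

# full taxid -> category lookup table, computed once and cached
category_table <- function(taxmap) {
  cached <- get0("categories", envir = taxmap$cache)
  if (!is.null(cached)) return(cached)
  nodes <- taxmap$nodes
  n <- nrow(nodes)
  cat <- rep(NA_character_, n)
  sk <- nodes$rank == "superkingdom" & nodes$name %in% names(SUPERKINGDOM_CATEGORY)
  cat[sk] <- SUPERKINGDOM_CATEGORY[nodes$name[sk]]
  parent_idx <- match(nodes$parent, nodes$taxid)
  # self-parent nodes are roots; walking past one without meeting a
  # superkingdom yields UNKNOWN
  is_root <- !is.na(parent_idx) & parent_idx == seq_len(n)
  cat[is.na(cat) & is_root] <- "UNKNOWN"
  cur <- parent_idx
  for (step in seq_len(n + 1L)) {
    todo <- is.na(cat) & !is.na(cur)
    if (!any(todo)) break
    if (step > n) stop("taxonomy contains a cycle or is not rooted", call. = FALSE)
    hit <- todo & !is.na(cat[cur])
    cat[hit] <- cat[cur[hit]]
    cur[todo & !hit] <- parent_idx[cur[todo & !hit]]
  }
  cat[is.na(cat)] <- "UNKNOWN"
  out <- setNames(cat, as.character(nodes$taxid))
  assign("categories", out, envir = taxmap$cache)
  out
}

#' Map taxids to the five routing categories
#'
#' Walks parent links to the superkingdom node. Taxid 0 (unclassified),
#' taxids absent from the map, and lineages that never reach a recognized
#' superkingdom all map to `UNKNOWN` — the function is total by design.
#'
#' @param taxid integer vector of taxids.
#' @param taxmap a [taxonomy_map()].
#' @return character vector over
#'   `c("ARCHAEA","BACTERIA","VIRUS","EUKARYOTE","UNKNOWN")`.
#' @export
categorize_taxid <- function(taxid, taxmap) {
  lut <- category_table(taxmap)
  out <- unname(lut[as.character(as.integer(taxid))])
  out[is.na(out)] <- "UNKNOWN"
  out
}

# uncached reference walk, used as the memoization cross-check
categorize_taxid_walk <- function(taxid, taxmap) {
  nodes <- taxmap$nodes
  vapply(as.integer(taxid), function(tx) {
    seen <- integer(0)
    while (TRUE) {
      i <- match(tx, nodes$taxid)
      if (is.na(i) || tx %in% seen) return("UNKNOWN")
      if (nodes$rank[i] == "superkingdom" &&
          nodes$name[i] %in% names(SUPERKINGDOM_CATEGORY)) {
        return(unname(SUPERKINGDOM_CATEGORY[nodes$name[i]]))
      }
      if (nodes$parent[i] == tx) return("UNKNOWN")
      seen <- c(seen, tx)
      tx <- nodes$parent[i]
    }
  }, "")
}

#' Build a mini k-mer reference database
#'
#' Indexes every canonical k-mer (lexicographic minimum of a k-mer and its
#' reverse complement) of every reference; k-mers containing `N` are
#' skipped. This is the package's built-in classifier database, a documented
#' stand-in for an external classifier index.
#'
#' @param refs named character vector (or `DNAStringSet`) of reference
#'   sequences; names are the reference ids.
#' @param taxids integer vector of taxids, one per reference (recycled from
#'   a named vector matched by ref id if named).
#' @param k odd k-mer size in 11..31 (default 31).
#' @return a `mini_ref_db` object.
#' @export
build_kmer_index <- function(refs, taxids, k = 31L) {
  if (methods::is(refs, "DNAStringSet")) {
    refs <- setNames(as.character(refs), names(refs))
  }
  if (length(refs) == 0L) stop("refs must be non-empty", call. = FALSE)
  if (is.null(names(refs)) || anyDuplicated(names(refs))) {
    stop("refs must have unique names", call. = FALSE)
  }
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L || k > 31L) {
    stop("k must be odd and in 11..31", call. = FALSE)
  }
  if (!is.null(names(taxids))) taxids <- taxids[names(refs)]
  taxids <- as.integer(taxids)
  if (length(taxids) != length(refs) || anyNA(taxids)) {
    stop("taxids must supply one taxid per reference", call. = FALSE)
  }
  if (all(nchar(refs) < k)) {
    stop(sprintf("all reference sequences are shorter than k=%d; empty index", k),
         call. = FALSE)
  }
  ptr <- .kmer_index_build(unname(toupper(refs)), k)
  structure(list(ptr = ptr, ref_ids = names(refs), taxids = taxids, k = k,
                 n_kmers = attr(ptr, "n_kmers")),
            class = "mini_ref_db")
}

#' @export
print.mini_ref_db <- function(x, ...) {
  cat(sprintf("<mini_ref_db> %d reference(s), k=%d, %.0f distinct canonical k-mers\n",
              length(x$ref_ids), x$k, x$n_kmers))
  invisible(x)
}

#' Classify sequences against a mini reference database
#'
#' For each query and candidate reference, `hit_length` is the number of
#' query bases covered by at least one matching k-mer (union of matched
#' k-mer intervals). The best reference(s) by `hit_length` are reported, one
#' row per tied reference, with `num_matches` the tie count — mirroring how
#' k-mer classifiers emit one line per equal-score hit. Queries with no
#' matching k-mer get `taxid = 0`, `hit_length = 0`, `num_matches = 0`.
#'
#' @param seqs character vector of query sequences; names (or `ids`) are
#'   the query ids.
#' @param db a [build_kmer_index()] database.
#' @param ids optional query ids overriding `names(seqs)`.
#' @return classifier hit `data.table` (`query_id`, `ref_id`, `taxid`,
#'   `score`, `second_best`, `hit_length`, `query_length`, `num_matches`).
#' @export
classify_with_index <- function(seqs, db, ids = names(seqs)) {
  stopifnot(inherits(db, "mini_ref_db"))
  if (is.null(ids)) ids <- paste0("q", seq_along(seqs))
  res <- .kmer_index_classify(db$ptr, unname(toupper(seqs)))
  hit <- res$ref > 0L
  data.table(query_id = ids[res$query],
             ref_id = ifelse(hit, db$ref_ids[ifelse(hit, res$ref, 1L)], "unclassified"),
             taxid = ifelse(hit, db$taxids[ifelse(hit, res$ref, 1L)], 0L),
             score = as.numeric(res$hit_length),
             second_best = 0,
             hit_length = res$hit_length,
             query_length = res$query_length,
             num_matches = res$num_matches)
}
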