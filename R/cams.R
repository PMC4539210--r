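#' Configuration for the CAMS clustering search
#'
#' @param subsets number of disjoint gene subsets `S` the shuffled gene
#'   list is split into before gene clustering (default 10).
#' @param clusters integer vector of cluster counts `C` tried on each gene
#'   subset (default `2:10`, i.e. 9 clustering solutions per subset).
#' @param shuffles how many times the whole gene list is reshuffled and
#'   re-partitioned (default 3).
#' @param min_patients candidate subtypes must contain strictly more
#'   patients than this threshold (default 20).
#' @param linkage,metric hierarchical clustering parameters; complete
#'   linkage with the Euclidean metric throughout.
#' @param seed integer seed driving the gene-list shuffles.
#' @return list of class `cams_config`.
#' @export
cams_config <- function(subsets = 10, clusters = 2:10, shuffles = 3,
                        min_patients = 20, linkage = "complete",
                        metric = "euclidean", seed = 1) {
  if (subsets < 1) abort("`subsets` must be >= 1")
  if (any(clusters < 2)) abort("all `clusters` entries must be >= 2")
  if (min_patients < 4) abort("`min_patients` must be >= 4 (two per group)")
  structure(list(subsets = as.integer(subsets),
                 clusters = as.integer(clusters),
                 shuffles = as.integer(shuffles),
                 min_patients = as.integer(min_patients),
                 linkage = linkage, metric = metric,
                 seed = as.integer(seed)),
            class = "cams_config")
}

#' Partition the gene list into disjoint subsets
#'
#' Shuffles the gene list (deterministically by seed) and splits it into
#' `S` contiguous blocks of `floor(m/S)` genes, distributing the remainder
#' one-per-block from the first block.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param S number of subsets.
#' @param seed shuffle seed.
#' @return list of `S` disjoint character vectors whose union is the input.
#' @export
#' @examples
#' lengths(partition_genes(paste0("g", 1:11), S = 3, seed = 1))  # 4 4 3
partition_genes <- function(gene_ids, S, seed = 1) {
  m <- length(gene_ids)
  if (S > m) abort("`S` exceeds the number of genes")
  shuffled <- withr::with_seed(seed, sample(gene_ids))
  sizes <- rep(m %/% S, S) + (seq_len(S) <= m %% S)
  split(shuffled, rep(seq_len(S), sizes))
}

hclust_rows <- function(M) hclust(dist(M, method = "euclidean"),
                                  method = "complete")

#' Cluster a gene subset into c groups
#'
#' Agglomerative hierarchical clustering (complete linkage, Euclidean
#' distance across patients) of the subset's expression rows, cut into
#' exactly `c` clusters.  Zero-variance genes are dropped first (their
#' pairwise distances are degenerate).
#'
#' @param expr genes-by-patients matrix with gene rownames.
#' @param subset character vector of gene ids to cluster.
#' @param c number of clusters.
#' @return list of `c` character vectors of gene ids.
#' @export
cluster_genes <- function(expr, subset, c) {
  sub <- expr[subset, , drop = FALSE]
  keep <- apply(sub, 1, var) > 0
  sub <- sub[keep, , drop = FALSE]
  if (c > nrow(sub)) abort("`c` exceeds the number of (informative) genes")
  ct <- cutree(hclust_rows(sub), k = c)
  unname(split(rownames(sub), ct))
}

#' Cluster patients on one gene-set and cut by subtype size
#'
#' Patients are clustered hierarchically on the submatrix restricted to the
#' gene-set (complete linkage, Euclidean distance over genes).  The
#' dendrogram is scanned from the highest cut (2 groups) downward and the
#' first level at which at least one cluster is a proper subset of the
#' cohort with strictly more than `min_patients` members is kept; all
#' qualifying clusters at that level are returned as candidate subtypes.
#'
#' @param expr genes-by-patients matrix with patient colnames.
#' @param gene_ids the subtype-identifier gene-set.
#' @param min_patients strict size threshold.
#' @return list of character vectors of patient ids (possibly empty when no
#'   level qualifies).
#' @export
cluster_patients <- function(expr, gene_ids, min_patients) {
  n <- ncol(expr)
  if (n < 2) abort("need at least 2 patients")
  if (min_patients >= n - 1) return(list())
  sub <- t(expr[gene_ids, , drop = FALSE])
  hc <- hclust_rows(sub)
  for (k in 2:(n - 1)) {
    ct <- cutree(hc, k = k)
    sizes <- tabulate(ct, k)
    qual <- which(sizes > min_patients & sizes < n)
    if (length(qual) > 0) {
      return(unname(map(qual, function(q) colnames(expr)[ct == q])))
    }
  }
  list()
}

#' Enumerate candidate molecular subtypes (the CAMS search)
#'
#' The full two-stage search: for each gene-list shuffle, partition the
#' genes into `S` disjoint subsets; hierarchically cluster each subset and
#' cut at every cluster count in `C`; use each resulting gene-cluster as a
#' subtype identifier and cluster the patients on it, keeping the
#' size-thresholded clusters as candidate subtypes.  Candidates with
#' identical patient sets are deduplicated (first provenance kept).
#'
#' @param expr genes-by-patients matrix with dimnames.
#' @param config a [cams_config()].
#' @return tibble with one row per candidate subtype:
#'   `subtype_id`, `n_genes`, `n_patients`, list-columns `gene_ids` and
#'   `patient_ids`, and provenance columns `shuffle`, `subset`, `c`,
#'   `cluster`.
#' @export
enumerate_subtypes <- function(expr, config = cams_config()) {
  stopifnot(inherits(config, "cams_config"))
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("g%05d", seq_len(nrow(expr)))
  if (is.null(colnames(expr))) colnames(expr) <- sprintf("p%04d", seq_len(ncol(expr)))
  informative <- rownames(expr)[apply(expr, 1, var) > 0]
  shuffle_seeds <- withr::with_seed(config$seed,
    sample.int(.Machine$integer.max, config$shuffles))

  rows <- list()
  for (s in seq_len(config$shuffles)) {
    parts <- partition_genes(informative, config$subsets, shuffle_seeds[s])
    for (b in seq_along(parts)) {
      sub <- expr[parts[[b]], , drop = FALSE]
      hc <- hclust_rows(sub)
      for (cc in config$clusters) {
        if (cc > nrow(sub)) next
        ct <- cutree(hc, k = cc)
        gene_clusters <- unname(split(rownames(sub), ct))
        for (g in seq_along(gene_clusters)) {
          pats <- cluster_patients(expr, gene_clusters[[g]],
                                   config$min_patients)
          for (ps in pats) {
            rows[[length(rows) + 1]] <- tibble(
              gene_ids = list(gene_clusters[[g]]),
              patient_ids = list(ps),
              shuffle = s, subset = b, c = cc, cluster = g
            )
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(subtype_id = character(), n_genes = integer(),
                  n_patients = integer(), gene_ids = list(),
                  patient_ids = list(), shuffle = integer(),
                  subset = integer(), c = integer(), cluster = integer()))
  }
  out <- list_rbind(rows)
  key <- map_chr(out$patient_ids, function(p) paste(sort(p), collapse = "|"))
  out <- out[!duplicated(key), , drop = FALSE]
  mutate(out,
         subtype_id = sprintf("S%03d", row_number()),
         n_genes = lengths(.data$gene_ids),
         n_patients = lengths(.data$patient_ids),
         .before = 1)
}

#' Jaccard overlap between two patient sets
#'
#' Evaluation helper for planted-subtype recovery: size of the intersection
#' over size of the union.
#'
#' @param a,b character vectors of patient ids.
#' @return scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
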