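# PSI and presence/absence AS profiles across samples, correlation and
# binary distance matrices, and feature-bootstrap hierarchical clustering.

#' Filter a PSI matrix for variable events
#'
#' Keeps rows with `0.05 < PSI < 0.95` in at least one sample.
#'
#' @param mat numeric matrix (rows = events, columns = samples), entries
#'   in `[0, 1]` or `NA`.
#' @return filtered matrix.
#' @export
filter_psi_matrix <- function(mat) {
  if (!nrow(mat)) return(mat)
  keep <- apply(mat, 1L, function(r)
    any(r > 0.05 & r < 0.95, na.rm = TRUE))
  mat[keep, , drop = FALSE]
}

#' Sample-by-sample correlation matrix
#'
#' `spearman_psi`: Spearman correlation of PSI profiles, pairwise-complete.
#' `pearson_log_expression`: rows (genes) are first filtered to expressed
#' genes (TPM > 5 in at least one sample), then Pearson correlation of
#' `log2(TPM + 1)`.
#'
#' @param mat numeric matrix (rows = events or genes, columns = samples).
#' @param method `"spearman_psi"` or `"pearson_log_expression"`.
#' @return symmetric correlation matrix with unit diagonal (`NA` where
#'   undefined).
#' @export
correlation_matrix <- function(mat,
                               method = c("spearman_psi",
                                          "pearson_log_expression")) {
  method <- match.arg(method)
  if (ncol(mat) < 2L) stopf("need at least 2 samples")
  if (method == "pearson_log_expression") {
    keep <- apply(mat, 1L, function(r) any(r > 5, na.rm = TRUE))
    mat <- log2(mat[keep, , drop = FALSE] + 1)
    cm <- suppressWarnings(cor(mat, method = "pearson",
                               use = "pairwise.complete.obs"))
  } else {
    cm <- suppressWarnings(cor(mat, method = "spearman",
                               use = "pairwise.complete.obs"))
  }
  n_complete <- crossprod(!is.na(mat))
  cm[n_complete < 3L] <- NA_real_
  diag(cm) <- 1
  cm
}

#' Asymmetric binary (Jaccard) distance between species columns
#'
#' For each pair of columns, among rows where at least one entry is 1, the
#' fraction where exactly one is 1.  Pairs with no informative rows are
#' `NA`.
#'
#' @param mat binary matrix (rows = orthologous genes or junctions,
#'   columns = species/samples).  Rows that are all zero are dropped
#'   first.
#' @return symmetric distance matrix with zero diagonal.
#' @export
binary_distance <- function(mat) {
  mat <- mat[rowSums(mat, na.rm = TRUE) > 0, , drop = FALSE]
  n <- ncol(mat)
  d <- matrix(NA_real_, n, n, dimnames = list(colnames(mat),
                                              colnames(mat)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- mat[, i]; b <- mat[, j]
    inf <- which((a == 1 | b == 1) & !is.na(a) & !is.na(b))
    d[i, j] <- if (length(inf)) mean(a[inf] != b[inf]) else NA_real_
  }
  diag(d) <- 0
  d
}

#' Bootstrap hierarchical clustering of samples
#'
#' Average-linkage (UPGMA) clustering on `1 - Spearman correlation` of the
#' profile matrix (or on the asymmetric binary distance for binary data);
#' node support is the fraction of feature-bootstrap replicates whose
#' clustering reproduces the node's leaf set.
#'
#' @param mat profile matrix (rows = features, columns = samples).
#' @param distance `"spearman"` (PSI profiles) or `"binary"`.
#' @param n_bootstrap number of replicates (default 1000).
#' @param seed integer seed.
#' @return list of class `bootstrap_clust` with `hclust`, `support`
#'   (named by node leaf sets), `n_bootstrap`.
#' @export
bootstrap_cluster <- function(mat, distance = c("spearman", "binary"),
                              n_bootstrap = 1000L, seed = 1L) {
  distance <- match.arg(distance)
  if (ncol(mat) < 3L) stopf("need at least 3 samples to cluster")
  if (nrow(mat) < 2L) stopf("too few features to resample")
  dist_of <- function(m) {
    if (distance == "binary") {
      as.dist(binary_distance(m))
    } else {
      cm <- suppressWarnings(cor(m, method = "spearman",
                                 use = "pairwise.complete.obs"))
      cm[is.na(cm)] <- 0
      as.dist(1 - cm)
    }
  }
  d0 <- dist_of(mat)
  hc <- hclust(d0, method = "average")
  node_sets <- .hclust_leaf_sets(hc)
  counts <- setNames(numeric(length(node_sets)), names(node_sets))
  with_seed(derive_seed(seed, 71L), {
    for (b in seq_len(n_bootstrap)) {
      rows <- sample(nrow(mat), replace = TRUE)
      db <- tryCatch(dist_of(mat[rows, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(db) || anyNA(db)) next
      hb <- hclust(db, method = "average")
      sets_b <- .hclust_leaf_sets(hb)
      hitset <- names(counts) %in% names(sets_b)
      counts[hitset] <- counts[hitset] + 1
    }
  })
  structure(list(hclust = hc, support = counts / n_bootstrap,
                 node_sets = node_sets,
                 n_bootstrap = as.integer(n_bootstrap)),
            class = "bootstrap_clust")
}

# canonical string per internal node: sorted leaf labels
.hclust_leaf_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  out <- character(nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[k, ]
    leaves <- c()
    for (kid in kids) {
      leaves <- c(leaves, if (kid < 0) hc$labels[-kid] else sets[[kid]])
    }
    sets[[k]] <- leaves
    out[k] <- paste(sort(leaves), collapse = "|")
  }
  setNames(sets, out)
}

#' Support for a given set of leaves
#'
#' @param clust result of [bootstrap_cluster()].
#' @param leaves character vector of sample names.
#' @return bootstrap support in `[0, 1]`, or `NA` when the node is not in
#'   the reference tree.
#' @export
node_support <- function(clust, leaves) {
  key <- paste(sort(leaves), collapse = "|")
  if (!key %in% names(clust$support)) return(NA_real_)
  unname(clust$support[key])
}

#' Build the cross-sample PSI matrix from classified events
#'
#' @param events list of classified event tables (or one combined table
#'   with a `sample_id` column).
#' @return numeric matrix: rows are event keys
#'   (`gene:type:inclusion-junction`), columns samples, entries PSI.
#' @export
psi_matrix <- function(events) {
  if (is.list(events) && !is.data.frame(events))
    events <- do.call(rbind, events)
  keys <- unique(events$event_id)
  samples <- unique(events$sample_id)
  m <- matrix(NA_real_, length(keys), length(samples),
              dimnames = list(keys, samples))
  for (k in seq_len(nrow(events))) {
    m[events$event_id[k], events$sample_id[k]] <- events$psi[k]
  }
  m
}

#' PSI matrix over conserved AS events across two species' samples
#'
#' Rows are matched EEJ pairs labeled `conserved`; columns are all samples
#' of both species; entries are the per-sample PSI of the event anchored
#' at each species' authentic junction.
#'
#' @param labels output of [call_conservation()].
#' @param events_a,events_b classified event tables (all samples).
#' @return numeric matrix of PSI values (NA where undefined).
#' @export
conserved_psi_matrix <- function(labels, events_a, events_b) {
  cons <- labels[labels$state == "conserved", , drop = FALSE]
  samples_a <- unique(events_a$sample_id)
  samples_b <- unique(events_b$sample_id)
  m <- matrix(NA_real_, nrow(cons), length(samples_a) + length(samples_b),
              dimnames = list(paste(cons$junction_a, cons$junction_b,
                                    sep = "|"),
                              c(samples_a, samples_b)))
  fill <- function(events, jids, samples, col_off) {
    ekey <- sprintf("%s:%d-%d:%s", events$chrom, events$excl_start,
                    events$excl_end, events$strand)
    for (r in seq_along(jids)) {
      hit <- which(ekey == jids[r])
      for (h in hit) {
        ci <- match(events$sample_id[h], samples)
        if (!is.na(ci)) m[r, col_off + ci] <<- events$psi[h]
      }
    }
  }
  fill(events_a, cons$junction_a, samples_a, 0L)
  fill(events_b, cons$junction_b, samples_b, length(samples_a))
  m
}

#' Build the binary AS presence/absence matrix over orthologous genes
#'
#' @param gene_as named list: one logical vector per species mapping gene
#'   id to AS presence.
#' @param ortholog_map data frame with one column of gene ids per species
#'   (named by species).
#' @return binary matrix, rows = ortholog groups, columns = species; rows
#'   that are all zero are removed.
#' @export
binary_as_matrix <- function(gene_as, ortholog_map) {
  sp <- names(gene_as)
  m <- sapply(sp, function(s) {
    v <- gene_as[[s]][ortholog_map[[s]]]
    as.integer(!is.na(v) & v)
  })
  rownames(m) <- apply(ortholog_map[, sp, drop = FALSE], 1L, paste,
                       collapse = "|")
  m[rowSums(m) > 0, , drop = FALSE]
}
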