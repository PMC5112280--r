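# RPTM normalization, abundance selection, and complete-linkage clustering
# of temporal expression profiles into archetypal classes A-D.

#' Normalize a count matrix to reads per ten million (RPTM)
#'
#' `rptm = count / library_total * scale_factor`.  The conventional unit is
#' reads per ten million (`scale_factor = 1e7`); a reads-per-million scale
#' (1e6) is equally supported since both appear in the literature for the
#' same acronym.
#'
#' @param counts numeric matrix, miRNAs x libraries.
#' @param library_totals clean-read totals per library (positive).
#' @param scale_factor normalization scale (default 1e7).
#' @return numeric matrix of RPTM values with the input dimnames and
#'   attributes `library_totals`, `scale_factor`.
#' @export
normalize_rptm <- function(counts, library_totals, scale_factor = 1e7) {
  counts <- as.matrix(counts)
  if (length(library_totals) != ncol(counts)) {
    stopf("library_totals must have one entry per column")
  }
  if (any(library_totals <= 0)) stopf("library totals must be positive")
  rptm <- sweep(counts, 2L, library_totals, "/") * scale_factor
  attr(rptm, "library_totals") <- library_totals
  attr(rptm, "scale_factor") <- scale_factor
  rptm
}

#' Select strongly expressed miRNAs
#'
#' Keeps rows whose maximum across libraries exceeds `min_rptm` (strict,
#' "more than"), the abundance selection used before expression clustering.
#'
#' @param rptm matrix from [normalize_rptm()].
#' @param min_rptm selection threshold.
#' @return the filtered matrix with attributes `n_kept` and `n_dropped`.
#' @export
select_expressed <- function(rptm, min_rptm = 100) {
  keep <- apply(rptm, 1L, max) > min_rptm
  out <- rptm[keep, , drop = FALSE]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Log2 fold change of each library against the profile mean
#'
#' @param rptm RPTM matrix.
#' @param pseudocount added to numerator and denominator to tame zeros.
#' @return matrix of `log2((rptm + pc) / (rowmean + pc))`.
#' @export
logfc_vs_mean <- function(rptm, pseudocount = 1) {
  log2(sweep(rptm + pseudocount, 1L, rowMeans(rptm) + pseudocount, "/"))
}

#' Cluster expression profiles and label temporal classes
#'
#' Profiles (log2 fold change versus the row mean) are clustered by
#' complete-linkage agglomeration and the tree is cut into `k` clusters.
#' Each cluster is labelled from its centroid: `A` if strictly decreasing
#' over the time course, `D` if strictly increasing, `B` if peaking at the
#' second library, `C` if peaking at the second or third library and not
#' already the `B` cluster, otherwise `unclassified`.  Ties are broken
#' deterministically by first row membership.
#'
#' @param rptm RPTM matrix (>= k rows, ordered library columns).
#' @param k number of clusters.
#' @param pseudocount see [logfc_vs_mean()].
#' @param distance `"euclidean"` on log fold changes (default) or
#'   `"pearson"` (1 - correlation).
#' @return list: `class` (named per-row labels), `cluster` (integer
#'   memberships), `hclust`, `logfc`, `centroids`, `newick` (dendrogram as
#'   Newick text).
#' @export
cluster_profiles <- function(rptm, k = 4L, pseudocount = 1,
                             distance = c("euclidean", "pearson")) {
  distance <- match.arg(distance)
  if (nrow(rptm) < k) {
    stopf("clustering requires at least k = %d rows, got %d", k, nrow(rptm))
  }
  if (is.null(rownames(rptm))) {
    rownames(rptm) <- paste0("row", seq_len(nrow(rptm)))
  }
  lfc <- logfc_vs_mean(rptm, pseudocount)
  d <- if (distance == "euclidean") {
    dist(lfc)
  } else {
    as.dist(1 - cor(t(lfc)))
  }
  hc <- hclust(d, method = "complete")
  cl <- cutree(hc, k = k)
  centroids <- t(vapply(seq_len(k), function(g) {
    colMeans(lfc[cl == g, , drop = FALSE])
  }, numeric(ncol(lfc))))
  lab <- rep("unclassified", k)
  for (g in seq_len(k)) {
    v <- centroids[g, ]
    if (all(diff(v) < 0)) lab[g] <- "A"
    else if (all(diff(v) > 0)) lab[g] <- "D"
  }
  first_row <- vapply(seq_len(k), function(g) min(which(cl == g)), 0L)
  open <- which(lab == "unclassified")
  peaks <- vapply(open, function(g) which.max(centroids[g, ]), 0L)
  b_cand <- open[peaks == 2L][order(first_row[open[peaks == 2L]])]
  if (length(b_cand)) lab[b_cand[1]] <- "B"
  for (g in setdiff(open, b_cand[1])) {
    if (which.max(centroids[g, ]) %in% c(2L, 3L)) lab[g] <- "C"
  }
  list(
    class = setNames(lab[cl], rownames(rptm)),
    cluster = setNames(cl, rownames(rptm)),
    hclust = hc,
    logfc = lfc,
    centroids = centroids,
    newick = ape::write.tree(ape::as.phylo(hc))
  )
}
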