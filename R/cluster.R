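#' Normalize a model population for clustering
#'
#' Replaces each parameter by its log2 fold-change versus the base set, so
#' distances are scale-free rather than dominated by the large time
#' constants. The pinned `u_o` column (base value 0, constant across the
#' population) is dropped; the inverse transform restores it.
#'
#' @param mat Population matrix (individuals x 28, canonical order) or a
#'   `ga_result`.
#' @param base Reference `bofc_params`.
#' @return Normalized matrix (individuals x 27) with attributes `base` and
#'   `dropped`.
#' @export
normalize_population <- function(mat, base = base_params()) {
  if (inherits(mat, "ga_result")) mat <- mat$population
  stopifnot(is.matrix(mat), ncol(mat) == 28)
  b <- bofc_params(base)
  keep <- setdiff(param_names(), .fixed_params)
  if (any(b[keep] <= 0))
    stop("non-positive base entry for: ",
         paste(keep[b[keep] <= 0], collapse = ", "))
  sub <- mat[, keep, drop = FALSE]
  if (any(sub <= 0))
    stop("non-positive parameter value(s) in the population")
  nm <- log2(sweep(sub, 2, as.numeric(b[keep]), `/`))
  attr(nm, "base") <- b
  attr(nm, "dropped") <- .fixed_params
  nm
}

#' @rdname normalize_population
#' @param nmat A normalized matrix from `normalize_population()`.
#' @export
denormalize_population <- function(nmat, base = attr(nmat, "base")) {
  b <- bofc_params(base)
  keep <- colnames(nmat)
  out <- matrix(rep(as.numeric(b), each = nrow(nmat)), nrow = nrow(nmat),
                dimnames = list(NULL, param_names()))
  out[, keep] <- sweep(2^nmat, 2, as.numeric(b[keep]), `*`)
  out
}

#' Agglomerative hierarchical clustering of a model population
#'
#' Euclidean distances in normalized (log2 fold-change) parameter space,
#' average linkage by default; the cophenetic correlation coefficient
#' (Pearson correlation between original and dendrogram-implied distances)
#' summarizes how faithfully the tree represents the population geometry.
#'
#' @param nmat Normalized population matrix.
#' @param method Linkage method (passed to [stats::hclust()]).
#' @return A `linkage_tree`: list with `hclust`, `merges` (data frame),
#'   `cophenetic_cc`, `method`, `n`.
#' @export
ahc_linkage <- function(nmat, method = "average") {
  stopifnot(is.matrix(nmat), nrow(nmat) >= 2)
  d <- dist(nmat)
  hc <- hclust(d, method = method)
  cc <- if (all(d == 0)) NA_real_ else suppressWarnings(cor(d, cophenetic(hc)))
  merges <- data.frame(a = hc$merge[, 1], b = hc$merge[, 2],
                       height = hc$height)
  structure(list(hclust = hc, merges = merges,
                 cophenetic_cc = cc, method = method, n = nrow(nmat),
                 degenerate = all(d == 0)),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %s linkage, n = %d, cophenetic cc = %s\n",
              x$method, x$n,
              if (is.na(x$cophenetic_cc)) "undefined (all distances 0)"
              else sprintf("%.3f", x$cophenetic_cc)))
  invisible(x)
}

#' Cut the dendrogram into the k most dissimilar clusters
#'
#' Cuts at the (k - 1) highest merge heights (ties resolved by the
#' deterministic merge order of the tree). Clusters are relabelled in
#' decreasing size order and centroids are arithmetic means in normalized
#' space, de-normalized for output.
#'
#' @param tree A `linkage_tree`.
#' @param nmat The normalized matrix the tree was built from.
#' @param k Number of clusters (2 <= k <= n).
#' @return A `cluster_cut`: list with `k`, `membership` (size-ranked
#'   labels), `sizes` (descending), `centroids_normalized`, `centroids`
#'   (matrix, canonical 28 columns).
#' @export
cut_top <- function(tree, nmat, k) {
  stopifnot(inherits(tree, "linkage_tree"), k >= 2, k <= tree$n)
  raw <- cutree(tree$hclust, k = k)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  mem <- unname(relabel[as.character(raw)])
  cen_n <- t(vapply(seq_len(k), function(g)
    colMeans(nmat[mem == g, , drop = FALSE]), numeric(ncol(nmat))))
  colnames(cen_n) <- colnames(nmat)
  base <- attr(nmat, "base")
  if (is.null(base)) base <- base_params()  # subsetting drops attributes
  attr(cen_n, "base") <- base
  cen <- denormalize_population(cen_n, base = base)
  structure(list(k = k, membership = mem,
                 sizes = as.integer(sizes),
                 centroids_normalized = cen_n, centroids = cen),
            class = "cluster_cut")
}

#' @export
print.cluster_cut <- function(x, ...) {
  cat(sprintf("<cluster_cut> k = %d, sizes: %s\n", x$k,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Percentile-constrained subset of a population
#'
#' Keeps rows whose every parameter lies within the two-sided
#' `[100 - p, p]` percentile band of that parameter's marginal distribution
#' across the population — the sensitivity analysis guarding the clustering
#' against extreme parameter values.
#'
#' @param nmat Normalized (or raw) population matrix.
#' @param p Percentile in (50, 100].
#' @return The retained rows (attributes preserved), with attribute
#'   `kept_rows` giving their original indices.
#' @export
percentile_constrain <- function(nmat, p) {
  stopifnot(is.matrix(nmat), p > 50, p <= 100)
  lo <- apply(nmat, 2, quantile, probs = (100 - p) / 100)
  hi <- apply(nmat, 2, quantile, probs = p / 100)
  keep <- rep(TRUE, nrow(nmat))
  for (j in seq_len(ncol(nmat)))
    keep <- keep & nmat[, j] >= lo[j] & nmat[, j] <= hi[j]
  if (!any(keep)) stop("percentile constraint removed every model")
  out <- nmat[keep, , drop = FALSE]
  attr(out, "base") <- attr(nmat, "base")
  attr(out, "dropped") <- attr(nmat, "dropped")
  attr(out, "kept_rows") <- which(keep)
  out
}

#' Export a dendrogram as Newick text
#'
#' @param tree A `linkage_tree`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick_tree <- function(tree, path) {
  stopifnot(inherits(tree, "linkage_tree"))
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
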