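#' Per-mode NSD histograms by group
#'
#' Bins the 12 NSD amplitude distributions separately for each group
#' (axial ligand, protein function or fold), after an optional
#' resolution filter. Counts are conserved: for every mode the counts
#' summed over groups and bins equal the number of rows passing the
#' filter.
#'
#' @param features data.frame or matrix with the 12 mode columns (from
#'   [nsd_table()]).
#' @param groups Factor or character vector, one label per row.
#' @param resolution Optional numeric vector of per-row resolutions
#'   (Angstrom).
#' @param resolution_max Keep rows with resolution <= this threshold;
#'   must lie within the supported slider range \[1.4, 8.2\] A. Rows
#'   with NA resolution are kept only when no filter is requested.
#' @param breaks Histogram breaks passed to [hist()] (default 20).
#' @return Object of class `nsd_histograms`: list `bins` (per mode, per
#'   group: `breaks`, `counts`), `n_used`, `n_total`. Empty selections
#'   give an object with `n_used = 0`, not an error.
#' @export
nsd_histograms <- function(features, groups, resolution = NULL,
                           resolution_max = NULL, breaks = 20) {
  x <- as.data.frame(features)[, mode_names(), drop = FALSE]
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(x))
  keep <- rep(TRUE, nrow(x))
  if (!is.null(resolution_max)) {
    if (resolution_max < 1.4 || resolution_max > 8.2)
      stop("resolution_max must lie in [1.4, 8.2] Angstrom")
    if (is.null(resolution))
      stop("resolution values required for a resolution filter")
    keep <- !is.na(resolution) & resolution <= resolution_max
  }
  x <- x[keep, , drop = FALSE]
  g <- droplevels(groups[keep])
  out <- list(bins = list(), n_used = nrow(x), n_total = length(keep))
  if (!nrow(x)) {
    out$status <- "empty selection"
    return(structure(out, class = "nsd_histograms"))
  }
  for (m in mode_names()) {
    rng <- range(x[[m]])
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(1e-6, abs(rng[1]))
    br <- seq(rng[1], rng[2], length.out = breaks + 1)
    out$bins[[m]] <- lapply(split(x[[m]], g), function(v) {
      h <- graphics::hist(v, breaks = br, plot = FALSE,
                          include.lowest = TRUE)
      list(breaks = h$breaks, counts = h$counts)
    })
  }
  structure(out, class = "nsd_histograms")
}

#' PCA of fitted heme coordinates
#'
#' Iteratively superposes all structures onto their mean (fit to the
#' current mean, recompute the mean, repeat until the mean moves less
#' than `tol` RMSD or `max_iter` is reached), then eigendecomposes the
#' covariance of the selected atom coordinates. Eigenvectors are
#' exportable as 25-atom displacements; contribution ratios and the
#' inner products of the leading eigenvectors with the saddling,
#' ruffling and doming modes are reported.
#'
#' @param coords n x 75 matrix of skeleton coordinates (atom-major
#'   x,y,z; e.g. rows built with `xyz_to_vec`), or a list of
#'   `heme_entry` objects.
#' @param ref A `porphyrin_ref` used for the initial orientation.
#' @param basis A `mode_basis` (for the mode inner products).
#' @param fit_atoms,pca_atoms Character vectors of atom names (subsets
#'   of the 25); defaults: all.
#' @param ncomp Number of components to report (default 10).
#' @param tol Mean-convergence threshold (Angstrom RMSD), default 1e-6.
#' @param max_iter Maximum fit-to-mean iterations, default 50.
#' @return Object of class `pca_result`: `mean` (25 x 3), `rotation`
#'   (eigenvectors, columns), `contribution` (ratios), `scores`
#'   (projections of each heme on the components), `mode_overlap`
#'   (ncomp x 3 inner products with saddling/ruffling/doming),
#'   `iterations`.
#' @export
pca_coordinates <- function(coords, ref, basis, fit_atoms = porphyrin_atoms(),
                            pca_atoms = porphyrin_atoms(), ncomp = 10,
                            tol = 1e-6, max_iter = 50) {
  X <- coords_matrix(coords)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 structures")
  fit_atoms <- match.arg(fit_atoms, porphyrin_atoms(), several.ok = TRUE)
  pca_atoms <- match.arg(pca_atoms, porphyrin_atoms(), several.ok = TRUE)
  fit_idx <- match(fit_atoms, porphyrin_atoms())
  pca_idx <- match(pca_atoms, porphyrin_atoms())
  col_idx <- function(at) as.vector(t(outer(at, 1:3,
                                            function(i, k) 3 * (i - 1) + k)))
  pca_cols <- col_idx(pca_idx)

  ## iterative fit to the mean; the mean is initialized from the first
  ## structure's frame
  mean_xyz <- vec_to_xyz(X[1, ])
  it <- 0
  repeat {
    it <- it + 1
    for (i in seq_len(n)) {
      xi <- vec_to_xyz(X[i, ])
      s <- superpose_subset(xi, mean_xyz, fit_idx)
      X[i, ] <- xyz_to_vec(s)
    }
    new_mean <- vec_to_xyz(colMeans(X))
    shift <- sqrt(mean(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    if (shift < tol || it >= max_iter) break
  }

  Xp <- X[, pca_cols, drop = FALSE]
  ctr <- colMeans(Xp)
  Xc <- sweep(Xp, 2, ctr)
  C <- crossprod(Xc) / (n - 1)
  e <- eigen(C, symmetric = TRUE)
  ncomp <- min(ncomp, ncol(Xp), n - 1)
  vals <- pmax(e$values, 0)
  contribution <- vals / sum(vals)
  rot <- e$vectors
  scores <- Xc %*% rot

  ## inner products with the saddling/ruffling/doming modes restricted
  ## to the PCA atoms (renormalized on the subset)
  ov <- matrix(NA_real_, ncomp, 3,
               dimnames = list(paste0("PC", seq_len(ncomp)),
                               c("saddling", "ruffling", "doming")))
  for (j in seq_len(3)) {
    mv <- basis$vectors[pca_cols, colnames(ov)[j]]
    nv <- sqrt(sum(mv^2))
    if (nv > 1e-12)
      ov[, j] <- as.vector(crossprod(rot[, seq_len(ncomp), drop = FALSE],
                                     mv / nv))
  }
  structure(list(mean = mean_xyz, rotation = rot,
                 contribution = contribution[seq_len(ncomp)],
                 scores = scores[, seq_len(ncomp), drop = FALSE],
                 mode_overlap = ov, iterations = it,
                 pca_atoms = pca_atoms, fit_atoms = fit_atoms),
            class = "pca_result")
}

## fit xi onto target using only the given atom rows, return all rows moved
superpose_subset <- function(xi, target, idx) {
  cx <- colMeans(xi[idx, , drop = FALSE])
  cy <- colMeans(target[idx, , drop = FALSE])
  C <- crossprod(sweep(xi[idx, , drop = FALSE], 2, cx),
                 sweep(target[idx, , drop = FALSE], 2, cy))
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(xi, 2, cx) %*% t(R), 2, cy, "+")
}

coords_matrix <- function(coords) {
  if (is.list(coords) && !is.matrix(coords))
    coords <- t(vapply(coords,
                       function(h) xyz_to_vec(skeleton_xyz(h)), numeric(75)))
  as.matrix(coords)
}

#' Linear discriminant analysis on the 12 NSD amplitudes
#'
#' Two-class discriminant with a shared (pooled) covariance: the
#' direction `w = S_pooled^-1 (mu2 - mu1)`, normalized. When the pooled
#' covariance is rank-deficient a ridge term (1e-6 x trace/12 on the
#' diagonal) is added and reported via the `regularized` flag. The
#' direction is also expressed as a 75-component displacement, the
#' corresponding linear combination of the 12 mode vectors.
#'
#' @param features n x 12 matrix/data.frame of NSD amplitudes.
#' @param groups Two-level factor (or coercible), one label per row;
#'   each level needs >= 2 rows.
#' @param basis A `mode_basis`.
#' @return Object of class `lda_result`: `direction` (named length-12
#'   unit vector), `displacement` (length 75, unit), `scores`
#'   (projections), `groups`, `group_means` (projected),
#'   `threshold` (midpoint decision value), `accuracy` (resubstitution
#'   fraction correct), `regularized`.
#' @export
lda_nsd <- function(features, groups, basis) {
  x <- as.matrix(as.data.frame(features)[, mode_names(), drop = FALSE])
  g <- droplevels(as.factor(groups))
  if (nlevels(g) != 2) stop("exactly two groups are required")
  if (any(table(g) < 2)) stop("each group needs at least 2 rows")
  x1 <- x[g == levels(g)[1], , drop = FALSE]
  x2 <- x[g == levels(g)[2], , drop = FALSE]
  s1 <- stats::cov(x1); s2 <- stats::cov(x2)
  n1 <- nrow(x1); n2 <- nrow(x2)
  sp <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
  regularized <- FALSE
  if (rcond_sym(sp) < 1e-10) {
    sp <- sp + diag(1e-6 * sum(diag(sp)) / ncol(sp), ncol(sp))
    regularized <- TRUE
  }
  w <- solve(sp, colMeans(x2) - colMeans(x1))
  w <- w / sqrt(sum(w^2))
  names(w) <- mode_names()
  scores <- as.vector(x %*% w)
  m1 <- mean(scores[g == levels(g)[1]])
  m2 <- mean(scores[g == levels(g)[2]])
  thr <- (m1 + m2) / 2
  pred <- ifelse((scores > thr) == (m2 > m1), levels(g)[2], levels(g)[1])
  disp <- as.vector(basis$vectors %*% w)
  disp <- disp / sqrt(sum(disp^2))
  structure(list(direction = w, displacement = disp, scores = scores,
                 groups = g, group_means = c(m1, m2), threshold = thr,
                 accuracy = mean(pred == as.character(g)),
                 regularized = regularized),
            class = "lda_result")
}

rcond_sym <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) 0 else min(abs(ev)) / max(abs(ev))
}

#' Cluster hemes on their NSD amplitudes (CAN)
#'
#' Cluster analysis with NSD: partitions the rows of the feature
#' matrix with one of four methods -- K-means, spectral clustering,
#' agglomerative (Ward) clustering or a Gaussian mixture -- always
#' using the number of target groups as the number of clusters. A
#' cluster x group contingency table (the numeric form of the heat
#' map) is returned. All methods are deterministic given `seed`.
#'
#' @param features n x 12 matrix/data.frame of NSD amplitudes.
#' @param groups Factor of target labels (defines k and the table).
#' @param method One of "kmeans", "spectral", "agglomerative", "gmm".
#' @param seed Integer seed (default 0) applied locally.
#' @return Object of class `clustering_result`: `method`, `k`,
#'   `labels` (integer cluster per row), `contingency` (k x groups
#'   table).
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_nsd <- function(features, groups,
                        method = c("kmeans", "spectral", "agglomerative",
                                   "gmm"),
                        seed = 0) {
  method <- match.arg(method)
  x <- as.matrix(as.data.frame(features)[, mode_names(), drop = FALSE])
  g <- droplevels(as.factor(groups))
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 target groups")
  if (nrow(x) < k) stop("fewer rows than clusters")
  labels <- withr_seed(seed, function() {
    switch(method,
      kmeans = stats::kmeans(x, centers = k, nstart = 10,
                             iter.max = 100)$cluster,
      spectral = as.integer(kernlab::specc(x, centers = k)),
      agglomerative = stats::cutree(stats::hclust(stats::dist(x),
                                                  method = "ward.D2"), k),
      gmm = Mclust(x, G = k, verbose = FALSE)$classification)
  })
  if (is.null(labels) || length(labels) != nrow(x))
    stop("clustering failed (", method, "): degenerate feature matrix?")
  structure(list(method = method, k = k, labels = as.integer(labels),
                 contingency = table(cluster = labels, group = g)),
            class = "clustering_result")
}

#' Export a 75-component displacement (eigenvector, feature vector) as xyz
#'
#' Writes label dx dy dz rows in the canonical 25-atom order, the same
#' format [save_mode_basis()] uses for one block; suitable for the PCA
#' eigenvectors, the LDA feature vector, or a mean structure.
#'
#' @param v Numeric vector of length 75 (atom-major), or a 25 x 3 matrix.
#' @param path Output path.
#' @param name Header tag written on the first line.
#' @return `path`, invisibly.
#' @export
export_displacement_xyz <- function(v, path, name = "displacement") {
  m <- if (is.matrix(v)) v else vec_to_xyz(v)
  writeLines(c(sprintf("mode %s", name),
               sprintf("%-4s %20.17f %20.17f %20.17f",
                       porphyrin_atoms(), m[, 1], m[, 2], m[, 3])), path)
  invisible(path)
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("CAN clustering (", x$method, "), k = ", x$k, "\n", sep = "")
  print(x$contingency)
  invisible(x)
}
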