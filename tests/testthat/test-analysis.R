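## synthetic NSD feature matrix: two groups offset along one mode
two_group_features <- function(n_per = 30, mode = "saddling", delta = 0.5,
                               sigma = 0.05, seed0 = 1000) {
  ref <- test_ref(); basis <- test_basis()
  amps <- c(rep(delta, n_per), rep(-delta, n_per))
  feats <- t(vapply(seq_along(amps), function(i)
    nsd_pipeline(make_distorted_heme(stats::setNames(amps[i], mode),
                                     ref, basis, sigma = sigma,
                                     seed = seed0 + i), ref, basis)$d,
    numeric(12)))
  list(features = as.data.frame(feats),
       groups = factor(rep(c("plus", "minus"), each = n_per),
                       levels = c("plus", "minus")))
}

test_that("histograms conserve counts and separate offset groups", {
  tg <- two_group_features(n_per = 25)
  hh <- nsd_histograms(tg$features, tg$groups)
  expect_identical(hh$n_used, 50L)
  for (m in mode_names()) {
    tot <- sum(vapply(hh$bins[[m]], function(b) sum(b$counts), 0))
    expect_equal(tot, 50)
  }
  ## group means along the injected mode differ by about 2 * delta
  mplus <- mean(tg$features$saddling[tg$groups == "plus"])
  mminus <- mean(tg$features$saddling[tg$groups == "minus"])
  expect_equal(mplus - mminus, 1.0, tolerance = 0.05)
})

test_that("the resolution filter keeps only entries at or below the threshold", {
  tg <- two_group_features(n_per = 10)
  res <- rep(c(1.5, 2.5), 10)
  hh <- nsd_histograms(tg$features, tg$groups, resolution = res,
                       resolution_max = 2.0)
  expect_identical(hh$n_used, 10L)
  expect_error(nsd_histograms(tg$features, tg$groups, resolution = res,
                              resolution_max = 9), "1.4")
})

test_that("an empty selection returns a status, not an error", {
  tg <- two_group_features(n_per = 5)
  hh <- nsd_histograms(tg$features, tg$groups,
                       resolution = rep(5, 10), resolution_max = 1.5)
  expect_identical(hh$n_used, 0L)
  expect_identical(hh$status, "empty selection")
})

test_that("all-zero distortions land in a single bin for every mode", {
  feats <- as.data.frame(matrix(0, 8, 12))
  names(feats) <- mode_names()
  hh <- nsd_histograms(feats, rep("g", 8))
  for (m in mode_names()) {
    counts <- hh$bins[[m]]$g$counts
    expect_identical(sum(counts > 0), 1L)
    expect_identical(sum(counts), 8L)
  }
})

test_that("one-factor PCA concentrates variance on PC1 aligned with the mode", {
  ref <- test_ref(); basis <- test_basis()
  set.seed(100)
  hemes <- lapply(rnorm(30, 0, 0.2), function(a)
    make_distorted_heme(c(saddling = a), ref, basis))
  p <- pca_coordinates(hemes, ref, basis)
  expect_gte(p$contribution[1], 0.99)
  expect_gte(abs(p$mode_overlap["PC1", "saddling"]), 0.99)
  ## eigenvector orthonormality and variance conservation
  expect_lt(max(abs(crossprod(p$rotation) - diag(ncol(p$rotation)))), 1e-8)
  ## the mean structure projects to the origin of PC space
  expect_lt(max(abs(colMeans(p$scores))), 1e-10)
})

test_that("two orthogonal injected modes split contribution by variance ratio", {
  ref <- test_ref(); basis <- test_basis()
  set.seed(101)
  a_sad <- rnorm(60, 0, 0.2)          # variance 4x
  a_ruf <- rnorm(60, 0, 0.1)
  hemes <- Map(function(s, r)
    make_distorted_heme(c(saddling = s, ruffling = r), ref, basis),
    a_sad, a_ruf)
  p <- pca_coordinates(hemes, ref, basis)
  top2 <- p$contribution[1:2] / sum(p$contribution[1:2])
  obs_ratio <- stats::var(a_sad) / (stats::var(a_sad) + stats::var(a_ruf))
  expect_equal(top2[1], obs_ratio, tolerance = 0.02)
})

test_that("PCA honors atom subsets and rank preconditions", {
  ref <- test_ref(); basis <- test_basis()
  set.seed(102)
  hemes <- lapply(rnorm(8, 0, 0.2), function(a)
    make_distorted_heme(c(doming = a), ref, basis))
  p <- pca_coordinates(hemes, ref, basis,
                       pca_atoms = c("FE", "NA", "NB", "NC", "ND"))
  expect_length(p$contribution, min(10, 15, 7))
  expect_error(pca_coordinates(hemes[1], ref, basis), "at least 2")
})

test_that("LDA separates opposed saddling groups through the saddling direction", {
  ## the direction estimate carries sampling noise of order sqrt(p/n),
  ## so the dominance check uses a larger sample than the accuracy check
  tg <- two_group_features(n_per = 100, delta = 0.5, sigma = 0.05)
  l <- lda_nsd(tg$features, tg$groups, test_basis())
  expect_equal(l$accuracy, 1.0)
  expect_gte(abs(l$direction["saddling"]), 0.95)
  expect_equal(sum(l$direction^2), 1, tolerance = 1e-9)
  expect_equal(sum(l$displacement^2), 1, tolerance = 1e-9)
})

test_that("LDA recovers the known discriminant of two simulated Gaussians", {
  ## two spherical 12-d Gaussians separated along a known direction:
  ## the pooled-covariance discriminant must align with it at n = 500
  set.seed(55)
  n <- 500
  truth <- rep(0, 12); truth[3] <- 1   # doming axis
  x <- matrix(rnorm(2 * n * 12, 0, 0.05), 2 * n, 12)
  x[seq_len(n), 3] <- x[seq_len(n), 3] + 0.5
  x[n + seq_len(n), 3] <- x[n + seq_len(n), 3] - 0.5
  colnames(x) <- mode_names()
  l <- lda_nsd(as.data.frame(x), rep(c("hi", "lo"), each = n), test_basis())
  expect_gte(abs(sum(l$direction * truth)), 0.99)
})

test_that("LDA on relabeled identical data shows no group separation", {
  ref <- test_ref(); basis <- test_basis()
  feats <- t(vapply(1:40, function(i)
    nsd_pipeline(make_distorted_heme(c(ruffling = 0.1), ref, basis,
                                     sigma = 0.05, seed = 2000 + i),
                 ref, basis)$d, numeric(12)))
  l <- lda_nsd(as.data.frame(feats), rep(c("a", "b"), 20), basis)
  ## projected group means differ by far less than the score spread
  expect_lt(abs(diff(l$group_means)), 2 * stats::sd(l$scores))
})

test_that("the LDA direction is scale-equivariant and matches MASS::lda", {
  skip_if_not_installed("MASS")
  tg <- two_group_features(n_per = 30)
  basis <- test_basis()
  l1 <- lda_nsd(tg$features, tg$groups, basis)
  l2 <- lda_nsd(tg$features * 2, tg$groups, basis)
  expect_gte(abs(sum(l1$direction * l2$direction)), 0.999)
  m <- MASS::lda(tg$features, grouping = tg$groups)
  w_mass <- m$scaling[, 1] / sqrt(sum(m$scaling[, 1]^2))
  expect_gte(abs(sum(l1$direction * w_mass)), 0.999)
})

test_that("degenerate pooled covariance triggers the reported ridge fallback", {
  basis <- test_basis()
  feats <- as.data.frame(matrix(0, 10, 12))
  names(feats) <- mode_names()
  feats$saddling <- c(rnorm(5, 1, 1e-4), rnorm(5, -1, 1e-4))
  l <- lda_nsd(feats, rep(c("a", "b"), each = 5), basis)
  expect_true(l$regularized)
  expect_equal(l$accuracy, 1.0)
})

test_that("well-separated blobs are recovered by all four clustering methods", {
  tg <- two_group_features(n_per = 30, delta = 0.5, sigma = 0.05)
  for (m in c("kmeans", "spectral", "agglomerative", "gmm")) {
    cl <- cluster_nsd(tg$features, tg$groups, m)
    expect_identical(cl$k, 2L)
    expect_identical(length(unique(cl$labels)), 2L)
    ct <- cl$contingency
    agree <- max(sum(diag(ct)), ct[1, 2] + ct[2, 1]) / sum(ct)
    expect_gte(agree, 0.99)
    ## counts are conserved
    expect_identical(sum(ct), 60L)
  }
})

test_that("a single tight blob forced to k = 2 still conserves counts", {
  ref <- test_ref(); basis <- test_basis()
  feats <- t(vapply(1:24, function(i)
    nsd_pipeline(make_distorted_heme(c(doming = 0.2), ref, basis,
                                     sigma = 0.03, seed = 3000 + i),
                 ref, basis)$d, numeric(12)))
  cl <- cluster_nsd(as.data.frame(feats), rep(c("x", "y"), 12), "kmeans")
  expect_identical(sum(cl$contingency), 24L)
  expect_identical(length(cl$labels), 24L)
})

test_that("clustering is deterministic for a fixed seed and rejects bad input", {
  tg <- two_group_features(n_per = 15)
  l1 <- cluster_nsd(tg$features, tg$groups, "kmeans", seed = 0)
  l2 <- cluster_nsd(tg$features, tg$groups, "kmeans", seed = 0)
  expect_identical(l1$labels, l2$labels)
  expect_error(cluster_nsd(tg$features, tg$groups, "dbscan"))
  expect_error(cluster_nsd(tg$features[1, , drop = FALSE], tg$groups[1]),
               "at least 2")
})

test_that("displacements export to xyz in canonical order", {
  basis <- test_basis()
  tf <- withr::local_tempfile(fileext = ".xyz")
  export_displacement_xyz(basis$vectors[, "doming"], tf, name = "doming")
  lines <- readLines(tf)
  expect_identical(length(lines), 26L)
  expect_match(lines[1], "doming")
  expect_match(lines[2], "^FE")
})
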