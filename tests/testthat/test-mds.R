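test_that("leading-logFC distance reproduces hand-computed RMS values", {
  # 2 genes, absolute differences {1, 3}
  m <- matrix(c(0, 0, 1, 3), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(leading_logfc_distance(m, top = 2)["s1", "s2"], sqrt(5))
  expect_equal(leading_logfc_distance(m, top = 1)["s1", "s2"], 3)
  # identical columns are at distance zero
  m2 <- m[, c(1, 1)]; colnames(m2) <- c("a", "b")
  expect_equal(leading_logfc_distance(m2, top = 2)["a", "b"], 0)
})

test_that("leading-logFC distance matches a brute-force oracle", {
  set.seed(123)
  for (rep in 1:25) {
    lcpm <- matrix(rnorm(50 * 6), 50, 6,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
    for (top in c(1, 5, 50, 1e6)) {
      for (mode in c("pairwise", "common")) {
        expect_equal(leading_logfc_distance(lcpm, top, mode),
                     brute_leading_distance(lcpm, top, mode),
                     tolerance = 1e-12,
                     label = paste("rep", rep, "top", top, mode))
      }
    }
  }
})

test_that("with top >= n_genes the distance is the plain RMS over all genes", {
  set.seed(5)
  lcpm <- matrix(rnorm(40 * 5), 40, 5,
                 dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
  full <- leading_logfc_distance(lcpm, top = 1e6, gene_selection = "pairwise")
  want <- as.matrix(dist(t(lcpm))) / sqrt(nrow(lcpm))
  expect_equal(full, want, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(full,
               leading_logfc_distance(lcpm, 1e6, "common"),
               tolerance = 1e-12)
})

test_that("distances are invariant to per-gene constant shifts", {
  set.seed(8)
  lcpm <- matrix(rnorm(30 * 4), 30, 4,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:4)))
  shifted <- lcpm + rnorm(30)  # recycles per row: per-gene constant
  for (mode in c("pairwise", "common")) {
    expect_equal(leading_logfc_distance(lcpm, 10, mode),
                 leading_logfc_distance(shifted, 10, mode),
                 tolerance = 1e-10)
  }
})

test_that("classical MDS reconstructs three mutually equidistant points", {
  D <- matrix(1, 3, 3) - diag(3)
  dimnames(D) <- list(paste0("p", 1:3), paste0("p", 1:3))
  fit <- classical_mds(D, k = 2)
  rec <- as.matrix(dist(fit$coordinates))
  expect_equal(rec, D, tolerance = 1e-10, ignore_attr = TRUE)
  ev <- fit$eigenvalues[fit$eigenvalues > 1e-12]
  expect_equal(ev[1], ev[2], tolerance = 1e-10)
  expect_equal(variance_explained(fit$eigenvalues), c(0.5, 0.5),
               tolerance = 1e-10)
})

test_that("classical MDS recovers planted 2-D configurations exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(20), 10, 2)
    D <- as.matrix(dist(X))
    dimnames(D) <- list(paste0("p", 1:10), paste0("p", 1:10))
    fit <- classical_mds(D, k = 2)
    expect_lt(procrustes_rms(X, fit$coordinates), 1e-8)
  }
})

test_that("classical MDS agrees with stats::cmdscale up to sign", {
  set.seed(21)
  X <- matrix(rnorm(24), 8, 3)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("p", 1:8), paste0("p", 1:8))
  fit <- classical_mds(D, k = 3)
  ref <- cmdscale(D, k = 3, eig = TRUE)
  expect_equal(abs(fit$coordinates), abs(ref$points),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$eigenvalues[1:3], ref$eig[1:3], tolerance = 1e-8)
})

test_that("classical MDS validates its input and fixes signs deterministically", {
  D <- matrix(c(0, 1, 1.1, 0), 2, 2)
  expect_error(classical_mds(D), "asymmetric")
  D2 <- matrix(c(0.5, 1, 1, 0), 2, 2)
  expect_error(classical_mds(D2), "diagonal")
  # duplicated point: coincident coordinate rows
  X <- rbind(c(0, 0), c(0, 0), c(3, 4))
  D3 <- as.matrix(dist(X))
  fit <- classical_mds(D3, k = 2)
  expect_equal(fit$coordinates[1, ], fit$coordinates[2, ], tolerance = 1e-10)
  # sign convention: largest-magnitude loading of each column is positive
  set.seed(4)
  Dr <- as.matrix(dist(matrix(rnorm(18), 9, 2)))
  co <- classical_mds(Dr, k = 2)$coordinates
  for (j in seq_len(ncol(co))) {
    expect_gt(co[which.max(abs(co[, j])), j], 0)
  }
})

test_that("variance explained ratios positive eigenvalues only", {
  expect_equal(variance_explained(c(4, 1)), c(0.8, 0.2))
  expect_equal(variance_explained(c(3, 2, -0.5)), c(0.6, 0.4))
  expect_error(variance_explained(c(-1, 0)), "positive")
  set.seed(10)
  for (i in 1:20) {
    ev <- rnorm(sample(2:8, 1))
    if (all(ev <= 0)) next
    ve <- variance_explained(ev)
    expect_equal(sum(ve), 1, tolerance = 1e-12)
    expect_true(all(diff(ve) <= 1e-12))  # non-increasing
  }
})

test_that("run_mds composes the pipeline with k = n_samples - 1", {
  sim <- simulate_counts(n_genes = 300, groups = c("b", "lp", "ml"),
                         samples_per_group = 3, n_de = 60, seed = 31)
  m <- run_mds(sim$expr)
  expect_s3_class(m, "MDSResult")
  expect_lte(ncol(m$coordinates), 8)  # nine samples: at most 8 dimensions
  expect_identical(rownames(m$coordinates), colnames(sim$expr$counts))
  expect_equal(sum(m$var_explained), 1, tolerance = 1e-12)
  expect_equal(m$params$top, 500)
  # permuting samples permutes coordinate rows identically
  perm <- c(4, 1, 9, 2, 8, 3, 7, 5, 6)
  expr_p <- expression_data(sim$expr$counts[, perm],
                            sample_table = sim$expr$samples[perm, ])
  m_p <- run_mds(expr_p)
  expect_equal(m_p$coordinates, m$coordinates[perm, ], tolerance = 1e-8)
})

test_that("the MDS pipeline agrees with limma's leading-logFC MDS", {
  skip_if_not_installed("limma")
  sim <- simulate_counts(n_genes = 400, n_de = 80, seed = 77)
  lcpm <- log_cpm(sim$expr)
  n <- ncol(lcpm)
  J <- diag(n) - 1 / n
  for (mode in c("pairwise", "common")) {
    ours <- leading_logfc_distance(lcpm, top = 100, gene_selection = mode)
    ref <- limma::plotMDS(lcpm, top = 100, gene.selection = mode,
                          plot = FALSE)
    # limma stores the doubly centered squared-distance matrix (-2B)
    expect_equal(J %*% ours^2 %*% J, ref$distance.matrix.squared,
                 tolerance = 1e-10, ignore_attr = TRUE,
                 label = mode)
    fit <- classical_mds(ours, k = 2)
    expect_equal(fit$eigenvalues, ref$eigen.values, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(abs(fit$coordinates[, 1]), abs(ref$x), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(abs(fit$coordinates[, 2]), abs(ref$y), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("dimension 1 separates strongly distinct groups", {
  hits <- 0
  for (seed in 1:20) {
    sim <- simulate_counts(n_genes = 500, n_de = 100, lfc_magnitude = 3,
                           seed = 1000 + seed)
    m <- run_mds(sim$expr, top = 100)
    d1 <- m$coordinates[, 1]
    grp <- sim$expr$samples$group
    between <- abs(outer(d1[grp == "A"], d1[grp == "B"], "-"))
    within <- c(dist(d1[grp == "A"]), dist(d1[grp == "B"]))
    if (min(between) > max(within)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})
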