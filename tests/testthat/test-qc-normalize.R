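test_that("feature filter keeps rows with totals at or above the threshold", {
  m <- matrix(c(0, 0, 0, 1, 1, 1, 2, 3), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  # row totals 0, 1, 2, 5
  ff <- filter_features(m, min_row_total = 2)
  expect_equal(counts_tbl(counts_matrix(ff$counts))$gene, c("g3", "g4"))
  expect_equal(ff$removed_genes, c("g1", "g2"))

  expect_equal(nrow(filter_features(m, min_row_total = 0)$counts), 4)
  expect_error(filter_features(m, min_row_total = 100), "no features")
})

test_that("sample filter drops columns below threshold, keeping exact boundary", {
  m <- rbind(c(49999, 50000, 125000), c(50000, 50000, 125000))
  dimnames(m) <- list(c("g1", "g2"), c("low", "edge", "high"))
  # column totals 99,999; 100,000; 250,000
  fs <- filter_samples(m, min_col_total = 100000)
  expect_equal(fs$removed_samples, "low")
  expect_equal(colnames(counts_matrix(fs$counts)), c("edge", "high"))
  expect_equal(ncol(counts_matrix(filter_samples(m, 0)$counts)), 3)

  # planted low-depth columns in a wide plate are exactly the ones dropped
  set.seed(4)
  big <- matrix(rpois(10 * 384, 400), 10,
                dimnames = list(paste0("g", 1:10), sprintf("w%03d", 1:384)))
  low <- c("w005", "w050", "w181", "w300", "w384")
  big[, low] <- matrix(rpois(10 * 5, 3), 10)
  fs2 <- filter_samples(big, min_col_total = 1000)
  expect_setequal(fs2$removed_samples, low)
})

test_that("control PCA is diagnostic: degenerate, clustered and bounded cases", {
  base <- matrix(rpois(30 * 6, 100), 30,
                 dimnames = list(paste0("g", 1:30), paste0("c", 1:6)))
  dup <- base
  dup[] <- base[, 1]  # all controls identical
  pc <- control_pca(dup, colnames(dup))
  expect_true(all(abs(pc$scores$PC1) < 1e-8))

  # two planted clusters separate on PC1 with opposite signs
  set.seed(8)
  cl <- matrix(rpois(100 * 8, 200), 100,
               dimnames = list(paste0("g", 1:100), paste0("c", 1:8)))
  cl[1:50, 5:8] <- cl[1:50, 5:8] + 150
  pc2 <- control_pca(cl, colnames(cl))
  expect_true(all(sign(pc2$scores$PC1[1:4]) != sign(pc2$scores$PC1[5:8])))
  expect_lte(sum(pc2$var_explained), 1 + 1e-8)

  expect_warning(expect_null(control_pca(base, c("c1", "c2"))), "fewer than 3")
})

test_that("D statistic excludes a planted shuffled control and only it", {
  set.seed(21)
  profile <- rpois(200, 300)
  m <- sapply(1:24, function(i) rpois(200, profile))
  dimnames(m) <- list(paste0("g", 1:200), sprintf("c%02d", 1:24))
  m[, "c24"] <- m[sample.int(200), "c24"]  # destroy gene correlation
  d <- d_statistic(m, colnames(m), sd_cut = 3)
  expect_equal(d$sample_id[d$excluded], "c24")

  # exclusion strictly increases the mean pairwise correlation of survivors
  cc <- control_correlations(m, colnames(m))
  before <- mean(cc[upper.tri(cc)])
  keep <- setdiff(colnames(m), "c24")
  cc2 <- control_correlations(m, keep)
  expect_gt(mean(cc2[upper.tri(cc2)]), before)
})

test_that("D statistic degenerate cases: identical controls and zero variance", {
  m <- matrix(rep(rpois(50, 100), 5), 50,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:5)))
  d <- d_statistic(m, colnames(m))          # sd(D) = 0: nothing excluded
  expect_false(any(d$excluded))

  m2 <- cbind(m[, 1:4], flat = 7)
  colnames(m2) <- c(paste0("c", 1:4), "flat")
  d2 <- d_statistic(m2, colnames(m2))
  expect_true(d2$excluded[d2$sample_id == "flat"])
  expect_match(d2$reason[d2$sample_id == "flat"], "zero-variance")

  expect_error(d_statistic(m[, 1:3], colnames(m)[1:3]), "at least 4")
})

test_that("pairwise control correlations match the direct formula", {
  m <- matrix(c(1, 2, 3, 2, 4, 6, 9, 5, 1), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("a", "b", "c")))
  cc <- control_correlations(m, c("a", "b", "c"))
  expect_equal(diag(cc), c(a = 1, b = 1, c = 1))
  expect_equal(cc, t(cc))
  direct <- cor(log2(m + 0.5))
  expect_equal(cc, direct)

  dup <- cbind(a = m[, 1], b = m[, 1])
  expect_equal(control_correlations(dup, c("a", "b"))["a", "b"], 1)
  anti <- matrix(c(1, 2, 3, 3, 2, 1), 3,
                 dimnames = list(paste0("g", 1:3), c("u", "v")))
  # log transform preserves the perfect anticorrelation only approximately;
  # use values symmetric on the log scale instead
  anti2 <- matrix(2^c(1, 2, 3, 3, 2, 1) - 0.5, 3,
                  dimnames = list(paste0("g", 1:3), c("u", "v")))
  expect_equal(control_correlations(anti2, c("u", "v"))["u", "v"], -1)
})

test_that("median-of-ratios size factors match hand computation and scale", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  sf <- size_factors(m)   # column 2 is exactly twice column 1
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  ident <- matrix(rep(c(5, 9, 14), 3), nrow = 3,
                  dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(size_factors(ident)), rep(1, 3))

  # scale equivariance: scaling one column by c scales its factor by c
  # relative to every other sample, and the normalized matrix is unchanged
  # up to one global constant (the geometric-mean renormalization)
  set.seed(31)
  r <- matrix(rpois(40 * 4, 500), 40,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:4)))
  r2 <- r; r2[, 2] <- r2[, 2] * 4
  sf1 <- size_factors(r); sf2 <- size_factors(r2)
  expect_equal((sf2[2] / sf2[1]) / (sf1[2] / sf1[1]), 4,
               tolerance = 1e-12, ignore_attr = TRUE)
  n1 <- counts_matrix(normalize_counts(r, sf1)$normalized)
  n2 <- counts_matrix(normalize_counts(r2, sf2)$normalized)
  ratio <- n2 / n1
  expect_lt(diff(range(ratio[is.finite(ratio)])), 1e-9)

  # no gene nonzero everywhere: total-count fallback with geometric mean 1
  holey <- matrix(c(0, 5, 10, 0), 2,
                  dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_warning(sfh <- size_factors(holey), "falling back")
  expect_equal(prod(sfh), 1, tolerance = 1e-12)
})

test_that("size factors agree with the established NB implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(41)
  m <- matrix(rnbinom(200 * 6, mu = 300, size = 20), 200,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("full QC stage detects every planted defect and conserves counts", {
  cfg <- sim_config(n_genes = 400, n_controls = 12, depth = 60000, seed = 5,
                    chemicals = list(chemX = c(0.1, 1, 10)),
                    n_lowcount_samples = 1, lowcount_factor = 0.01,
                    n_outlier_controls = 1, n_subthreshold_genes = 15)
  sim <- simulate_counts(cfg)
  qc <- qc_counts(sim$counts, sim$layout, min_col_total = 20000)

  expect_setequal(qc$removed$genes, sim$truth$gene[sim$truth$subthreshold])
  expect_equal(qc$removed$samples, sim$defects$lowcount_samples)
  expect_equal(qc$removed$controls, sim$defects$outlier_controls)

  r <- qc$report
  expect_equal(r$genes_in, r$genes_removed + r$genes_kept)
  expect_equal(r$samples_in,
               r$samples_removed_lowcount + r$controls_removed_dstat +
                 r$samples_kept)
  expect_equal(nrow(qc$layout), r$samples_kept)
})
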