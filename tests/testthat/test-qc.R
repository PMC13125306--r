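test_that("qc_filter applies each criterion and reports removals", {
  ## 10 cells, 3 violating exactly one criterion each
  n_genes <- 300L
  genes <- data.frame(gene = c(sprintf("g%03d", 1:(n_genes - 1)), "MT-ND1"),
                      chrom = c(rep("chr1", n_genes - 1), "chrM"),
                      start = seq_len(n_genes) * 1000L,
                      end = seq_len(n_genes) * 1000L + 500L,
                      cytoband = NA)
  m <- matrix(2L, 10, n_genes,
              dimnames = list(sprintf("c%02d", 1:10), genes$gene))
  ## healthy baseline: 299 genes x 2 counts = 598 UMIs, 300 genes detected
  m[1, ] <- 0L; m[1, 1:50] <- 3L            # 150 UMIs -> low_umis + low_genes? 50 genes also < 200
  m[1, 51:250] <- 0L                         # keep: 50 genes, 150 UMIs
  m[2, ] <- 0L; m[2, 1:99] <- 4L; m[2, 99] <- 24L   # 99 genes < 100, 416 UMIs
  m[3, n_genes] <- 200L                      # mito fraction 200/798 > 0.2
  thr <- qc_thresholds(min_umis = 200, min_genes = 100, max_genes = 6000,
                       max_mito_fraction = 0.2)
  cells <- data.frame(cell = rownames(m), sample = "s", histology = NA,
                      is_reference = FALSE)
  res <- qc_filter(new_cohort(m, cells, genes), thr)
  expect_equal(attr(res$report, "n_retained"), 7)
  rep <- setNames(res$report$n_violating, res$report$criterion)
  expect_equal(unname(rep["low_umis"]), 1)   # cell 1 (150 UMIs)
  expect_equal(unname(rep["low_genes"]), 2)  # cells 1 and 2
  expect_equal(unname(rep["high_mito"]), 1)  # cell 3
  expect_false(any(c("c01", "c02", "c03") %in% rownames(res$cohort$counts)))

  ## idempotence: filtering a filtered cohort removes nothing
  res2 <- qc_filter(res$cohort, thr)
  expect_equal(attr(res2$report, "n_retained"), attr(res2$report, "n_input"))

  ## zero survivors is an explicit error
  expect_error(qc_filter(res$cohort, qc_thresholds(min_umis = 1e6)),
               "every cell")
})

test_that("normalize_log1p scales cells and preserves shapes", {
  x <- matrix(c(10, 0, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("g1", "g2")))
  e <- normalize_log1p(x, scale = 10)
  expect_equal(e["a", ], c(g1 = log(11), g2 = 0))
  expect_equal(e["b", ], c(g1 = 0, g2 = 0))  # all-zero cell stays zero

  m <- toy_cohort()$counts
  e2 <- normalize_log1p(m, scale = 1e4)
  expect_identical(dim(e2), dim(m))
  sums <- rowSums(expm1(e2))
  expect_true(all(abs(sums[rowSums(m) > 0] - 1e4) < 1e-6))
  ## monotone per cell
  i <- order(m[1, ]); expect_true(all(diff(e2[1, i]) >= 0))
})

test_that("select_hvg_vst ranks genuine variability first", {
  set.seed(31)
  n <- 200
  e <- matrix(rnorm(n * 50, mean = 5), n, 50,
              dimnames = list(NULL, sprintf("g%02d", 1:50)))
  e[, "g01"] <- rnorm(n, 5, 10)       # 100x the variance at equal mean
  e[, "g02"] <- 3                     # constant
  hv <- select_hvg_vst(e, 10)
  expect_equal(hv[1], "g01")
  expect_false("g02" %in% select_hvg_vst(e, 49))

  ## agreement with a direct standardized-variance computation
  mu <- colMeans(e); v <- apply(e, 2, var)
  ok <- v > 0
  fit <- lm(log10(v[ok]) ~ poly(log10(mu[ok]), 2))
  sdp <- sqrt(10^predict(fit))
  sv <- vapply(which(ok), function(j)
    var(pmin((e[, j] - mu[j]) / sdp[[sum(ok[1:j])]], sqrt(n))), numeric(1))
  oracle <- names(sort(sv, decreasing = TRUE))[1:10]
  expect_setequal(select_hvg_vst(e, 10), oracle)

  expect_error(select_hvg_vst(matrix(1, 5, 5), 2), "nonzero variance")
})

test_that("cluster_snn separates blobs and degenerates sensibly", {
  set.seed(41)
  blob <- function(center, n = 60)
    matrix(rnorm(n * 40, center, 0.3), n, 40)
  e <- rbind(blob(0), blob(8))
  rownames(e) <- sprintf("c%03d", 1:120)
  colnames(e) <- sprintf("g%02d", 1:40)
  cl <- cluster_snn(e, n_pcs = 10, resolution = 0.1, seed = 1)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:60])), 1)
  expect_equal(length(unique(cl[61:120])), 1)

  ## gene relabelling leaves the partition unchanged
  e2 <- e[, rev(seq_len(ncol(e)))]
  colnames(e2) <- colnames(e)
  expect_true(ari(cl, cluster_snn(e2, n_pcs = 10, resolution = 0.1, seed = 1)) > 0.999)

  ## resolution -> 0 on a connected graph: one cluster
  e3 <- matrix(rnorm(80 * 30), 80, 30,
               dimnames = list(sprintf("c%02d", 1:80), sprintf("g%02d", 1:30)))
  cl3 <- cluster_snn(e3, n_pcs = 5, resolution = 1e-4, k = 40, seed = 1)
  expect_equal(length(unique(cl3)), 1)

  expect_error(cluster_snn(e3, n_pcs = 100), "n_pcs")
})

test_that("cluster_snn recovers planted clones (ARI >= 0.8)", {
  sim <- simulate_cohort(three_clone_config(51))
  tumor <- names(sim$truth$clone)[sim$truth$clone != "normal"]
  co <- subset_cohort(sim$cohort, cells = tumor)
  e <- normalize_log1p(co)
  hv <- select_hvg_vst(e, 500)
  cl <- cluster_snn(e[, hv], n_pcs = 20, resolution = 0.1, seed = 1,
                    batch = co$cells$sample)
  expect_gte(ari(cl, sim$truth$clone[tumor]), 0.8)
  ## batch-centering stand-in never changes the number of cells
  expect_length(cl, length(tumor))
})

test_that("annotate_markers assigns panels and flags ties", {
  markers <- default_marker_table()
  genes <- c(unlist(markers, use.names = FALSE), sprintf("f%02d", 1:10))
  ## flat background: markers not expressed except the planted ones
  e <- matrix(0.1, 90, length(genes),
              dimnames = list(sprintf("c%02d", 1:90), genes))
  lab <- rep(1:3, each = 30)
  e[lab == 1, "EPCAM"] <- 5                     # only epithelial marker up
  e[lab == 2, markers$T_cell] <- 5
  e[lab == 3, markers$B_cell] <- 5
  ann <- annotate_markers(e, lab)
  expect_equal(ann$cell_type, c("epithelial", "T_cell", "B_cell"))
  expect_false(any(ann$tie))

  ## identical profiles -> same label, tie flagged
  e2 <- e; e2[lab == 2, ] <- e2[lab == 1, ]
  ann2 <- annotate_markers(e2[lab %in% 1:2, ], lab[lab %in% 1:2])
  expect_equal(ann2$cell_type[1], ann2$cell_type[2])
  expect_true(all(ann2$tie))

  expect_error(annotate_markers(e[, 1:3], lab), "no marker genes")
})

test_that("module_score is zero on uniform input and monotone in signal", {
  e <- matrix(1, 50, 200,
              dimnames = list(sprintf("c%02d", 1:50), sprintf("g%03d", 1:200)))
  sc <- module_score(e, c("g001", "g002"), seed = 1)
  expect_true(all(abs(sc) < 1e-12))

  set.seed(71)
  e2 <- matrix(rexp(100 * 200), 100, 200,
               dimnames = list(sprintf("c%03d", 1:100), sprintf("g%03d", 1:200)))
  sig <- c("g005", "g010", "g015", "g020", "g025")
  hi <- 1:50
  e2[hi, sig] <- e2[hi, sig] * 4
  sc2 <- module_score(e2, sig, seed = 1)
  expect_gt(min(sc2[hi]) - max(sc2[-hi]), -Inf)  # guard
  expect_gt(mean(sc2[hi]), mean(sc2[-hi]))
  ## AUROC of score vs planted signal >= 0.9
  r <- rank(sc2)
  auroc <- (sum(r[hi]) - length(hi) * (length(hi) + 1) / 2) /
    (length(hi) * (100 - length(hi)))
  expect_gte(auroc, 0.9)

  expect_error(module_score(e2, character(0)), "empty")
  expect_error(module_score(e2, "nope"), "absent")
})
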