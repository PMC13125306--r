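## Shared small planted cohort for the CNV chain tests.
cnv_world <- local({
  sim <- simulate_cohort(burden_config(81, cells_per_clone = 120))
  inf <- infer_cnv(sim$cohort)[[1]]
  list(sim = sim, inf = inf)
})

test_that("center_on_reference drops low genes and centres on the reference", {
  set.seed(91)
  e <- matrix(rnorm(40 * 30, 1), 40, 30,
              dimnames = list(sprintf("c%02d", 1:40), sprintf("g%02d", 1:30)))
  e[, "g30"] <- 0.05                       # below the 0.1 cutoff
  r <- center_on_reference(e, rownames(e), center_cells = FALSE, clip = 100)
  expect_false("g30" %in% colnames(r))     # cutoff drop
  expect_true(all(abs(colMeans(r)) < 1e-12))  # reference-only: means 0

  expect_error(center_on_reference(e, character(0)), "empty reference")
  expect_error(center_on_reference(e, rownames(e)[1:5]), ">= 20")
  expect_error(center_on_reference(e * 0 + 0.01, rownames(e)), "cutoff")
})

test_that("planted amplification produces positive residuals in carriers only", {
  sim <- cnv_world$sim; inf <- cnv_world$inf
  g <- sim$cohort$genes
  amp <- intersect(colnames(inf$residuals),
                   g$gene[g$chrom == "chr2"][1:120])  # copy-4 block
  carrier <- names(sim$truth$clone)[sim$truth$clone %in% c("dcis", "idc")]
  carrier <- intersect(carrier, rownames(inf$residuals))
  ref <- intersect(sim$cohort$cells$cell[sim$cohort$cells$is_reference],
                   rownames(inf$residuals))
  ## carriers well above reference (which only keeps the small systematic
  ## per-cell median-centering offset that denoising later removes)
  expect_gt(mean(inf$residuals[carrier, amp]), 0.3)
  expect_lt(abs(mean(inf$residuals[ref, amp])), 0.1)
  ## post-denoise reference signal is a small fraction of the carrier signal
  expect_lt(mean(abs(unclass(inf$cnv)[ref, amp])),
            0.1 * mean(abs(unclass(inf$cnv)[carrier, amp])))
})

test_that("smooth_genome equals the brute-force window mean and respects edges", {
  genes <- data.frame(gene = sprintf("g%02d", 1:30),
                      chrom = rep(c("chr1", "chr2"), each = 15),
                      start = rep(seq_len(15) * 100L, 2),
                      end = rep(seq_len(15) * 100L + 50L, 2), cytoband = NA)
  set.seed(92)
  m <- matrix(rnorm(2 * 30), 2, 30, dimnames = list(c("a", "b"), genes$gene))
  sm <- smooth_genome(m, genes, window = 5)
  ## brute force with shrinking edges, never crossing chromosomes
  for (chrom in c("chr1", "chr2")) {
    j <- which(genes$chrom == chrom)
    for (p in seq_along(j)) {
      w <- j[max(1, p - 2):min(length(j), p + 2)]
      expect_equal(sm[, j[p]], rowMeans(m[, w, drop = FALSE]))
    }
  }
  ## constants unchanged; window 1 is the identity
  expect_equal(smooth_genome(m * 0 + 3, genes, window = 7), m * 0 + 3,
               ignore_attr = TRUE)
  expect_equal(smooth_genome(m, genes, window = 1), m, ignore_attr = TRUE)
  ## oversized window: warning + cap (one chromosome -> one warning)
  expect_warning(smooth_genome(m[, 1:15], genes[1:15, ], window = 31),
                 "capped")
})

test_that("denoise_dynamic suppresses the closed reference band only", {
  m <- rbind(ref1 = c(-1, 0, 1, 0), ref2 = c(1, 0, -1, 0),
             a = c(1.5, 1.5001, 10, 0))
  colnames(m) <- sprintf("g%d", 1:4)
  ## per-gene ref sd: gene1/3 sd = sqrt(2), gene2/4 sd = 0 -> global fallback
  d <- denoise_dynamic(m, c("ref1", "ref2"), k_sd = 1.5)
  expect_equal(unname(d["a", "g3"]), 10)        # far outside band
  expect_equal(unname(d["a", "g1"]), 0)         # 1.5 = 1.5 * sd(=1)? no: sd=sqrt2
  ## exact boundary: value at mean + 1.5*sd is suppressed, just above passes
  m2 <- rbind(r1 = c(-1, 0), r2 = c(1, 0), x = c(1.5, 0))
  colnames(m2) <- c("g1", "g2")
  ## gene1 ref sd = sqrt(2); craft exact boundary
  m2["x", "g1"] <- 1.5 * sd(c(-1, 1))
  expect_equal(unname(denoise_dynamic(m2, c("r1", "r2"))["x", "g1"]), 0)
  m2["x", "g1"] <- 1.5 * sd(c(-1, 1)) + 1e-9
  expect_gt(denoise_dynamic(m2, c("r1", "r2"))["x", "g1"], 0)

  ## all inside band -> all-zero signal
  mz <- rbind(r1 = c(-1, 1), r2 = c(1, -1), y = c(0.5, -0.5))
  colnames(mz) <- c("g1", "g2")
  expect_true(all(denoise_dynamic(mz, c("r1", "r2")) == 0))

  ## zero reference variance -> error
  mc <- rbind(r1 = c(1, 1), r2 = c(1, 1), z = c(5, 5))
  colnames(mc) <- c("g1", "g2")
  expect_error(denoise_dynamic(mc, c("r1", "r2")), "reference variance")

  ## monotone: larger k_sd never increases |signal|
  sm <- smooth_genome(
    cnv_world$inf$residuals,
    cnv_world$sim$cohort$genes, window = 51)
  ref <- cnv_world$sim$cohort$cells$cell[cnv_world$sim$cohort$cells$is_reference]
  ref <- intersect(ref, rownames(sm))
  d1 <- abs(denoise_dynamic(sm, ref, k_sd = 1.0))
  d2 <- abs(denoise_dynamic(sm, ref, k_sd = 2.0))
  expect_true(all(d2 <= d1 + 1e-12))
})

test_that("rescale_unit maps to [-1, 1] preserving order", {
  m <- matrix(c(2, -1, 0.5, 0), 2, 2)
  r <- rescale_unit(m)
  expect_equal(max(abs(r)), 1)
  expect_equal(unname(r[1, 1]), 1)
  expect_identical(order(as.vector(m)), order(as.vector(unclass(r))))
  z <- matrix(0, 2, 2)
  expect_true(all(rescale_unit(z) == 0))
})

test_that("cnv_score is a gene-count-normalised absolute burden", {
  m <- rbind(a = c(0.5, -0.5), b = c(0, 0))
  expect_equal(unname(cnv_score(m)), c(0.5, 0))
  expect_equal(unname(cnv_score(m, mode = "sum_abs")), c(1, 0))
  ## invariant to gene-order permutation
  sim_cnv <- cnv_world$inf$cnv
  perm <- sample(ncol(sim_cnv))
  expect_equal(cnv_score(sim_cnv), cnv_score(unclass(sim_cnv)[, perm]))
})

test_that("pipeline equivariance: permuting cells permutes outputs", {
  sim <- cnv_world$sim
  co <- sim$cohort
  perm <- rev(rownames(co$counts))
  co2 <- subset_cohort(co, cells = perm)
  i1 <- infer_cnv(co)[[1]]
  i2 <- infer_cnv(co2)[[1]]
  expect_equal(unclass(i1$cnv)[perm, ], unclass(i2$cnv)[perm, ])
  expect_equal(i1$score[perm], i2$score[perm])
})

test_that("planted tumor cells outscore reference cells (Wilcoxon)", {
  sim <- cnv_world$sim; inf <- cnv_world$inf
  sc <- inf$score
  tum <- sc[names(sc) %in% names(sim$truth$clone)[sim$truth$clone != "normal"]]
  ref <- sc[names(sc) %in% names(sim$truth$clone)[sim$truth$clone == "normal"]]
  w <- wilcoxon_compare(tum, ref)
  expect_lt(w$p.value, 0.05)
  expect_gt(mean(tum), mean(ref))
})

test_that("cluster_clones recovers the planted 2-clone split", {
  sim <- cnv_world$sim; inf <- cnv_world$inf
  tumor <- intersect(names(sim$truth$clone)[sim$truth$clone != "normal"],
                     rownames(inf$cnv))
  cl <- cluster_clones(inf$cnv[tumor, , drop = FALSE])
  expect_gte(ari(cl, sim$truth$clone[tumor]), 0.9)
})
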