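## Small simulation configs shared across test files. Kept deliberately
## lighter than the default cohort so the unit suite stays fast; the
## default-scale world is exercised in test-acceptance.R.

small_genome <- function(n_chrom = 4L, genes = 300L)
  stats::setNames(rep(genes, n_chrom), paste0("chr", seq_len(n_chrom)))

## One founder + one descendant (+2 events): the DCIS vs IDC burden world.
burden_config <- function(seed, cells_per_clone = 150L, n_ref = 100L) {
  base <- list(cnv_event("chr1", 181, 120, 3),
               cnv_event("chr2", 1, 120, 4),
               cnv_event("chr3", 151, 150, 1))
  extra <- list(cnv_event("chr2", 181, 120, 1),
                cnv_event("chr4", 161, 140, 4))
  simulation_config(
    seed = seed, n_samples = 1L, cells_per_sample = 2L * cells_per_clone,
    n_reference_cells = n_ref, genes_per_chromosome = small_genome(4L),
    clone_tree_spec = list(
      clone_spec("dcis", NA, base, 0.5, c(DCIS = 1, IDC = 0)),
      clone_spec("idc", "dcis", c(base, extra), 0.5, c(DCIS = 0, IDC = 1))))
}

## Three well-separated clones for clustering tests.
three_clone_config <- function(seed, cells_per_clone = 120L) {
  e1 <- cnv_event("chr1", 1, 150, 4)
  e2 <- cnv_event("chr2", 1, 150, 4)
  e3 <- cnv_event("chr3", 1, 150, 1)
  simulation_config(
    seed = seed, n_samples = 1L, cells_per_sample = 3L * cells_per_clone,
    n_reference_cells = 60L, genes_per_chromosome = small_genome(4L),
    clone_tree_spec = list(
      clone_spec("a", NA, list(e1), 1 / 3),
      clone_spec("b", "a", list(e1, e2), 1 / 3),
      clone_spec("c", "a", list(e1, e3), 1 / 3)))
}

## Tiny deterministic cohort for IO / QC plumbing tests.
toy_cohort <- function(n_cells = 10L, n_genes = 20L, seed = 42L) {
  with_seed_t(seed, {
    genes <- data.frame(gene = sprintf("g%02d", 1:n_genes), chrom = "chr1",
                        start = (0:(n_genes - 1)) * 1000L + 1L,
                        end = (0:(n_genes - 1)) * 1000L + 500L,
                        cytoband = "1p1")
    m <- matrix(rpois(n_cells * n_genes, 5), n_cells, n_genes,
                dimnames = list(sprintf("c%02d", 1:n_cells), genes$gene))
    cells <- data.frame(cell = rownames(m), sample = "s1",
                        histology = rep(c("DCIS", "IDC"), length.out = n_cells),
                        is_reference = rep(c(TRUE, FALSE), length.out = n_cells))
    new_cohort(m, cells, genes)
  })
}

with_seed_t <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}
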