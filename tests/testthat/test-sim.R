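test_that("simulate_cohort plants the dosage model and is seed-deterministic", {
  ## copy-4 event over 50 genes: carrier mean counts ~ 2x reference
  ev <- cnv_event("chr2", 21, 50, 4)
  cfg <- simulation_config(
    seed = 11, n_samples = 1, cells_per_sample = 250, n_reference_cells = 250,
    genes_per_chromosome = small_genome(3L, 100L),
    clone_tree_spec = list(clone_spec("t", NA, list(ev), 1)))
  sim <- simulate_cohort(cfg)
  g <- sim$cohort$genes
  in_ev <- which(g$chrom == "chr2")[21:70]
  tumor <- sim$truth$clone == "t"
  ## normalise out library-size differences before comparing means
  lib <- rowSums(sim$cohort$counts)
  cpm <- sim$cohort$counts / lib
  ratio <- mean(colMeans(cpm[tumor, in_ev])) /
    mean(colMeans(cpm[!tumor, in_ev]))
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)

  ## same config, same seed: byte-identical
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim$cohort$counts, sim2$cohort$counts)
  expect_identical(sim$truth, sim2$truth)
})

test_that("a clone with no events carries no signal", {
  cfg <- simulation_config(
    seed = 12, n_samples = 1, cells_per_sample = 300, n_reference_cells = 300,
    genes_per_chromosome = small_genome(2L, 100L),
    clone_tree_spec = list(clone_spec("t", NA, list(), 1)))
  sim <- simulate_cohort(cfg)
  tumor <- sim$truth$clone == "t"
  cpm <- sim$cohort$counts / rowSums(sim$cohort$counts)
  ## per-gene mean ratio ~ 1 in expectation
  r <- colMeans(cpm[tumor, ]) / colMeans(cpm[!tumor, ])
  expect_lt(abs(mean(r) - 1), 0.05)
  expect_true(all(sim$truth$copy_number == 2L))
})

test_that("dosage monotonicity: mean counts increase with planted copy number", {
  evs <- list(cnv_event("chr1", 1, 60, 1), cnv_event("chr1", 1, 60, 3),
              cnv_event("chr1", 1, 60, 4))
  means <- vapply(seq_along(evs), function(i) {
    cfg <- simulation_config(
      seed = 13, n_samples = 1, cells_per_sample = 200,
      n_reference_cells = 20, genes_per_chromosome = small_genome(2L, 100L),
      clone_tree_spec = list(clone_spec("t", NA, evs[i], 1)))
    sim <- simulate_cohort(cfg)
    mean(sim$cohort$counts[sim$truth$clone == "t", 1:60])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("invalid clone trees are rejected naming the offending clone", {
  e1 <- cnv_event("chr1", 1, 50, 3); e2 <- cnv_event("chr2", 1, 50, 1)
  expect_error(
    simulation_config(
      genes_per_chromosome = small_genome(2L, 100L),
      clone_tree_spec = list(
        clone_spec("p", NA, list(e1), 0.5),
        clone_spec("child", "p", list(e2), 0.5))),  # dropped parent event
    "child.*irreversibility|irreversibility.*child")
  expect_error(
    simulation_config(clone_tree_spec = list(
      clone_spec("a", NA, list(), 0.6), clone_spec("b", "a", list(), 0.6))),
    "sum to 1")
})

test_that("planted truth respects irreversibility (event-set nesting)", {
  cfg <- simulation_config(seed = 1, n_samples = 1, cells_per_sample = 40,
                           n_reference_cells = 20)
  tr <- simulate_cohort(cfg)$truth
  for (cl in cfg$clone_tree_spec) {
    if (is.na(cl$parent)) next
    expect_true(all(tr$clone_events[[cl$parent]] %in%
                      tr$clone_events[[cl$id]]))
  }
  expect_length(setdiff(names(tr$clone), character(0)),
                length(tr$histology))  # labels cover every simulated cell
})

test_that("spatial sections keep clones inside their regions", {
  cfg <- simulation_config(
    seed = 21, genes_per_chromosome = small_genome(2L, 100L),
    clone_tree_spec = list(
      clone_spec("A", NA, list(cnv_event("chr1", 1, 60, 4)), 0.5,
                 c(DCIS = 1, IDC = 0)),
      clone_spec("B", "A", list(cnv_event("chr1", 1, 60, 4),
                                cnv_event("chr2", 1, 60, 1)), 0.5,
                 c(DCIS = 0, IDC = 1))))
  st <- simulate_spatial_sections(
    cfg, 10, 10,
    regions = list(list(rows = 1:5, cols = 1:10, clone = "A", histology = "DCIS"),
                   list(rows = 6:10, cols = 1:10, clone = "B", histology = "IDC")))
  expect_true(all(st$truth$clone[st$truth$region == 1] == "A"))
  expect_true(all(st$truth$clone[st$truth$region == 2] == "B"))
  expect_true(all(st$cohort$cells$histology[st$truth$clone == "A"] == "DCIS"))

  ## recovered adjacency from coordinates equals the planted adjacency
  got <- spot_adjacency(st$cohort$cells, st$truth$clone)
  expect_identical(got, st$truth$adjacency)
})

test_that("checkerboard clone layout yields the planted adjacency graph", {
  e <- cnv_event("chr1", 1, 60, 4)
  mk <- function(id, parent, extra)
    clone_spec(id, parent, c(list(e), extra), 0.25)
  cfg <- simulation_config(
    seed = 22, genes_per_chromosome = small_genome(3L, 100L),
    clone_tree_spec = list(
      mk("A", NA, list()),
      mk("B", "A", list(cnv_event("chr2", 1, 50, 3))),
      mk("C", "A", list(cnv_event("chr2", 51, 50, 1))),
      mk("D", "A", list(cnv_event("chr3", 1, 50, 4)))))
  regions <- list(
    list(rows = 1:4, cols = 1:4, clone = "A", histology = "DCIS"),
    list(rows = 1:4, cols = 5:8, clone = "B", histology = "DCIS"),
    list(rows = 5:8, cols = 1:4, clone = "C", histology = "IDC"),
    list(rows = 5:8, cols = 5:8, clone = "D", histology = "IDC"))
  st <- simulate_spatial_sections(cfg, 8, 8, regions)
  got <- spot_adjacency(st$cohort$cells, st$truth$clone)
  expect_identical(got, sort(c("A|B", "A|C", "B|D", "C|D")))
})

test_that("spatial generator rejects layouts exceeding the grid", {
  cfg <- simulation_config(genes_per_chromosome = small_genome(2L, 100L),
                           clone_tree_spec = list(clone_spec("A", NA, list(), 1)))
  expect_error(
    simulate_spatial_sections(cfg, 2, 2, regions = list(
      list(rows = 1:3, cols = 1:3, clone = "A", histology = "DCIS"))),
    "grid smaller")
})

test_that("all-DCIS layouts label every spot DCIS", {
  cfg <- simulation_config(genes_per_chromosome = small_genome(2L, 100L),
                           clone_tree_spec = list(
                             clone_spec("A", NA, list(), 1, c(DCIS = 1, IDC = 0))))
  st <- simulate_spatial_sections(cfg, 4, 4, regions = list(
    list(rows = 1:4, cols = 1:4, clone = "A", histology = "DCIS")))
  expect_true(all(st$cohort$cells$histology == "DCIS"))
})

test_that("survival generator enforces its preconditions", {
  expect_error(simulate_survival_cohort(10, 2), "n < 20")
  expect_error(simulate_survival_cohort(50, 0), "positive")
  ## ~100% censoring: censoring window so small no event can precede it
  expect_error(simulate_survival_cohort(50, 1, seed = 3,
                                        base_hazard = 1e-9,
                                        censor_upper = 1e-6),
               "censored")
  d1 <- simulate_survival_cohort(100, 3, 0.5, seed = 7)
  d2 <- simulate_survival_cohort(100, 3, 0.5, seed = 7)
  expect_identical(d1, d2)
  expect_true(all(d1$time >= 0) && all(d1$event %in% 0:1))
})
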