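## ---------------------------------------------------------------------------
## Synthetic cohorts with planted clonal CNV architecture.
##
## The generator states a world once: negative-binomial counts (overdispersion
## is the dominant scRNA-seq noise the denoising step must survive), a linear
## dosage model (expression multiplier = copy/2, floored at 0.05 for homozygous
## deletions so ambient counts remain), lognormal library sizes, a per-sample
## scale factor as the only batch effect, and a 13-gene mitochondrial
## chromosome excluded from CNV inference but exercising the QC mito filter.
## ---------------------------------------------------------------------------

#' Describe one planted CNV event
#'
#' @param chrom chromosome name (must exist in the simulated genome).
#' @param start_gene 1-based index of the first affected gene on `chrom`.
#' @param n_genes number of consecutive genes affected.
#' @param copy integer copy number in `0:4` (2 = neutral is disallowed:
#'   a neutral "event" is no event).
#' @return a `cnv_event` list.
#' @export
cnv_event <- function(chrom, start_gene, n_genes, copy) {
  assert_that(copy %in% c(0L, 1L, 3L, 4L),
              "event copy number must be in {0,1,3,4} (2 is neutral)")
  assert_that(start_gene >= 1 && n_genes >= 1, "bad event coordinates")
  structure(list(chrom = chrom, start_gene = as.integer(start_gene),
                 n_genes = as.integer(n_genes), copy = as.integer(copy)),
            class = "cnv_event")
}

event_key <- function(e) {
  sprintf("%s:%d-%d:%s", e$chrom, e$start_gene, e$start_gene + e$n_genes - 1L,
          if (e$copy > 2) "amp" else "del")
}

#' Describe one clone of the planted tree
#'
#' @param id clone identifier.
#' @param parent parent clone id, or `NA` for the founder.
#' @param events list of [cnv_event()]s carried by this clone. Under the
#'   irreversibility assumption every clone must carry all of its parent's
#'   events, identically.
#' @param fraction fraction of a sample's tumor cells belonging to the clone.
#' @param histology named numeric vector of DCIS/IDC label probabilities.
#' @return a `clone_spec` list.
#' @export
clone_spec <- function(id, parent, events, fraction,
                       histology = c(DCIS = 0.5, IDC = 0.5)) {
  structure(list(id = id, parent = parent, events = events,
                 fraction = fraction, histology = histology),
            class = "clone_spec")
}

#' Default planted clone tree
#'
#' A founder with four arm-scale events (two gains, one loss, one gain) and
#' three descendants forming a branching topology:
#' `c1 -> (c2 -> c4, c3)`. Event sizes (120-150 genes) are arm-scale on the
#' default 300-gene chromosomes; HER2+ tumors routinely carry ~10 arm-level
#' CNVs, so a 4-6 event clone family is conservative.
#'
#' @return list of [clone_spec()]s.
#' @export
default_clone_tree <- function() {
  e1 <- cnv_event("chr1", 181, 120, 3)  # 1q gain
  e2 <- cnv_event("chr2", 1, 120, 4)    # 2p high-level amp
  e3 <- cnv_event("chr3", 151, 150, 1)  # 3q loss
  e4 <- cnv_event("chr6", 1, 150, 3)    # 6p gain
  e5 <- cnv_event("chr4", 1, 140, 1)    # 4p loss        (c2+)
  e6 <- cnv_event("chr5", 161, 140, 4)  # 5q amp         (c3+)
  e7 <- cnv_event("chr2", 181, 120, 1)  # 2q loss        (c3+)
  e8 <- cnv_event("chr6", 181, 120, 1)  # 6q loss        (c4+)
  base <- list(e1, e2, e3, e4)
  list(
    clone_spec("c1", NA, base, 0.25, c(DCIS = 0.9, IDC = 0.1)),
    clone_spec("c2", "c1", c(base, list(e5)), 0.25, c(DCIS = 0.6, IDC = 0.4)),
    clone_spec("c3", "c1", c(base, list(e6, e7)), 0.25, c(DCIS = 0.3, IDC = 0.7)),
    clone_spec("c4", "c2", c(base, list(e5, e8)), 0.25, c(DCIS = 0.1, IDC = 0.9))
  )
}

#' Configuration of the synthetic cohort generator
#'
#' @param seed RNG seed; the same config yields byte-identical cohorts.
#' @param n_samples number of samples (patients).
#' @param cells_per_sample tumor cells per sample, split across clones by
#'   their `fraction`s.
#' @param n_reference_cells copy-neutral normal cells per sample (the
#'   reference population for CNV centering).
#' @param genes_per_chromosome named integer vector, chromosome -> gene count.
#' @param clone_tree_spec list of [clone_spec()]s; see [default_clone_tree()].
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param library_size_lognormal `c(meanlog, sdlog)` of per-cell library
#'   size factors.
#' @param dosage_floor expression multiplier assigned to copy 0 (ambient
#'   counts; exactly 0 would make likelihoods degenerate).
#' @param include_chrM add a fixed 13-gene mitochondrial chromosome.
#' @param baseline_lognormal `c(meanlog, sdlog)` of per-gene baseline means.
#' @param sample_scale_sdlog sdlog of the per-sample scale factor (the only
#'   simulated batch effect).
#' @return a validated `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_samples = 3L,
                              cells_per_sample = 800L,
                              n_reference_cells = 100L,
                              genes_per_chromosome = stats::setNames(
                                rep(300L, 6), paste0("chr", 1:6)),
                              clone_tree_spec = default_clone_tree(),
                              nb_dispersion = 0.1,
                              library_size_lognormal = c(0, 0.3),
                              dosage_floor = 0.05,
                              include_chrM = TRUE,
                              baseline_lognormal = c(1, 1),
                              sample_scale_sdlog = 0.1) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              cells_per_sample = as.integer(cells_per_sample),
              n_reference_cells = as.integer(n_reference_cells),
              genes_per_chromosome = genes_per_chromosome,
              clone_tree_spec = clone_tree_spec,
              nb_dispersion = nb_dispersion,
              library_size_lognormal = library_size_lognormal,
              dosage_floor = dosage_floor, include_chrM = include_chrM,
              baseline_lognormal = baseline_lognormal,
              sample_scale_sdlog = sample_scale_sdlog)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$nb_dispersion > 0, "nb_dispersion must be positive")
  fr <- vapply(cfg$clone_tree_spec, `[[`, numeric(1), "fraction")
  assert_that(abs(sum(fr) - 1) < 1e-8, "clone fractions must sum to 1")
  ids <- vapply(cfg$clone_tree_spec, `[[`, character(1), "id")
  assert_that(!anyDuplicated(ids), "duplicate clone ids")
  by_id <- stats::setNames(cfg$clone_tree_spec, ids)
  roots <- 0L
  for (cl in cfg$clone_tree_spec) {
    for (e in cl$events) {
      assert_that(e$chrom %in% names(cfg$genes_per_chromosome),
                  "event chromosome %s not in simulated genome", e$chrom)
      assert_that(e$start_gene + e$n_genes - 1L <=
                    cfg$genes_per_chromosome[[e$chrom]],
                  "event on %s exceeds chromosome length", e$chrom)
    }
    if (is.na(cl$parent)) { roots <- roots + 1L; next }
    assert_that(cl$parent %in% ids, "clone %s has unknown parent %s",
                cl$id, cl$parent)
    pk <- vapply(by_id[[cl$parent]]$events, event_key, character(1))
    ck <- vapply(cl$events, event_key, character(1))
    if (!all(pk %in% ck))
      stopf("clone %s violates irreversibility: missing parent event(s) %s",
            cl$id, paste(setdiff(pk, ck), collapse = ", "))
  }
  assert_that(roots == 1L, "clone tree must have exactly one founder (root)")
  invisible(cfg)
}

## 13 canonical mitochondrial protein-coding genes.
MITO_GENES <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6",
                "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6",
                "MT-CYB")

## Gene positions: 1 kb genes on a 10 kb grid, non-overlapping, 1-based
## inclusive. Cytoband = arm (p first half / q second half) + 50-gene band.
make_gene_positions <- function(cfg) {
  out <- list()
  for (chrom in names(cfg$genes_per_chromosome)) {
    n <- cfg$genes_per_chromosome[[chrom]]
    i <- seq_len(n)
    arm <- ifelse(i <= n / 2, "p", "q")
    band <- ceiling(ifelse(arm == "p", i, i - n / 2) / 50)
    out[[chrom]] <- data.frame(
      gene = sprintf("%s-G%04d", chrom, i), chrom = chrom,
      start = (i - 1L) * 10000L + 1L, end = (i - 1L) * 10000L + 1000L,
      cytoband = paste0(sub("^chr", "", chrom), arm, band))
  }
  if (cfg$include_chrM) {
    i <- seq_along(MITO_GENES)
    out[["chrM"]] <- data.frame(
      gene = MITO_GENES, chrom = "chrM",
      start = (i - 1L) * 1200L + 1L, end = (i - 1L) * 1200L + 1000L,
      cytoband = NA_character_)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

## Per-clone true copy-number matrix (clones x genes), chrM always neutral.
clone_copy_matrix <- function(cfg, genes) {
  ids <- vapply(cfg$clone_tree_spec, `[[`, character(1), "id")
  cn <- matrix(2L, length(ids), nrow(genes),
               dimnames = list(ids, genes$gene))
  for (cl in cfg$clone_tree_spec) {
    for (e in cl$events) {
      idx <- which(genes$chrom == e$chrom)[e$start_gene:(e$start_gene + e$n_genes - 1L)]
      cn[cl$id, idx] <- e$copy
    }
  }
  cn
}

dosage_multiplier <- function(copy, floor = 0.05) {
  m <- copy / 2
  m[copy == 0L] <- floor
  m
}

## Draw an n_cells x n_genes NB count block. mu = baseline * lib * dosage.
nb_block <- function(mu, dispersion) {
  matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
         nrow = nrow(mu))
}

#' Simulate a multi-sample cohort with planted clonal CNV architecture
#'
#' Counts are negative binomial with mean
#' `baseline(gene) * library_size(cell) * sample_scale * dosage(copy)`;
#' reference cells are copy-neutral. Identical configs (same seed) give
#' byte-identical output.
#'
#' @param config a [simulation_config()].
#' @return list with `cohort` (a [new_cohort()]) and `truth`
#'   (per-cell clone/histology labels, per-gene per-clone copy numbers,
#'   the planted tree as a parent map, and per-clone event keys).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    genes <- make_gene_positions(config)
    ng <- nrow(genes)
    baseline <- stats::rlnorm(ng, config$baseline_lognormal[1],
                              config$baseline_lognormal[2])
    if (config$include_chrM) {
      mi <- genes$chrom == "chrM"  # boost mito baseline -> ~5% mito fraction
      baseline[mi] <- stats::rlnorm(sum(mi), log(30), 0.3)
    }
    cn <- clone_copy_matrix(config, genes)
    mult <- dosage_multiplier(cn, config$dosage_floor)
    ids <- rownames(cn)
    frac <- vapply(config$clone_tree_spec, `[[`, numeric(1), "fraction")
    counts <- list(); meta <- list()
    for (s in seq_len(config$n_samples)) {
      sname <- sprintf("S%02d", s)
      sscale <- stats::rlnorm(1, 0, config$sample_scale_sdlog)
      ncl <- diff(round(cumsum(c(0, frac)) * config$cells_per_sample))
      groups <- c(list(list(id = "normal", n = config$n_reference_cells,
                            mult = rep(1, ng), hist = NULL)),
                  lapply(seq_along(ids), function(i)
                    list(id = ids[i], n = ncl[i], mult = mult[i, ],
                         hist = config$clone_tree_spec[[i]]$histology)))
      for (g in groups) {
        if (g$n == 0L) next
        lib <- stats::rlnorm(g$n, config$library_size_lognormal[1],
                             config$library_size_lognormal[2])
        mu <- (lib * sscale) %o% (baseline * g$mult)
        x <- nb_block(mu, config$nb_dispersion)
        cellids <- sprintf("%s_%s_%03d", sname, g$id, seq_len(g$n))
        rownames(x) <- cellids
        hist <- if (is.null(g$hist)) rep("normal", g$n) else
          sample(names(g$hist), g$n, replace = TRUE, prob = g$hist)
        counts[[length(counts) + 1L]] <- x
        meta[[length(meta) + 1L]] <- data.frame(
          cell = cellids, sample = sname, histology = hist,
          is_reference = g$id == "normal", clone = g$id)
      }
    }
    counts <- do.call(rbind, counts)
    colnames(counts) <- genes$gene
    meta <- do.call(rbind, meta)
    cohort <- new_cohort(counts, meta[, c("cell", "sample", "histology",
                                          "is_reference")], genes)
    parent <- stats::setNames(
      vapply(config$clone_tree_spec, function(cl)
        if (is.na(cl$parent)) NA_character_ else cl$parent, character(1)), ids)
    events <- stats::setNames(lapply(config$clone_tree_spec, function(cl)
      sort(vapply(cl$events, event_key, character(1)))), ids)
    truth <- list(clone = stats::setNames(meta$clone, meta$cell),
                  histology = stats::setNames(meta$histology, meta$cell),
                  copy_number = cn, tree_parent = parent,
                  clone_events = events)
    list(cohort = cohort, truth = truth)
  })
}

#' Simulate a spatial section with region-structured clones
#'
#' Lays spots on an integer grid; each rectangular region is occupied by one
#' clone with one histology label, so clones are spatially contiguous by
#' construction. Counts follow the same dosage model as [simulate_cohort()].
#'
#' @param config a [simulation_config()] (provides genome, clones, noise).
#' @param grid_nrow,grid_ncol grid dimensions.
#' @param regions list of regions, each
#'   `list(rows =, cols =, clone =, histology =)`; `clone = "normal"` plants
#'   copy-neutral reference spots. Regions must not overlap.
#' @return list with `cohort` (spots with x/y coordinates) and `truth`
#'   (per-spot clone, region id, and planted region clone-adjacency graph).
#' @export
simulate_spatial_sections <- function(config, grid_nrow, grid_ncol, regions) {
  validate_sim_config(config)
  cover <- matrix(NA_integer_, grid_nrow, grid_ncol)
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    assert_that(max(r$rows) <= grid_nrow && max(r$cols) <= grid_ncol,
                "grid smaller than requested region layout")
    assert_that(all(is.na(cover[r$rows, r$cols])), "regions overlap")
    cover[r$rows, r$cols] <- i
  }
  n_spots <- sum(!is.na(cover))
  assert_that(grid_nrow * grid_ncol >= n_spots, "grid smaller than spot count")
  with_seed(config$seed + 1L, {
    genes <- make_gene_positions(config)
    ng <- nrow(genes)
    baseline <- stats::rlnorm(ng, config$baseline_lognormal[1],
                              config$baseline_lognormal[2])
    if (config$include_chrM)
      baseline[genes$chrom == "chrM"] <-
        stats::rlnorm(sum(genes$chrom == "chrM"), log(30), 0.3)
    cn <- clone_copy_matrix(config, genes)
    counts <- list(); meta <- list()
    for (i in seq_along(regions)) {
      r <- regions[[i]]
      idx <- which(cover == i, arr.ind = TRUE)
      n <- nrow(idx)
      m <- if (r$clone == "normal") rep(1, ng) else
        dosage_multiplier(cn[r$clone, ], config$dosage_floor)
      lib <- stats::rlnorm(n, config$library_size_lognormal[1],
                           config$library_size_lognormal[2])
      x <- nb_block(lib %o% (baseline * m), config$nb_dispersion)
      ids <- sprintf("spot_r%02d_%03d", i, seq_len(n))
      rownames(x) <- ids
      counts[[i]] <- x
      meta[[i]] <- data.frame(
        cell = ids, sample = "ST1",
        histology = if (r$clone == "normal") "normal" else r$histology,
        is_reference = r$clone == "normal",
        x = idx[, "col"], y = idx[, "row"], clone = r$clone, region = i)
    }
    counts <- do.call(rbind, counts); colnames(counts) <- genes$gene
    meta <- do.call(rbind, meta)
    cohort <- new_cohort(counts, meta[, c("cell", "sample", "histology",
                                          "is_reference", "x", "y")], genes)
    truth <- list(clone = stats::setNames(meta$clone, meta$cell),
                  region = stats::setNames(meta$region, meta$cell),
                  adjacency = region_adjacency(cover, regions))
    list(cohort = cohort, truth = truth)
  })
}

## Clone adjacency implied by the region layout (rook neighbourhood).
region_adjacency <- function(cover, regions) {
  cl <- vapply(regions, `[[`, character(1), "clone")
  edges <- character(0)
  nr <- nrow(cover); nc <- ncol(cover)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    a <- cover[r, c]
    if (is.na(a)) next
    for (d in list(c(0, 1), c(1, 0))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 > nr || c2 > nc) next
      b <- cover[r2, c2]
      if (is.na(b) || cl[a] == cl[b]) next
      edges <- c(edges, paste(sort(c(cl[a], cl[b])), collapse = "|"))
    }
  }
  sort(unique(edges))
}

#' Recompute the clone adjacency graph from emitted spot coordinates
#'
#' @param cells spot metadata with `x`, `y` columns.
#' @param clone per-spot clone labels (named by cell or aligned).
#' @return sorted character vector of undirected `"a|b"` edges.
#' @export
spot_adjacency <- function(cells, clone) {
  key <- paste(cells$x, cells$y)
  lab <- stats::setNames(as.character(clone), key)
  edges <- character(0)
  for (i in seq_len(nrow(cells))) {
    for (d in list(c(1, 0), c(0, 1))) {
      k2 <- paste(cells$x[i] + d[1], cells$y[i] + d[2])
      if (!k2 %in% names(lab)) next
      a <- lab[[key[i]]]; b <- lab[[k2]]
      if (a != b) edges <- c(edges, paste(sort(c(a, b)), collapse = "|"))
    }
  }
  sort(unique(edges))
}

#' Simulate a survival cohort with a planted expression cutpoint effect
#'
#' Event times are exponential with hazard `base_hazard * true_hr` for
#' subjects whose expression exceeds `true_cutpoint`; censoring is uniform
#' on `(0, censor_upper)`.
#'
#' @param n subjects (>= 20; smaller fixtures are underpowered).
#' @param true_hr hazard ratio above the cutpoint (> 0).
#' @param true_cutpoint threshold on the standard-normal expression score.
#' @param seed RNG seed.
#' @param base_hazard baseline exponential hazard.
#' @param censor_upper upper bound of the uniform censoring time.
#' @return data.frame `subject, time, event, expression`.
#' @export
simulate_survival_cohort <- function(n, true_hr, true_cutpoint = 0, seed = 1L,
                                     base_hazard = 0.1, censor_upper = 20) {
  assert_that(n >= 20, "n < 20 rejected: underpowered survival fixture")
  assert_that(true_hr > 0, "true_hr must be positive")
  with_seed(seed, {
    expr <- stats::rnorm(n)
    haz <- base_hazard * ifelse(expr > true_cutpoint, true_hr, 1)
    t_event <- stats::rexp(n, rate = haz)
    t_cens <- stats::runif(n, 0, censor_upper)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    assert_that(sum(event) > 0, "all subjects censored: no events to analyse")
    data.frame(subject = sprintf("P%04d", seq_len(n)), time = time,
               event = event, expression = expr)
  })
}
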