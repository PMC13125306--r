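## ---------------------------------------------------------------------------
## End-to-end pipeline and deterministic text outputs.
## ---------------------------------------------------------------------------

#' Run the full clonal-CNV pipeline on a cohort
#'
#' QC -> per-sample CNV inference -> malignancy calling -> clone clustering
#' (per sample, on tumor cells) -> per-cell HMM region calls with boundary
#' refinement -> clone-level consensus events -> clone tree with branch
#' lengths, node diameters and DCIS/IDC composition.
#'
#' @param x a `cohort`.
#' @param thresholds QC thresholds.
#' @param window,cutoff,k_sd CNV inference parameters.
#' @param k_malignant clusters for score-based malignancy calling.
#' @param clone_k clones per sample (`NULL`: silhouette selection).
#' @param min_fraction consensus support threshold.
#' @param tree_scale,tree_floor branch-length parameters.
#' @return named list per sample with `scores`, `malignancy`, `clones`,
#'   `events`, `tree`, `composition`, plus top-level `qc_report`.
#' @export
run_pipeline <- function(x, thresholds = qc_thresholds(), window = 101L,
                         cutoff = 0.1, k_sd = 1.5, k_malignant = 3L,
                         clone_k = NULL, min_fraction = 0.75,
                         tree_scale = 10, tree_floor = 2) {
  qc <- qc_filter(x, thresholds)
  x <- qc$cohort
  inf <- infer_cnv(x, cutoff = cutoff, window = window, k_sd = k_sd)
  out <- list(qc_report = qc$report, samples = list())
  for (s in names(inf)) {
    res <- inf[[s]]
    meta <- x$cells[x$cells$sample == s, ]
    mal <- classify_malignant(res$score, rep(s, length(res$score)),
                              k = k_malignant)
    tumor <- mal$cell[mal$label == "tumor"]
    sample_out <- list(scores = res$score, malignancy = mal,
                       sigma_ref = res$sigma_ref)
    if (length(tumor) >= 10) {
      clones <- cluster_clones(res$cnv[tumor, , drop = FALSE], k = clone_k)
      clone_ids <- stats::setNames(sprintf("%s_cl%d", s, clones),
                                   names(clones))
      calls <- call_states_hmm(
        res$cnv[tumor, , drop = FALSE], res$positions,
        sigma = res$sigma_ref, refine = TRUE,
        refine_on = res$residuals[tumor, , drop = FALSE])
      prof <- clone_profiles(res$cnv[tumor, , drop = FALSE], clone_ids)
      prof_res <- clone_profiles(res$residuals[tumor, , drop = FALSE],
                                 clone_ids)
      ## delta from the per-cell matrix: averaging denoised cells dilutes
      ## the nonzero-signal median the profile matrix would yield
      dlt <- stats::median(abs(res$cnv[res$cnv != 0]))
      pcalls <- call_states_hmm(prof, res$positions, sigma = res$sigma_ref,
                                delta = dlt, refine = TRUE,
                                refine_on = prof_res)
      ev <- consensus_clone_events(calls, clone_ids,
                                   min_fraction = min_fraction,
                                   profile_calls = pcalls)
      sample_out$clones <- clone_ids
      sample_out$events <- ev
      if (nrow(ev) > 0) {
        sets <- clone_event_sets(ev)
        nm <- table(clone_ids)[names(sets)]
        hist <- meta$histology[match(names(clone_ids), meta$cell)]
        comp <- clone_composition(unname(clone_ids), hist)
        sample_out$composition <- comp
        sample_out$tree <- build_tree(sets, n_members = nm,
                                      composition = comp,
                                      scale = tree_scale,
                                      floor_px = tree_floor)
      }
    }
    out$samples[[s]] <- sample_out
  }
  out
}

#' Write pipeline results as deterministic text files
#'
#' Emits, per sample: `<s>_scores.tsv`, `<s>_malignancy.tsv`,
#' `<s>_clones.tsv`, `<s>_events.tsv`, `<s>_tree_edges.tsv`, `<s>_tree.nwk`
#' and `<s>_tree.svg`; plus `qc_report.tsv`. No timestamps, so identical
#' runs produce byte-identical files.
#'
#' @param res output of [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$qc_report, file.path(dir, "qc_report.tsv"))
  for (s in names(res$samples)) {
    so <- res$samples[[s]]
    write_tsv(data.frame(cell = names(so$scores), score = unname(so$scores)),
              file.path(dir, paste0(s, "_scores.tsv")))
    write_tsv(so$malignancy, file.path(dir, paste0(s, "_malignancy.tsv")))
    if (!is.null(so$clones))
      write_tsv(data.frame(cell = names(so$clones),
                           clone = unname(so$clones)),
                file.path(dir, paste0(s, "_clones.tsv")))
    if (!is.null(so$events))
      write_tsv(so$events, file.path(dir, paste0(s, "_events.tsv")))
    if (!is.null(so$tree)) {
      write_tsv(so$tree$edges, file.path(dir, paste0(s, "_tree_edges.tsv")))
      writeLines(to_newick(so$tree), file.path(dir, paste0(s, "_tree.nwk")))
      write_tree_svg(so$tree, file.path(dir, paste0(s, "_tree.svg")))
    }
  }
  invisible(dir)
}
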