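## ---------------------------------------------------------------------------
## Clone-level consensus CNV events from per-cell region calls.
## ---------------------------------------------------------------------------

## Reciprocal overlap of two [start, end] gene intervals.
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2) + 1L
  if (ov <= 0) return(0)
  min(ov / (e1 - s1 + 1L), ov / (e2 - s2 + 1L))
}

## Cluster calls (rows of df with start_gene/end_gene) into connected
## components of the "reciprocal overlap >= min_overlap" graph
## (single linkage). Returns integer component labels.
overlap_components <- function(df, min_overlap) {
  n <- nrow(df)
  if (n == 1L) return(1L)
  s <- df$start_gene; e <- df$end_gene
  len <- e - s + 1L
  ov <- pmin(outer(e, e, pmin) - outer(s, s, pmax) + 1L, 0L + outer(len, len, pmin))
  ov[ov < 0L] <- 0L
  rec <- ov / outer(len, len, pmax)       # reciprocal = ov / max length
  adj <- rec >= min_overlap
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Consensus clone-level CNV events from per-cell calls
#'
#' Within each clone, same-chromosome same-direction per-cell calls are
#' grouped by overlap; a group becomes a clone event when at least
#' `min_fraction` of the clone's cells carry a call overlapping the group's
#' consensus region by at least `min_overlap` (reciprocal). The consensus
#' region takes the median start/end over supporting calls. Events are then
#' harmonised across clones (same chromosome + direction, reciprocal overlap
#' >= `min_overlap`) into shared `event_id`s so that clone event sets are
#' directly comparable for tree building.
#'
#' When `profile_calls` is supplied (clone-level region calls from
#' [call_states_hmm()] run on clone-mean profiles — the default segmentation
#' unit of the pipeline, with far lower noise than single cells), those
#' regions are used as the candidate events and the per-cell calls only
#' provide the supporting fractions.
#'
#' @param calls per-cell calls from [call_states_hmm()].
#' @param clone_labels named vector (cell -> clone id) covering every cell.
#' @param min_fraction minimum supporting cell fraction per clone.
#' @param min_overlap reciprocal gene-overlap threshold.
#' @param min_cells clones with fewer cells are skipped with a warning.
#' @param profile_calls optional clone-level calls (the `cell` column
#'   holding clone ids) defining the candidate regions.
#' @return data.frame of events: `clone, event_id, chrom, start_gene,
#'   end_gene, state, support` (supporting fraction), `n_cells`.
#' @export
consensus_clone_events <- function(calls, clone_labels, min_fraction = 0.75,
                                   min_overlap = 0.5, min_cells = 5L,
                                   profile_calls = NULL) {
  cells <- names(clone_labels)
  assert_that(!is.null(cells), "clone_labels must be named by cell")
  assert_that(all(calls$cell %in% cells),
              "calls contain cells without a clone label")
  events <- list()
  for (cl in unique(clone_labels)) {
    members <- cells[clone_labels == cl]
    if (length(members) < min_cells) {
      warnf("clone %s has %d (< %d) cells; skipped", cl, length(members),
            min_cells)
      next
    }
    cc <- calls[calls$cell %in% members, , drop = FALSE]
    cand <- list()
    if (is.null(profile_calls)) {
      ## candidates from per-cell calls: overlap clusters, median boundaries
      for (chrom in unique(cc$chrom)) for (st in unique(cc$state)) {
        d <- cc[cc$chrom == chrom & cc$state == st, , drop = FALSE]
        if (nrow(d) == 0) next
        comp <- overlap_components(d, min_overlap)
        for (k in unique(comp))
          cand[[length(cand) + 1L]] <- list(
            chrom = chrom, state = st,
            s = as.integer(round(stats::median(d$start_gene[comp == k]))),
            e = as.integer(round(stats::median(d$end_gene[comp == k]))))
      }
    } else {
      pc <- profile_calls[profile_calls$cell == cl, , drop = FALSE]
      for (i in seq_len(nrow(pc)))
        cand[[length(cand) + 1L]] <- list(
          chrom = pc$chrom[i], state = pc$state[i],
          s = pc$start_gene[i], e = pc$end_gene[i])
    }
    for (cn in cand) {
      d <- cc[cc$chrom == cn$chrom & cc$state == cn$state, , drop = FALSE]
      supp <- if (nrow(d) == 0) logical(0) else
        vapply(seq_len(nrow(d)), function(i)
          reciprocal_overlap(d$start_gene[i], d$end_gene[i], cn$s, cn$e) >=
            min_overlap, logical(1))
      frac <- length(unique(d$cell[supp])) / length(members)
      if (frac >= min_fraction)
        events[[length(events) + 1L]] <- data.frame(
          clone = cl, chrom = cn$chrom, start_gene = cn$s, end_gene = cn$e,
          state = cn$state, support = frac, n_cells = length(members))
    }
  }
  if (length(events) == 0)
    return(data.frame(clone = character(0), event_id = character(0),
                      chrom = character(0), start_gene = integer(0),
                      end_gene = integer(0), state = character(0),
                      support = numeric(0), n_cells = integer(0)))
  ev <- do.call(rbind, events)
  harmonise_events(ev, min_overlap)
}

## Assign shared event ids across clones: cluster events by chromosome +
## direction + reciprocal overlap, canonical region = median over members.
harmonise_events <- function(ev, min_overlap = 0.5) {
  ev$event_id <- NA_character_
  for (chrom in unique(ev$chrom)) for (st in unique(ev$state)) {
    i <- which(ev$chrom == chrom & ev$state == st)
    if (length(i) == 0) next
    comp <- overlap_components(ev[i, , drop = FALSE], min_overlap)
    for (k in unique(comp)) {
      j <- i[comp == k]
      s <- as.integer(round(stats::median(ev$start_gene[j])))
      e <- as.integer(round(stats::median(ev$end_gene[j])))
      ev$event_id[j] <- sprintf("%s:%d-%d:%s", chrom, s, e,
                                if (st == "amplification") "amp" else "del")
    }
  }
  ev[order(ev$clone, ev$chrom, ev$start_gene), , drop = FALSE]
}

#' Collect per-clone event sets from a consensus event table
#'
#' @param ev output of [consensus_clone_events()].
#' @return named list clone -> character vector of event ids.
#' @export
clone_event_sets <- function(ev) {
  lapply(split(ev$event_id, ev$clone), function(x) sort(unique(x)))
}
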