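## ---------------------------------------------------------------------------
## Clone phylogenies from CNV event sets under the irreversibility
## assumption: an event, once acquired, is never lost, so shared events imply
## common ancestry and event-set inclusion defines parenthood. The root is
## the inferred common ancestor P carrying the intersection of all clone
## event sets; partially overlapping clones attach through synthesized
## internal ancestors carrying their intersection.
## ---------------------------------------------------------------------------

#' Branch length from event-count difference
#'
#' `bk = scale * log2(z_descendant - z_parent)` for differences of at least
#' 2 events. The formula is undefined at differences 0 and 1 (log2(0) and
#' log2(1) = 0), so those branches get a configurable pixel floor that keeps
#' them visually discernible.
#'
#' @param z_descendant,z_parent event counts of descendant and parent clone;
#'   `z_descendant >= z_parent` (anything else is an upstream
#'   irreversibility violation).
#' @param scale multiplier of the log2 difference (pixels).
#' @param floor_px minimum branch length (pixels).
#' @return branch length in pixels.
#' @export
branch_length <- function(z_descendant, z_parent, scale = 10, floor_px = 2) {
  assert_that(z_parent >= 0 && z_descendant >= z_parent,
              "z_descendant < z_parent: irreversibility violation upstream")
  diff <- z_descendant - z_parent
  if (diff < 2) return(floor_px)
  max(floor_px, scale * log2(diff))
}

#' Node diameter from clone prevalence
#'
#' `dl = sqrt(p)` where `p` is the percentage (0-100) of a sample's
#' epithelial spots/cells assigned to the clone.
#'
#' @param p_percent percentage in `[0, 100]`.
#' @return diameter in pixels.
#' @export
node_diameter <- function(p_percent) {
  assert_that(all(p_percent >= 0 & p_percent <= 100),
              "p must be a percentage in [0, 100]")
  sqrt(p_percent)
}

#' Per-clone DCIS/IDC composition
#'
#' @param clone per-cell clone labels (named or aligned with `histology`).
#' @param histology per-cell labels in `{DCIS, IDC, normal, NA}`; only
#'   DCIS/IDC enter the denominator.
#' @return data.frame `clone, n_dcis, n_idc, frac_dcis, frac_idc, defined`;
#'   clones without any labelled member are flagged `defined = FALSE` with
#'   `NA` fractions (not 0/0).
#' @export
clone_composition <- function(clone, histology) {
  assert_that(length(clone) == length(histology), "length mismatch")
  out <- lapply(sort(unique(clone)), function(cl) {
    h <- histology[clone == cl]
    nd <- sum(h == "DCIS", na.rm = TRUE)
    ni <- sum(h == "IDC", na.rm = TRUE)
    tot <- nd + ni
    data.frame(clone = cl, n_dcis = nd, n_idc = ni,
               frac_dcis = if (tot > 0) nd / tot else NA_real_,
               frac_idc = if (tot > 0) ni / tot else NA_real_,
               defined = tot > 0)
  })
  do.call(rbind, out)
}

set_key <- function(s) paste(sort(s), collapse = "\r")

#' Build a clone tree from event sets
#'
#' The root P carries the intersection of all clone event sets. Each clone's
#' parent is the node with the largest event set that is a strict subset of
#' its own; non-nested clones attach to a synthesized internal ancestor
#' carrying their pairwise intersection. Synthesized nodes with a single
#' child (other than the root) are spliced out. Clones with identical event
#' sets are merged with a warning; opposite-direction events on the same
#' region between two clones are irreversibility violations: they are
#' reported and the tree is built on the non-conflicting events.
#'
#' @param clones named list clone id -> character vector of event ids
#'   (format `"chrom:start-end:dir"`), e.g. from [clone_event_sets()].
#' @param n_members optional named vector of member counts per clone (for
#'   node sizes).
#' @param composition optional output of [clone_composition()].
#' @param scale,floor_px passed to [branch_length()].
#' @return a `clone_tree`: list with `nodes` (data.frame `id, n_events,
#'   synthesized, n_members, diameter, frac_dcis, frac_idc`), `edges`
#'   (data.frame `parent, child, bk, z_parent, z_child`), `root`,
#'   `events` (per-node event sets), `violations` (conflicting event pairs),
#'   `merged` (id -> representative for merged clones).
#' @export
build_tree <- function(clones, n_members = NULL, composition = NULL,
                       scale = 10, floor_px = 2) {
  assert_that(length(clones) >= 1, "need at least one clone")
  assert_that(!is.null(names(clones)), "clones must be a named list")
  clones <- lapply(clones, function(s) sort(unique(s)))

  ## irreversibility violations: same region, opposite direction anywhere
  all_ev <- unique(unlist(clones))
  reg <- sub(":(amp|del)$", "", all_ev)
  dir <- sub("^.*:", "", all_ev)
  viol <- character(0)
  for (r in unique(reg[duplicated(reg)])) {
    d <- dir[reg == r]
    if (length(unique(d)) > 1) viol <- c(viol, r)
  }
  if (length(viol) > 0) {
    warnf("irreversibility violation on region(s) %s; excluded from tree",
          paste(viol, collapse = ", "))
    drop <- all_ev[reg %in% viol]
    clones <- lapply(clones, setdiff, y = drop)
  }

  ## merge identical event sets
  keys <- vapply(clones, set_key, character(1))
  merged <- stats::setNames(names(clones)[match(keys, keys)], names(clones))
  if (anyDuplicated(keys)) {
    dups <- names(clones)[duplicated(keys)]
    warnf("clones with identical event sets merged: %s",
          paste(dups, collapse = ", "))
  }
  uniq <- !duplicated(keys)
  sets <- clones[uniq]

  ## closure under pairwise intersection (synthesized internal ancestors)
  repeat {
    added <- FALSE
    ks <- vapply(sets, set_key, character(1))
    nn <- length(sets)
    for (i in seq_len(nn)) for (j in seq_len(nn)) {
      if (i >= j) next
      int <- intersect(sets[[i]], sets[[j]])
      if (!set_key(int) %in% ks) {
        sets[[sprintf("anc%02d", sum(startsWith(names(sets), "anc")) + 1L)]] <- int
        ks <- c(ks, set_key(int))
        added <- TRUE
      }
    }
    if (!added) break
  }
  ## root P = intersection of all observed clone sets
  root_set <- Reduce(intersect, clones[uniq])
  if (!set_key(root_set) %in% vapply(sets, set_key, character(1)))
    sets[["P"]] <- root_set

  ids <- names(sets)
  sizes <- lengths(sets)
  root <- ids[match(set_key(root_set), vapply(sets, set_key, character(1)))]
  observed <- names(clones)[uniq]

  ## parent = largest strict subset; prefer observed clones, then smaller id
  parent <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (id in setdiff(ids, root)) {
    cand <- ids[vapply(ids, function(o)
      length(sets[[o]]) < sizes[[id]] && all(sets[[o]] %in% sets[[id]]),
      logical(1))]
    if (length(cand) == 0) { parent[id] <- root; next }
    cand <- cand[order(-lengths(sets[cand]), !(cand %in% observed), cand)]
    parent[id] <- cand[1]
  }
  ## splice out synthesized single-child non-root nodes
  repeat {
    synth <- setdiff(ids, c(observed, root))
    nch <- table(factor(parent, levels = ids))
    drop <- synth[nch[synth] == 1L]
    if (length(drop) == 0) break
    d <- drop[1]
    parent[parent == d & !is.na(parent)] <- parent[[d]]
    ids <- setdiff(ids, d); sets[[d]] <- NULL
    parent <- parent[ids]; sizes <- sizes[ids]
  }
  ## also drop childless synthesized nodes (can arise from the closure)
  repeat {
    synth <- setdiff(ids, c(observed, root))
    nch <- table(factor(parent, levels = ids))
    drop <- synth[nch[synth] == 0L]
    if (length(drop) == 0) break
    ids <- setdiff(ids, drop)
    for (d in drop) sets[[d]] <- NULL
    parent <- parent[ids]; sizes <- sizes[ids]
  }

  ## a synthesized root is the inferred common ancestor: call it P
  if (!(root %in% observed) && !"P" %in% ids) {
    names(sets)[names(sets) == root] <- "P"
    parent[parent == root & !is.na(parent)] <- "P"
    names(parent)[names(parent) == root] <- "P"
    ids[ids == root] <- "P"
    root <- "P"
  }

  edges <- do.call(rbind, lapply(setdiff(ids, root), function(id)
    data.frame(parent = parent[[id]], child = id,
               z_parent = length(sets[[parent[[id]]]]),
               z_child = length(sets[[id]]),
               bk = branch_length(length(sets[[id]]),
                                  length(sets[[parent[[id]]]]),
                                  scale, floor_px))))
  if (is.null(edges))
    edges <- data.frame(parent = character(0), child = character(0),
                        z_parent = integer(0), z_child = integer(0),
                        bk = numeric(0))
  nm <- if (is.null(n_members)) stats::setNames(rep(NA_integer_, length(ids)), ids)
        else stats::setNames(n_members[ids], ids)
  total <- sum(nm, na.rm = TRUE)
  diam <- vapply(ids, function(id)
    if (!is.na(nm[[id]]) && total > 0) node_diameter(100 * nm[[id]] / total)
    else NA_real_, numeric(1))
  nodes <- data.frame(id = ids, n_events = unname(lengths(sets[ids])),
                      synthesized = !(ids %in% observed),
                      n_members = unname(nm[ids]), diameter = unname(diam))
  if (!is.null(composition)) {
    m <- match(nodes$id, composition$clone)
    nodes$frac_dcis <- composition$frac_dcis[m]
    nodes$frac_idc <- composition$frac_idc[m]
  }
  structure(list(nodes = nodes, edges = edges, root = root,
                 events = sets[ids], violations = viol, merged = merged),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("<clone_tree> %d nodes (%d synthesized), root = %s\n",
              nrow(x$nodes), sum(x$nodes$synthesized), x$root))
  invisible(x)
}

#' Serialize a clone tree to Newick
#'
#' Branch lengths are the `bk` values; node labels are clone ids. The output
#' round-trips through standard Newick parsers (e.g. `ape::read.tree`),
#' except the degenerate single-node tree, emitted as `"P;"`.
#'
#' @param t a `clone_tree`.
#' @return Newick string.
#' @export
to_newick <- function(t) {
  kids <- split(t$edges$child, t$edges$parent)
  bk <- stats::setNames(t$edges$bk, t$edges$child)
  rec <- function(id) {
    ch <- kids[[id]]
    lab <- gsub("[(),:;\\s]", "_", id)
    if (is.null(ch)) return(lab)
    paste0("(", paste(vapply(sort(ch), function(c2)
      paste0(rec(c2), ":", format(bk[[c2]], digits = 10)),
      character(1)), collapse = ","), ")", lab)
  }
  paste0(rec(t$root), ";")
}

#' Render a clone tree as a simple SVG
#'
#' Rectangular layout: branch lengths horizontal (`bk` pixels), nodes as
#' circles of diameter `dl` with a DCIS/IDC pie wedge when composition is
#' available.
#'
#' @param t a `clone_tree`.
#' @param path output file.
#' @param unit horizontal pixels per bk unit; `gap` vertical spacing.
#' @return `path`, invisibly.
#' @export
write_tree_svg <- function(t, path, unit = 3, gap = 40) {
  kids <- split(t$edges$child, t$edges$parent)
  bk <- stats::setNames(t$edges$bk, t$edges$child)
  xpos <- stats::setNames(numeric(nrow(t$nodes)), t$nodes$id)
  ypos <- xpos
  leaf_y <- 0
  assign_pos <- function(id, x0) {
    xpos[[id]] <<- x0
    ch <- kids[[id]]
    if (is.null(ch)) {
      leaf_y <<- leaf_y + gap
      ypos[[id]] <<- leaf_y
    } else {
      for (c2 in sort(ch)) assign_pos(c2, x0 + bk[[c2]] * unit)
      ypos[[id]] <<- mean(ypos[sort(ch)])
    }
  }
  assign_pos(t$root, 20)
  w <- max(xpos) + 60; h <- leaf_y + gap
  seg <- function(x1, y1, x2, y2)
    sprintf('<path d="M %.1f %.1f L %.1f %.1f L %.1f %.1f" stroke="black" fill="none"/>',
            x1, y1, x1, y2, x2, y2)
  lines <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f">', w, h))
  for (i in seq_len(nrow(t$edges)))
    lines <- c(lines, seg(xpos[[t$edges$parent[i]]], ypos[[t$edges$parent[i]]],
                          xpos[[t$edges$child[i]]], ypos[[t$edges$child[i]]]))
  for (i in seq_len(nrow(t$nodes))) {
    id <- t$nodes$id[i]
    r <- if (is.na(t$nodes$diameter[i])) 4 else max(t$nodes$diameter[i] / 2, 2)
    fd <- if ("frac_dcis" %in% names(t$nodes)) t$nodes$frac_dcis[i] else NA
    if (!is.na(fd) && fd < 1 && fd > 0) {
      ang <- 2 * pi * fd
      lines <- c(lines,
        sprintf('<circle cx="%.1f" cy="%.1f" r="%.2f" fill="chartreuse" stroke="black"/>',
                xpos[[id]], ypos[[id]], r),
        sprintf('<path d="M %.1f %.1f L %.1f %.1f A %.2f %.2f 0 %d 1 %.1f %.1f Z" fill="dodgerblue" stroke="black"/>',
                xpos[[id]], ypos[[id]], xpos[[id]], ypos[[id]] - r, r, r,
                as.integer(ang > pi),
                xpos[[id]] + r * sin(ang), ypos[[id]] - r * cos(ang)))
    } else {
      fill <- if (t$nodes$synthesized[i]) "black"
              else if (!is.na(fd) && fd >= 1) "dodgerblue"
              else if (!is.na(fd)) "chartreuse" else "grey"
      lines <- c(lines,
        sprintf('<circle cx="%.1f" cy="%.1f" r="%.2f" fill="%s" stroke="black"/>',
                xpos[[id]], ypos[[id]], r, fill))
    }
    lines <- c(lines,
      sprintf('<text x="%.1f" y="%.1f" font-size="10">%s</text>',
              xpos[[id]] + r + 2, ypos[[id]] + 3, id))
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}
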