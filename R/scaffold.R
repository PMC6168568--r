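# Ordering and orienting draft contigs into chromosomes from cross-contig
# synteny continuity on reference genomes, constrained by subtelomeric and
# pericentromeric marker genes.

end_id <- function(contig, side) paste0(contig, ":", side)
end_contig <- function(end) sub(":[LR]$", "", end)
end_side <- function(end) sub("^.*:", "", end)

#' Classify contig ends by marker content
#'
#' Each end is labelled `subtelomeric` when a subtelomeric-class marker
#' lies within `margin_bp` of it, otherwise `pericentromeric` when such a
#' marker does, otherwise `internal`. Pericentromeric markers anywhere on
#' the contig additionally set a contig-level flag used to check that every
#' assembled chromosome contains a centromere.
#'
#' @param genes gene table with `marker_class`.
#' @param contigs contig table (`contig_id`, `length`).
#' @param margin_bp end margin in bp (default 50000).
#' @return tibble: `contig_id`, `end` (`"left"`/`"right"`), `label`,
#'   `evidence` (comma-joined marker gene ids),
#'   `has_pericentromeric` (contig-level flag, repeated on both rows).
#' @export
classify_contig_ends <- function(genes, contigs, margin_bp = 50000) {
  purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    cid <- contigs$contig_id[i]
    len <- contigs$length[i]
    g <- genes[genes$contig_id == cid, , drop = FALSE]
    peri_any <- any(g$marker_class == "pericentromeric")
    one_end <- function(side) {
      near <- if (side == "left") g$start < margin_bp else g$end > len - margin_bp
      gm <- g[near & g$marker_class %in% c("subtelomeric", "pericentromeric"), ,
              drop = FALSE]
      label <- if (any(gm$marker_class == "subtelomeric")) "subtelomeric"
               else if (any(gm$marker_class == "pericentromeric")) "pericentromeric"
               else "internal"
      ev <- gm$gene_id[gm$marker_class == label]
      tibble::tibble(contig_id = cid, end = side, label = label,
                     evidence = paste(ev, collapse = ","),
                     has_pericentromeric = peri_any)
    }
    dplyr::bind_rows(one_end("left"), one_end("right"))
  })
}

#' Candidate contig adjacencies from reference synteny
#'
#' On each reference chromosome, two blocks that are within
#' `max_reference_gap_bp` of each other and whose contig-side spans reach
#' the respective contig ends (within `end_margin_bp`) bridge a junction
#' between those two contig ends. Orientation fixes which ends pair: a `+`
#' block continues off the right end of its contig, a `-` block off the
#' left. Support is the bridging anchor count (sum of the two block
#' weights), summed per reference over all bridging block pairs.
#'
#' @param blocks_by_ref named list of block tibbles, one per reference
#'   genome, with the draft contigs on the `a` side and the reference on
#'   the `b` side.
#' @param contigs draft contig table (`contig_id`, `length`).
#' @param max_reference_gap_bp maximum on-reference gap between bridging
#'   blocks (default 30000).
#' @param end_margin_bp how close to a contig end a block must reach
#'   (default 50000).
#' @return tibble: `end_1`, `end_2` (canonical order, `"<contig>:L"` /
#'   `":R"`), `support`, `reference`.
#' @export
build_adjacency_graph <- function(blocks_by_ref, contigs,
                                  max_reference_gap_bp = 30000,
                                  end_margin_bp = 50000) {
  len <- stats::setNames(contigs$length, contigs$contig_id)
  rows <- list()
  for (ref in names(blocks_by_ref)) {
    b <- blocks_by_ref[[ref]]
    if (!nrow(b)) next
    b <- b[order(b$contig_b, b$b_start), , drop = FALSE]
    ij <- expand.grid(i = seq_len(nrow(b)), j = seq_len(nrow(b)))
    ij <- ij[ij$i < ij$j, , drop = FALSE]
    for (k in seq_len(nrow(ij))) {
      i <- ij$i[k]; j <- ij$j[k]
      if (b$contig_b[i] != b$contig_b[j]) next
      # j must start past i's end but within the gap window; blocks from
      # rearranged segments may interleave, so all such pairs are scanned,
      # not only consecutive ones
      if (b$b_start[j] < b$b_end[i]) next
      if (b$b_start[j] - b$b_end[i] > max_reference_gap_bp) next
      if (b$contig_a[i] == b$contig_a[j]) next
      # which end of each contig faces the junction
      side_i <- if (b$sign[i] == "+") "R" else "L"
      side_j <- if (b$sign[j] == "+") "L" else "R"
      reaches_i <- if (side_i == "R")
        b$a_end[i] > len[b$contig_a[i]] - end_margin_bp
      else b$a_start[i] < end_margin_bp
      reaches_j <- if (side_j == "R")
        b$a_end[j] > len[b$contig_a[j]] - end_margin_bp
      else b$a_start[j] < end_margin_bp
      if (!isTRUE(reaches_i) || !isTRUE(reaches_j)) next
      e1 <- end_id(b$contig_a[i], side_i)
      e2 <- end_id(b$contig_a[j], side_j)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        end_1 = min(e1, e2), end_2 = max(e1, e2),
        support = b$weight[i] + b$weight[j], reference = ref)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(end_1 = character(), end_2 = character(),
                          support = numeric(), reference = character()))
  }
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$end_1, .data$end_2, .data$reference) |>
    dplyr::summarise(support = sum(.data$support), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$support), .data$end_1, .data$end_2)
}

# resolve cross-reference disagreements: when two references propose
# different partners for one contig end, the earlier reference in the
# priority order wins; dropped proposals are reported as conflicts
resolve_reference_conflicts <- function(candidates, reference_priority) {
  rank <- stats::setNames(seq_along(reference_priority), reference_priority)
  candidates$ref_rank <- rank[candidates$reference]
  candidates$ref_rank[is.na(candidates$ref_rank)] <- length(rank) + 1L
  conflicts <- tibble::tibble(end = character(), winner_reference = character(),
                              loser_reference = character(),
                              winner_partner = character(),
                              loser_partner = character())
  drop <- rep(FALSE, nrow(candidates))
  ends <- unique(c(candidates$end_1, candidates$end_2))
  for (e in ends) {
    at_e <- which(!drop & (candidates$end_1 == e | candidates$end_2 == e))
    if (length(at_e) < 2) next
    partner <- ifelse(candidates$end_1[at_e] == e,
                      candidates$end_2[at_e], candidates$end_1[at_e])
    if (length(unique(partner)) < 2) next
    best <- min(candidates$ref_rank[at_e])
    keep_partners <- unique(partner[candidates$ref_rank[at_e] == best])
    bad <- at_e[!(partner %in% keep_partners)]
    for (k in bad) {
      conflicts <- dplyr::bind_rows(conflicts, tibble::tibble(
        end = e,
        winner_reference = candidates$reference[at_e[candidates$ref_rank[at_e] == best][1]],
        loser_reference = candidates$reference[k],
        winner_partner = keep_partners[1],
        loser_partner = ifelse(candidates$end_1[k] == e,
                               candidates$end_2[k], candidates$end_1[k])))
    }
    drop[bad] <- TRUE
  }
  list(candidates = candidates[!drop, , drop = FALSE], conflicts = conflicts)
}

#' Order and orient contigs into chromosomes
#'
#' Greedy maximum-support path cover over the contig-end adjacency graph
#' with constraint backtracking: exactly `n_chromosomes` paths, every path
#' terminating at subtelomeric-labelled ends and containing at least one
#' pericentromeric contig, every contig used once. When references
#' disagree on an adjacency the earlier genome in `reference_priority`
#' wins and the conflict is reported. If a second, different cover of equal
#' total support exists the result is flagged non-unique rather than
#' silently chosen. Chromosomes are named by descending assembled length;
#' each path is reported in canonical orientation (lexicographically
#' smaller terminal end first).
#'
#' @param candidates adjacency candidates from [build_adjacency_graph()].
#' @param end_labels end labels from [classify_contig_ends()].
#' @param contigs draft contig table (for lengths and the contig universe).
#' @param n_chromosomes number of chromosomes to assemble.
#' @param reference_priority character vector of reference names, closest
#'   first; defaults to the order references appear in `candidates`.
#' @return list with `assemblies` (tibble `chromosome`, `ord`, `contig_id`,
#'   `orientation`), `conflicts` (cross-reference disagreements), and
#'   `unique` (FALSE when an equally supported alternative cover exists).
#' @export
order_contigs <- function(candidates, end_labels, contigs, n_chromosomes,
                          reference_priority = NULL) {
  stopifnot(n_chromosomes >= 1)
  reference_priority <- reference_priority %||% unique(candidates$reference)
  sub_ends <- end_labels[end_labels$label == "subtelomeric", , drop = FALSE]
  if (nrow(sub_ends) < 2 * n_chromosomes) {
    abort_bad_arg(paste0(
      "infeasible: ", nrow(sub_ends), " subtelomeric end(s) found but ",
      2 * n_chromosomes, " needed; missing evidence on contigs: ",
      paste(setdiff(contigs$contig_id, sub_ends$contig_id), collapse = ", ")))
  }
  res <- resolve_reference_conflicts(candidates, reference_priority)
  cand <- res$candidates |>
    dplyr::group_by(.data$end_1, .data$end_2) |>
    dplyr::summarise(support = sum(.data$support),
                     reference = paste(unique(.data$reference), collapse = ","),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$support), .data$end_1, .data$end_2)

  n_edges_needed <- nrow(contigs) - n_chromosomes
  sub_set <- end_id(sub_ends$contig_id,
                    ifelse(sub_ends$end == "left", "L", "R"))
  peri <- stats::setNames(
    end_labels$has_pericentromeric[!duplicated(end_labels$contig_id)],
    end_labels$contig_id[!duplicated(end_labels$contig_id)])

  # DFS over edges in support order: accept when both ends are free and no
  # cycle closes; reject branch explored afterwards (constraint backtracking)
  cids <- contigs$contig_id
  uf_find <- function(parent, x) { while (parent[x] != x) x <- parent[x]; x }
  best <- NULL; best_support <- -Inf; n_best <- 0L; solutions_differ <- FALSE
  budget <- 200000L
  search <- function(k, parent, used, picked, support) {
    if (budget <= 0L) return()
    budget <<- budget - 1L
    if (length(picked) == n_edges_needed) {
      free <- setdiff(c(end_id(cids, "L"), end_id(cids, "R")),
                      unlist(cand[picked, c("end_1", "end_2")]))
      if (!all(free %in% sub_set)) return()
      comp <- vapply(cids, function(cc) uf_find(parent, which(cids == cc)), 0L)
      ok_peri <- all(vapply(split(cids, comp), function(cc)
        any(peri[cc]), TRUE))
      if (!ok_peri) return()
      if (support > best_support) {
        best <<- picked; best_support <<- support; n_best <<- 1L
        solutions_differ <<- FALSE
      } else if (support == best_support) {
        n_best <<- n_best + 1L
        if (!identical(sort(picked), sort(best))) solutions_differ <<- TRUE
      }
      return()
    }
    if (k > nrow(cand)) return()
    if (length(picked) + (nrow(cand) - k + 1) < n_edges_needed) return()
    e1 <- cand$end_1[k]; e2 <- cand$end_2[k]
    c1 <- which(cids == end_contig(e1)); c2 <- which(cids == end_contig(e2))
    if (!(e1 %in% used) && !(e2 %in% used) &&
        uf_find(parent, c1) != uf_find(parent, c2)) {
      p2 <- parent; p2[uf_find(p2, c1)] <- uf_find(p2, c2)
      search(k + 1, p2, c(used, e1, e2), c(picked, k),
             support + cand$support[k])
    }
    search(k + 1, parent, used, picked, support)
  }
  search(1L, seq_along(cids), character(0), integer(0), 0)
  if (is.null(best)) {
    abort_bad_arg(paste0(
      "infeasible: no path cover into ", n_chromosomes,
      " chromosome(s) satisfies the subtelomeric/pericentromeric constraints"))
  }

  # walk paths from terminal ends
  edges <- cand[best, , drop = FALSE]
  partner <- c(stats::setNames(edges$end_2, edges$end_1),
               stats::setNames(edges$end_1, edges$end_2))
  all_ends <- c(end_id(cids, "L"), end_id(cids, "R"))
  terminals <- setdiff(all_ends, c(edges$end_1, edges$end_2))
  paths <- list()
  seen <- character(0)
  for (t0 in sort(terminals)) {
    if (t0 %in% seen) next
    path <- tibble::tibble(contig_id = character(), orientation = character())
    e <- t0
    repeat {
      cc <- end_contig(e)
      ori <- if (end_side(e) == "L") "+" else "-"
      path <- dplyr::bind_rows(path, tibble::tibble(contig_id = cc,
                                                    orientation = ori))
      other <- end_id(cc, if (end_side(e) == "L") "R" else "L")
      seen <- c(seen, e, other)
      if (!other %in% names(partner)) break
      e <- partner[[other]]
    }
    paths[[length(paths) + 1L]] <- path
  }
  lens <- vapply(paths, function(p)
    sum(contigs$length[match(p$contig_id, contigs$contig_id)]), 0)
  paths <- paths[order(-lens)]
  assemblies <- purrr::imap_dfr(paths, function(p, i) {
    tibble::tibble(chromosome = paste0("chr", i), ord = seq_len(nrow(p)),
                   contig_id = p$contig_id, orientation = p$orientation)
  })
  list(assemblies = assemblies, conflicts = res$conflicts,
       unique = !solutions_differ)
}

#' Lift contig-space blocks onto assembled chromosome coordinates
#'
#' Rewrites the `a` side of a block table from draft-contig coordinates to
#' the coordinates of the chromosomes assembled by [order_contigs()]
#' (contigs laid out in order with `spacer_bp` gaps; blocks on flipped
#' contigs have their spans mirrored and their sign inverted). Needed
#' before computing rearrangement distances between an assembled draft and
#' a reference, so that contig fragmentation does not masquerade as
#' rearrangement.
#'
#' @param blocks block tibble with the draft on the `a` side.
#' @param assemblies assembly tibble from [order_contigs()].
#' @param contigs draft contig table.
#' @param spacer_bp gap placed between consecutive contigs (default 100).
#' @return list with `blocks` (lifted) and `contigs` (tibble
#'   `contig_id` = chromosome, `length`).
#' @export
lift_blocks_to_assembly <- function(blocks, assemblies, contigs,
                                    spacer_bp = 100) {
  asm <- assemblies[order(assemblies$chromosome, assemblies$ord), ,
                    drop = FALSE]
  asm$len <- contigs$length[match(asm$contig_id, contigs$contig_id)]
  asm <- asm |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(offset = cumsum(c(0, utils::head(.data$len + spacer_bp,
                                                   -1)))) |>
    dplyr::ungroup()
  i <- match(blocks$contig_a, asm$contig_id)
  if (anyNA(i)) abort_bad_arg("block on a contig absent from the assembly")
  flip <- asm$orientation[i] == "-"
  new_start <- ifelse(flip, asm$offset[i] + asm$len[i] - blocks$a_end,
                      asm$offset[i] + blocks$a_start)
  new_end <- ifelse(flip, asm$offset[i] + asm$len[i] - blocks$a_start,
                    asm$offset[i] + blocks$a_end)
  out <- blocks
  out$contig_a <- asm$chromosome[i]
  out$a_start <- new_start
  out$a_end <- new_end
  out$sign <- ifelse(flip, ifelse(blocks$sign == "+", "-", "+"),
                     blocks$sign)
  chroms <- asm |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(length = sum(.data$len) +
                       spacer_bp * (dplyr::n() - 1), .groups = "drop")
  list(blocks = out,
       contigs = tibble::tibble(contig_id = chroms$chromosome,
                                length = chroms$length))
}

#' Write an assembly as an AGP-like table / FASTA
#'
#' The FASTA export concatenates each chromosome's contigs in order and
#' orientation with 100-`N` spacers between them (overlapping contig ends
#' are not merged).
#'
#' @param assemblies assembly tibble from [order_contigs()].
#' @param path output path.
#' @return input, invisibly.
#' @export
write_assembly <- function(assemblies, path) {
  readr::write_tsv(assemblies, path)
  invisible(assemblies)
}

#' @rdname write_assembly
#' @param g draft `genome` holding the contig sequences.
#' @export
write_assembly_fasta <- function(assemblies, g, path) {
  if (is.null(g$seqs)) abort_bad_arg("draft genome carries no sequences")
  spacer <- paste(rep("N", 100), collapse = "")
  out <- vapply(split(assemblies, assemblies$chromosome), function(a) {
    a <- a[order(a$ord), , drop = FALSE]
    pieces <- vapply(seq_len(nrow(a)), function(i) {
      s <- g$seqs[[a$contig_id[i]]]
      if (a$orientation[i] == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, "")
    paste(pieces, collapse = spacer)
  }, "")
  seqs <- Biostrings::DNAStringSet(out)
  Biostrings::writeXStringSet(seqs, path)
  invisible(assemblies)
}
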