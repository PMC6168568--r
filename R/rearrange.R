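# Double-cut-and-join (DCJ) rearrangement distance and typed sorting
# scenarios for multichromosomal signed genomes.
#
# Marker g has two extremities: tail (2g-1) and head (2g). Reading +g left
# to right visits tail then head; -g visits head then tail. A genome is a
# set of adjacencies (pairs of consecutive extremities) and telomeres
# (unpaired extremities at linear chromosome ends). The DCJ distance between
# genomes on N common markers is N - C - I/2, where C counts cycles and I
# odd-length paths of the adjacency graph.

ext_left <- function(g) ifelse(g > 0, 2L * g - 1L, -2L * g)
ext_right <- function(g) ifelse(g > 0, 2L * g, -2L * g - 1L)

# partner extremity of every extremity (0 = telomere) for one genome
adjacency_map <- function(chroms, circular, n_markers) {
  adj <- integer(2L * n_markers)
  for (ci in seq_along(chroms)) {
    v <- chroms[[ci]]
    n <- length(v)
    if (n > 1) {
      x <- ext_right(v[-n]); y <- ext_left(v[-1])
      adj[x] <- y; adj[y] <- x
    }
    if (isTRUE(circular[ci]) && n >= 1) {
      x <- ext_right(v[n]); y <- ext_left(v[1])
      adj[x] <- y; adj[y] <- x
    }
  }
  adj
}

# relabel two genomes onto a shared 1..N marker universe
relabel_pair <- function(a, b) {
  ma <- sort(abs(unlist(a$chromosomes, use.names = FALSE)))
  mb <- sort(abs(unlist(b$chromosomes, use.names = FALSE)))
  if (!identical(ma, mb)) {
    only_a <- setdiff(ma, mb); only_b <- setdiff(mb, ma)
    abort_bad_arg(paste0(
      "marker universes differ; only in first: {",
      paste(utils::head(only_a, 5), collapse = ", "), "}, only in second: {",
      paste(utils::head(only_b, 5), collapse = ", "), "}"))
  }
  relab <- function(g) lapply(g$chromosomes, function(v)
    as.integer(sign(v) * match(abs(v), ma)))
  list(a = relab(a), b = relab(b), n = length(ma), markers = ma)
}

dcj_distance_core <- function(adj_a, adj_b, n_markers) {
  n_ext <- 2L * n_markers
  seen <- logical(n_ext)
  cycles <- 0L; odd_paths <- 0L
  for (s in seq_len(n_ext)) {
    if (seen[s]) next
    comp <- integer(0)
    stack <- s
    while (length(stack)) {
      e <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[e]) next
      seen[e] <- TRUE
      comp <- c(comp, e)
      pa <- adj_a[e]; pb <- adj_b[e]
      if (pa > 0 && !seen[pa]) stack <- c(stack, pa)
      if (pb > 0 && !seen[pb]) stack <- c(stack, pb)
    }
    is_cycle <- all(adj_a[comp] > 0) && all(adj_b[comp] > 0)
    if (is_cycle) cycles <- cycles + 1L
    else if (length(comp) %% 2L == 1L) odd_paths <- odd_paths + 1L
  }
  as.integer(n_markers - cycles - odd_paths %/% 2L)
}

#' DCJ rearrangement distance between two signed genomes
#'
#' Minimal number of double-cut-and-join operations transforming one genome
#' into the other, computed exactly via the adjacency-graph closed form
#' N - C - I/2 (N markers, C cycles, I odd paths). Symmetric; zero exactly
#' when the genomes agree up to chromosome order and whole-chromosome
#' reflection. Both genomes must carry the same marker set.
#'
#' @param a,b `signed_genome` objects over the same marker universe.
#' @return integer distance.
#' @export
#' @examples
#' a <- signed_genome(list(c(1L, 2L, 3L)))
#' b <- signed_genome(list(c(1L, -2L, 3L)))
#' rearrangement_distance(a, b)  # one inversion
rearrangement_distance <- function(a, b) {
  rl <- relabel_pair(a, b)
  if (rl$n == 0L) return(0L)
  dcj_distance_core(adjacency_map(rl$a, a$circular, rl$n),
                    adjacency_map(rl$b, b$circular, rl$n), rl$n)
}

# ---- genome surgery used by the sorter --------------------------------------

# orient a fragment so that extremity e sits at the requested end
orient_frag <- function(v, e, end) {
  at_left <- length(v) && ext_left(v[1]) == e
  at_right <- length(v) && ext_right(v[length(v)]) == e
  stopifnot(at_left || at_right)
  if ((end == "right" && at_right) || (end == "left" && at_left)) v
  else rev(-v)
}

frag_has_end <- function(v, e) {
  length(v) > 0 && (ext_left(v[1]) == e || ext_right(v[length(v)]) == e)
}

# cut the adjacency containing extremity e (no-op when e is a telomere);
# circular chromosomes linearise, linear chromosomes split in two
state_cut <- function(st, e) {
  for (ci in seq_along(st$chrom)) {
    v <- st$chrom[[ci]]
    n <- length(v)
    if (!n) next
    pos <- which(ext_left(v) == e | ext_right(v) == e)
    if (!length(pos)) next
    i <- pos[1]
    left_side <- ext_left(v[i]) == e
    if (st$circ[ci]) {
      # rotate so the cut falls at the chromosome boundary
      rot <- if (left_side) c(v[i:n], v[seq_len(i - 1)])
             else c(v[seq(i + 1, length.out = n - i)], v[seq_len(i)])
      st$chrom[[ci]] <- rot
      st$circ[ci] <- FALSE
      return(st)
    }
    if (left_side && i == 1) return(st)            # already a telomere
    if (!left_side && i == n) return(st)
    if (left_side) {
      st$chrom[[ci]] <- v[seq_len(i - 1)]
      st$chrom[[length(st$chrom) + 1L]] <- v[i:n]
    } else {
      st$chrom[[ci]] <- v[seq_len(i)]
      st$chrom[[length(st$chrom) + 1L]] <- v[seq(i + 1, n)]
    }
    st$circ <- c(st$circ, FALSE)
    return(st)
  }
  abort_bad_arg("extremity not found in genome state")
}

# join extremities e and f, both telomeric after cutting; joining the two
# ends of one fragment circularises it
state_join <- function(st, e, f) {
  ie <- which(vapply(st$chrom, frag_has_end, TRUE, e = e) & !st$circ)
  jf <- which(vapply(st$chrom, frag_has_end, TRUE, e = f) & !st$circ)
  stopifnot(length(ie) >= 1, length(jf) >= 1)
  ie <- ie[1]
  if (length(jf) > 1) jf <- setdiff(jf, ie)[1] else jf <- jf[1]
  if (ie == jf) {
    v <- st$chrom[[ie]]
    # e and f are the two ends of the same fragment -> circular chromosome
    st$chrom[[ie]] <- orient_frag(v, e, "right")
    st$circ[ie] <- TRUE
    return(st)
  }
  left <- orient_frag(st$chrom[[ie]], e, "right")
  right <- orient_frag(st$chrom[[jf]], f, "left")
  st$chrom[[ie]] <- c(left, right)
  st$chrom[[jf]] <- NULL
  st$circ <- st$circ[-jf]
  st
}

drop_empty <- function(st) {
  keep <- vapply(st$chrom, length, 0L) > 0
  st$chrom <- st$chrom[keep]
  st$circ <- st$circ[keep]
  st
}

state_adj <- function(st, n_markers) adjacency_map(st$chrom, st$circ, n_markers)

# chromosome index holding extremity e
ext_chrom <- function(st, e) {
  for (ci in seq_along(st$chrom)) {
    v <- st$chrom[[ci]]
    if (any(ext_left(v) == e | ext_right(v) == e)) return(ci)
  }
  NA_integer_
}

# DCJ creating adjacency {p, q}; the freed partner extremities are joined
# (or left as telomeres when absent)
dcj_make_adjacency <- function(st, p, q, n_markers) {
  adj <- state_adj(st, n_markers)
  if (adj[p] == q) return(st)
  x <- adj[p]; y <- adj[q]
  st <- state_cut(st, p)
  st <- state_cut(st, q)
  st <- state_join(st, p, q)
  if (x > 0 && y > 0) st <- state_join(st, x, y)
  drop_empty(st)
}

# DCJ cutting the adjacency containing p into two telomeres (fission)
dcj_break_adjacency <- function(st, p) drop_empty(state_cut(st, p))

classify_op <- function(before, after, same_chrom, fission) {
  if (fission) return("fission")
  circ_before <- sum(before$circ); circ_after <- sum(after$circ)
  if (circ_after > circ_before) return("excision")
  if (circ_after < circ_before) return("reintegration")
  if (same_chrom) return("inversion")
  if (length(after$chrom) < length(before$chrom)) return("fusion")
  "translocation"
}

#' Optimal typed DCJ sorting scenario
#'
#' Deterministic greedy construction of a minimum-length operation list
#' transforming `a` into `b`: target adjacencies are fixed in ascending
#' marker order, always choosing a distance-reducing operation and
#' preferring ones that keep every chromosome linear. Operations are typed
#' `inversion` (both cuts on one chromosome), `translocation` (cuts on two
#' chromosomes), `fusion`/`fission` (telomeric cases) and — only when no
#' linear-preserving optimal move exists, as for a block interchange —
#' `excision`/`reintegration` of a transient circular intermediate, which
#' the very next operation reabsorbs. The scenario length always equals
#' [rearrangement_distance()], and replaying it on `a` yields `b` up to
#' chromosome order and reflection.
#'
#' @param a,b `signed_genome` objects over the same marker universe.
#' @return tibble with columns `step`, `kind`, `chrom_1`, `pos_1`,
#'   `chrom_2`, `pos_2` (cut locations before the operation; index of the
#'   marker to the left of the cut, 0 for a telomere or absent second cut)
#'   and replay columns `join_p`, `join_q` (extremity pair created; 0,0 for
#'   a pure fission at `break_p`).
#' @seealso [replay_scenario()]
#' @export
sort_scenario <- function(a, b) {
  rl <- relabel_pair(a, b)
  ops <- tibble::tibble(step = integer(), kind = character(),
                        chrom_1 = integer(), pos_1 = integer(),
                        chrom_2 = integer(), pos_2 = integer(),
                        join_p = integer(), join_q = integer(),
                        break_p = integer())
  if (rl$n == 0L) return(ops)
  adj_b <- adjacency_map(rl$b, b$circular, rl$n)
  st <- list(chrom = rl$a, circ = as.logical(a$circular))
  d <- dcj_distance_core(state_adj(st, rl$n), adj_b, rl$n)

  # target adjacencies {p,q} with p < q, and target telomeres, in
  # deterministic marker order
  tgt_adj <- unique(t(vapply(which(adj_b > 0), function(e)
    c(min(e, adj_b[e]), max(e, adj_b[e])), c(0L, 0L))))
  if (length(tgt_adj)) {
    tgt_adj <- tgt_adj[order(tgt_adj[, 1], tgt_adj[, 2]), , drop = FALSE]
  }
  tgt_tel <- which(adj_b == 0)

  while (d > 0) {
    cur_adj <- state_adj(st, rl$n)
    applied <- FALSE
    best_fallback <- NULL
    for (k in seq_len(nrow(tgt_adj))) {
      p <- tgt_adj[k, 1]; q <- tgt_adj[k, 2]
      if (cur_adj[p] == q) next
      cand <- dcj_make_adjacency(st, p, q, rl$n)
      nd <- dcj_distance_core(state_adj(cand, rl$n), adj_b, rl$n)
      if (nd != d - 1L) next
      info <- list(st = cand, p = p, q = q, fission = FALSE,
                   same = identical(ext_chrom(st, p), ext_chrom(st, q)),
                   c1 = ext_chrom(st, p), c2 = ext_chrom(st, q))
      if (!any(cand$circ)) { applied <- TRUE }
      else if (is.null(best_fallback)) best_fallback <- info
      if (applied) { best_fallback <- info; break }
    }
    if (!applied) {
      for (p in tgt_tel) {
        if (cur_adj[p] == 0) next
        cand <- dcj_break_adjacency(st, p)
        nd <- dcj_distance_core(state_adj(cand, rl$n), adj_b, rl$n)
        if (nd != d - 1L) next
        best_fallback <- list(st = cand, p = p, q = 0L, fission = TRUE,
                              same = TRUE, c1 = ext_chrom(st, p), c2 = NA_integer_)
        applied <- TRUE
        break
      }
    }
    if (is.null(best_fallback)) {
      abort_bad_arg("sorting stalled; this should be unreachable")
    }
    info <- best_fallback
    kind <- classify_op(st, info$st, info$same, info$fission)
    marker_pos <- function(ci, e) {
      if (is.na(ci)) return(0L)
      v <- st$chrom[[ci]]
      which(ext_left(v) == e | ext_right(v) == e)[1]
    }
    ops <- dplyr::bind_rows(ops, tibble::tibble(
      step = nrow(ops) + 1L, kind = kind,
      chrom_1 = info$c1 %||% 0L, pos_1 = marker_pos(info$c1, info$p),
      chrom_2 = ifelse(info$fission, 0L, info$c2),
      pos_2 = ifelse(info$fission, 0L, marker_pos(info$c2, info$q)),
      join_p = ifelse(info$fission, 0L, info$p),
      join_q = ifelse(info$fission, 0L, info$q),
      break_p = ifelse(info$fission, info$p, 0L)))
    st <- info$st
    d <- d - 1L
  }
  attr(ops, "markers") <- rl$markers
  ops
}

#' Replay a sorting scenario
#'
#' Applies the operations of a [sort_scenario()] result to a genome and
#' returns the rearranged genome; replaying the full scenario on the source
#' genome reproduces the target (distance zero).
#'
#' @param a source `signed_genome`.
#' @param scenario tibble from [sort_scenario()].
#' @return `signed_genome` after all operations.
#' @export
replay_scenario <- function(a, scenario) {
  markers <- attr(scenario, "markers")
  chroms <- lapply(a$chromosomes, function(v)
    as.integer(sign(v) * match(abs(v), markers)))
  n <- length(markers)
  st <- list(chrom = chroms, circ = as.logical(a$circular))
  for (i in seq_len(nrow(scenario))) {
    if (scenario$break_p[i] > 0) {
      st <- dcj_break_adjacency(st, scenario$break_p[i])
    } else {
      st <- dcj_make_adjacency(st, scenario$join_p[i], scenario$join_q[i], n)
    }
  }
  signed_genome(lapply(st$chrom, function(v)
    as.integer(sign(v) * markers[abs(v)])), circular = st$circ,
    name = a$name)
}

# ---- blocks -> signed genomes ----------------------------------------------

#' Convert shared blocks to a pair of signed genomes
#'
#' Markers are numbered by block order along genome A (all positive there);
#' genome B receives the induced signed order, with chromosome boundaries
#' taken from the contig assignment on each side.
#'
#' @param blocks block tibble ([chain_anchors()] output); each row must
#'   carry coordinates on both genomes.
#' @param contigs_a,contigs_b contig tables fixing chromosome order.
#' @return list of two `signed_genome`s named `a` and `b`.
#' @export
blocks_to_signed_genomes <- function(blocks, contigs_a, contigs_b) {
  need <- c("contig_a", "a_start", "contig_b", "b_start", "sign")
  if (anyNA(blocks[, need])) {
    abort_bad_arg("block present on only one genome (missing coordinates)")
  }
  blocks <- blocks |>
    dplyr::arrange(match(.data$contig_a, contigs_a$contig_id), .data$a_start)
  blocks$marker <- seq_len(nrow(blocks))
  ga <- lapply(split(blocks$marker,
                     factor(blocks$contig_a, levels = contigs_a$contig_id))[
                       unique(blocks$contig_a)],
               as.integer)
  bo <- blocks |>
    dplyr::arrange(match(.data$contig_b, contigs_b$contig_id), .data$b_start)
  gb <- lapply(split(ifelse(bo$sign == "+", bo$marker, -bo$marker),
                     factor(bo$contig_b, levels = contigs_b$contig_id))[
                       unique(bo$contig_b)],
               as.integer)
  list(a = signed_genome(unname(ga), name = "genome_a"),
       b = signed_genome(unname(gb), name = "genome_b"))
}

#' Multichromosomal distance (MCD) summary
#'
#' Normalises rearrangement counts the way comparative tables report them:
#' per chromosome, per megabase, and the gross/all percentage. Ratios are
#' rounded half away from zero to two decimals, the percentage to the
#' nearest integer.
#'
#' @param all_changes MCD counted from every block regardless of size.
#' @param gross_changes MCD counted from blocks > 20 kb outside
#'   subtelomeric regions; at most `all_changes`.
#' @param n_chromosomes chromosome number of the genome the values refer to.
#' @param genome_size_mb genome size in Mb (NA when unknown; per-Mb ratios
#'   then stay NA).
#' @return one-row tibble: `all_changes`, `gross_changes`, `n_chromosomes`,
#'   `genome_size_mb`, `per_chromosome_all`, `per_chromosome_gross`,
#'   `per_mb_all`, `per_mb_gross`, `gross_over_all_pct`.
#' @export
#' @examples
#' mcd_summary(46, 11, 3)   # per-chromosome 15.33 / 3.67, 24 %
mcd_summary <- function(all_changes, gross_changes, n_chromosomes,
                        genome_size_mb = NA_real_) {
  stopifnot(all_changes >= gross_changes, gross_changes >= 0,
            n_chromosomes >= 1)
  if (all_changes == 0) {
    warning("all_changes is 0; gross/all percentage undefined, reported as 0")
    pct <- 0
  } else {
    pct <- round_half_up(100 * gross_changes / all_changes)
  }
  tibble::tibble(
    all_changes = all_changes, gross_changes = gross_changes,
    n_chromosomes = n_chromosomes, genome_size_mb = genome_size_mb,
    per_chromosome_all = round_half_up(all_changes / n_chromosomes, 2),
    per_chromosome_gross = round_half_up(gross_changes / n_chromosomes, 2),
    per_mb_all = round_half_up(all_changes / genome_size_mb, 2),
    per_mb_gross = round_half_up(gross_changes / genome_size_mb, 2),
    gross_over_all_pct = pct)
}
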