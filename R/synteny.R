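# Chaining orthologue anchors into signed locally collinear blocks (LCBs).

anchor_table <- function(pairs, genes_a, genes_b) {
  ia <- match(pairs$gene_a, genes_a$gene_id)
  ib <- match(pairs$gene_b, genes_b$gene_id)
  if (anyNA(ia) || anyNA(ib)) {
    abort_bad_arg("pair member absent from the supplied gene tables")
  }
  tibble::tibble(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    contig_a = genes_a$contig_id[ia], contig_b = genes_b$contig_id[ib],
    a_start = genes_a$start[ia], a_end = genes_a$end[ia],
    b_start = genes_b$start[ib], b_end = genes_b$end[ib],
    rel_sign = ifelse(genes_a$strand[ia] == genes_b$strand[ib], "+", "-"))
}

# longest chain (by anchor count) over anchors of one orientation within one
# contig pair; returns list of index vectors (chains), extracted greedily
chain_one_orientation <- function(an, sign, max_gap_bp, min_anchors) {
  ord <- order(an$a_start, an$b_start)
  an <- an[ord, , drop = FALSE]
  n <- nrow(an)
  avail <- rep(TRUE, n)
  chains <- list()
  repeat {
    idx <- which(avail)
    if (length(idx) < min_anchors) break
    m <- length(idx)
    dp <- rep(1L, m); back <- rep(0L, m)
    for (k in seq_len(m)) {
      i <- idx[k]
      if (k == 1) next
      js <- idx[seq_len(k - 1)]
      gap_a <- an$a_start[i] - an$a_end[js]
      ok_a <- an$a_start[js] < an$a_start[i] & gap_a <= max_gap_bp
      if (sign == "+") {
        gap_b <- an$b_start[i] - an$b_end[js]
        ok_b <- an$b_start[js] < an$b_start[i] & gap_b <= max_gap_bp
      } else {
        gap_b <- an$b_start[js] - an$b_end[i]
        ok_b <- an$b_start[js] > an$b_start[i] & gap_b <= max_gap_bp
      }
      ok <- ok_a & ok_b
      if (any(ok)) {
        cand <- which(ok)
        best <- cand[which.max(dp[cand])]
        dp[k] <- dp[best] + 1L
        back[k] <- best
      }
    }
    if (max(dp) < min_anchors) break
    # reconstruct the heaviest chain (ties: leftmost end)
    k <- which.max(dp)
    chain <- integer(0)
    while (k > 0) { chain <- c(idx[k], chain); k <- back[k] }
    chains[[length(chains) + 1L]] <- ord[chain]
    avail[match(chain, seq_len(n))] <- FALSE
  }
  chains
}

#' Chain anchors into signed collinear blocks
#'
#' Sparse dynamic programming per contig pair and orientation, maximising
#' anchor count: consecutive anchors of a chain must be collinear (same
#' relative orientation as the chain sign), at most `max_gap_bp` apart on
#' both genomes, and strictly increasing on genome A (increasing on B for
#' `+` blocks, decreasing for `-`). Chains are extracted greedily from
#' heaviest down; chains below `min_anchors` are discarded. Residual span
#' overlaps between blocks on either genome are resolved by keeping the
#' heavier block and trimming the lighter at the midpoint of the overlap,
#' so blocks tile without overlap. The result is independent of the input
#' row order.
#'
#' @param pairs orthologue pair tibble ([infer_rbh()] output).
#' @param genes_a,genes_b gene tables of the two genomes.
#' @param max_gap_bp maximum anchor gap on both genomes (default 30000).
#' @param min_anchors minimum anchors per block (default 3).
#' @return block tibble: `block_id`, `contig_a`, `a_start`, `a_end`,
#'   `contig_b`, `b_start`, `b_end`, `sign`, `weight`, `length_bp`, plus a
#'   list-column `anchors` of per-block anchor tables.
#' @export
chain_anchors <- function(pairs, genes_a, genes_b,
                          max_gap_bp = 30000, min_anchors = 3) {
  empty <- tibble::tibble(block_id = integer(), contig_a = character(),
                          a_start = numeric(), a_end = numeric(),
                          contig_b = character(), b_start = numeric(),
                          b_end = numeric(), sign = character(),
                          weight = integer(), length_bp = numeric(),
                          anchors = list())
  if (!nrow(pairs)) return(empty)
  an <- anchor_table(pairs, genes_a, genes_b)
  an <- dplyr::arrange(an, .data$contig_a, .data$contig_b, .data$a_start,
                       .data$b_start, .data$gene_a)
  groups <- split(seq_len(nrow(an)),
                  interaction(an$contig_a, an$contig_b, drop = TRUE))
  blocks <- list()
  for (g in groups) {
    sub <- an[g, , drop = FALSE]
    for (sgn in c("+", "-")) {
      ss <- sub[sub$rel_sign == sgn, , drop = FALSE]
      if (nrow(ss) < min_anchors) next
      for (ch in chain_one_orientation(ss, sgn, max_gap_bp, min_anchors)) {
        cc <- ss[ch, , drop = FALSE]
        blocks[[length(blocks) + 1L]] <- tibble::tibble(
          contig_a = cc$contig_a[1], a_start = min(cc$a_start),
          a_end = max(cc$a_end), contig_b = cc$contig_b[1],
          b_start = min(cc$b_start), b_end = max(cc$b_end),
          sign = sgn, weight = nrow(cc), anchors = list(cc))
      }
    }
  }
  if (!length(blocks)) return(empty)
  out <- dplyr::bind_rows(blocks) |>
    dplyr::arrange(.data$contig_a, .data$a_start, .data$contig_b,
                   .data$b_start)
  out <- resolve_overlaps(out, "a")
  out <- resolve_overlaps(out, "b")
  out |>
    dplyr::arrange(.data$contig_a, .data$a_start, .data$contig_b,
                   .data$b_start) |>
    dplyr::mutate(block_id = dplyr::row_number(),
                  length_bp = pmin(.data$a_end - .data$a_start,
                                   .data$b_end - .data$b_start)) |>
    dplyr::select("block_id", dplyr::everything())
}

# trim the lighter of two span-overlapping blocks at the overlap midpoint
resolve_overlaps <- function(blocks, side) {
  cg <- paste0("contig_", side)
  s <- paste0(side, "_start"); e <- paste0(side, "_end")
  ord <- order(blocks[[cg]], blocks[[s]])
  b <- blocks[ord, , drop = FALSE]
  for (i in seq_len(nrow(b))[-1]) {
    j <- i - 1
    if (b[[cg]][i] != b[[cg]][j]) next
    if (b[[s]][i] < b[[e]][j]) {
      mid <- (b[[s]][i] + b[[e]][j]) / 2
      if (b$weight[i] >= b$weight[j]) b[[e]][j] <- mid else b[[s]][i] <- mid
    }
  }
  b
}

#' Split blocks into gross and all sets
#'
#' Gross blocks drive the large-rearrangement counts: a block qualifies when
#' it is longer than `gross_min_block_bp` (strictly) and does not lie within
#' `subtelomere_margin_bp` of a contig end labelled subtelomeric — chromosome
#' ends churn structurally and are excluded from gross counts.
#'
#' @param blocks block tibble from [chain_anchors()].
#' @param contigs_a contig table of genome A (`contig_id`, `length`).
#' @param end_labels_a optional end-label tibble from
#'   [classify_contig_ends()] for genome A; when `NULL` no subtelomeric
#'   exclusion is applied.
#' @param gross_min_block_bp size threshold in bp (default 20000).
#' @param subtelomere_margin_bp end margin in bp (default 50000).
#' @return `blocks` with an added logical column `gross`.
#' @export
classify_blocks <- function(blocks, contigs_a, end_labels_a = NULL,
                            gross_min_block_bp = 20000,
                            subtelomere_margin_bp = 50000) {
  if (!nrow(blocks)) {
    blocks$gross <- logical()
    return(blocks)
  }
  gross <- blocks$length_bp > gross_min_block_bp
  if (!is.null(end_labels_a) && nrow(end_labels_a)) {
    sub <- dplyr::filter(end_labels_a, .data$label == "subtelomeric")
    len <- contigs_a$length[match(blocks$contig_a, contigs_a$contig_id)]
    for (k in seq_len(nrow(sub))) {
      on_contig <- blocks$contig_a == sub$contig_id[k]
      if (sub$end[k] == "left") {
        gross <- gross & !(on_contig & blocks$a_start < subtelomere_margin_bp)
      } else {
        gross <- gross & !(on_contig & blocks$a_end > len - subtelomere_margin_bp)
      }
    }
  }
  blocks$gross <- gross
  blocks
}

#' Export block coordinates on concatenated genome axes
#'
#' Lossless dot-plot export: block spans are shifted by cumulative contig
#' lengths so both genomes lie on single axes.
#'
#' @param blocks block tibble.
#' @param contigs_a,contigs_b contig tables in axis order.
#' @return tibble with `x_start`, `x_end`, `y_start`, `y_end`, `sign` (plus
#'   the source block columns).
#' @export
export_dotplot <- function(blocks, contigs_a, contigs_b) {
  off_a <- stats::setNames(cumsum(c(0, contigs_a$length))[seq_len(nrow(contigs_a))],
                           contigs_a$contig_id)
  off_b <- stats::setNames(cumsum(c(0, contigs_b$length))[seq_len(nrow(contigs_b))],
                           contigs_b$contig_id)
  tibble::tibble(
    block_id = blocks$block_id,
    x_start = unname(blocks$a_start + off_a[blocks$contig_a]),
    x_end = unname(blocks$a_end + off_a[blocks$contig_a]),
    y_start = unname(ifelse(blocks$sign == "+",
                            blocks$b_start + off_b[blocks$contig_b],
                            blocks$b_end + off_b[blocks$contig_b])),
    y_end = unname(ifelse(blocks$sign == "+",
                          blocks$b_end + off_b[blocks$contig_b],
                          blocks$b_start + off_b[blocks$contig_b])),
    sign = blocks$sign)
}

#' Dot-plot of synteny blocks
#'
#' @param blocks block tibble.
#' @param contigs_a,contigs_b contig tables in axis order.
#' @return a ggplot object: one segment per block, inverted blocks slanting
#'   downward and coloured separately, contig boundaries as grid lines.
#' @export
plot_dotplot <- function(blocks, contigs_a, contigs_b) {
  d <- export_dotplot(blocks, contigs_a, contigs_b)
  bounds_a <- cumsum(contigs_a$length)
  bounds_b <- cumsum(contigs_b$length)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x_start, xend = .data$x_end,
                                       y = .data$y_start, yend = .data$y_end,
                                       colour = .data$sign),
                          linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = bounds_a, colour = "grey80") +
    ggplot2::geom_hline(yintercept = bounds_b, colour = "grey80") +
    ggplot2::scale_colour_manual(values = c(`+` = "#2166ac", `-` = "#b2182b")) +
    ggplot2::labs(x = "genome A (bp, concatenated)",
                  y = "genome B (bp, concatenated)", colour = "orientation") +
    ggplot2::theme_minimal()
}

#' Write a block table
#'
#' @param blocks block tibble.
#' @param path TSV output path (the `anchors` list-column is dropped).
#' @return `blocks`, invisibly.
#' @export
write_block_table <- function(blocks, path) {
  readr::write_tsv(dplyr::select(blocks, -dplyr::any_of("anchors")), path)
  invisible(blocks)
}
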