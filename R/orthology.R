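# One-to-one orthologue inference from reciprocal hit tables.

best_hits <- function(hits, evalue_max) {
  hits <- dplyr::filter(hits, .data$evalue <= evalue_max)
  if (!nrow(hits)) {
    return(tibble::tibble(query_id = character(), subject_id = character(),
                          evalue = numeric(), bitscore = numeric(),
                          ambiguous = logical()))
  }
  # best hit per query: bitscore desc, then evalue asc, then subject id;
  # a tie surviving all three marks the query ambiguous
  hits |>
    dplyr::group_by(.data$query_id) |>
    dplyr::arrange(dplyr::desc(.data$bitscore), .data$evalue,
                   .data$subject_id, .by_group = TRUE) |>
    dplyr::summarise(
      best_subject = .data$subject_id[1],
      best_evalue = .data$evalue[1],
      best_bitscore = .data$bitscore[1],
      ambiguous = dplyr::n() > 1 &&
        isTRUE(.data$bitscore[2] == .data$bitscore[1]) &&
        isTRUE(.data$evalue[2] == .data$evalue[1]) &&
        isTRUE(.data$subject_id[2] == .data$subject_id[1]),
      .groups = "drop") |>
    dplyr::rename(subject_id = "best_subject", evalue = "best_evalue",
                  bitscore = "best_bitscore")
}

#' Infer reciprocal-best-hit orthologue pairs
#'
#' A pair (a, b) is kept exactly when b is a's unique best hit in the
#' forward table and a is b's unique best hit in the reverse table, both
#' under the E-value ceiling. Best hits are ranked by bitscore (descending),
#' then E-value (ascending), then subject id; a gene whose top two hits tie
#' on all three is ambiguous and forms no pair.
#'
#' @param hits_ab,hits_ba hit tibbles (`query_id`, `subject_id`, `evalue`,
#'   `bitscore`) for the two search directions.
#' @param evalue_max maximum E-value for a hit to count (default 1e-3).
#' @return tibble with columns `gene_a`, `gene_b`, `evalue_ab`, `evalue_ba`,
#'   `bitscore_ab`, `bitscore_ba`. A partial matching: no gene appears twice.
#' @export
#' @examples
#' ab <- tibble::tibble(query_id = "A1", subject_id = "B1",
#'                      evalue = 1e-50, bitscore = 500)
#' ba <- tibble::tibble(query_id = "B1", subject_id = "A1",
#'                      evalue = 1e-48, bitscore = 480)
#' infer_rbh(ab, ba)
infer_rbh <- function(hits_ab, hits_ba, evalue_max = 1e-3) {
  fa <- best_hits(hits_ab, evalue_max)
  fb <- best_hits(hits_ba, evalue_max)
  fa <- dplyr::filter(fa, !.data$ambiguous)
  fb <- dplyr::filter(fb, !.data$ambiguous)
  out <- dplyr::inner_join(
    fa, fb,
    by = c(query_id = "subject_id", subject_id = "query_id"),
    suffix = c("_ab", "_ba"))
  tibble::tibble(gene_a = out$query_id, gene_b = out$subject_id,
                 evalue_ab = out$evalue_ab, evalue_ba = out$evalue_ba,
                 bitscore_ab = out$bitscore_ab, bitscore_ba = out$bitscore_ba) |>
    dplyr::arrange(.data$gene_a)
}

# gene-order index within each genome: rank of a gene along its contig
gene_order <- function(genes) {
  genes |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(order = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "contig_id", "order", "strand", "start", "end",
                  "marker_class")
}

#' Keep only synteny-supported orthologue pairs
#'
#' A pair survives when at least `min_neighbors` other pairs lie within
#' `window_genes` gene positions of it on *both* genomes, on the same contig
#' pair. Isolated single-gene matches — the hallmark of repeats and chance
#' hits — are discarded. Idempotent at `min_neighbors = 1`.
#'
#' @param pairs tibble from [infer_rbh()].
#' @param genes_a,genes_b gene tables of the two genomes (see [genome()]).
#' @param min_neighbors minimum supporting neighbour pairs (default 1).
#' @param window_genes neighbourhood half-width in gene positions (default 5).
#' @return `pairs` filtered, with an integer `synteny_support` column.
#' @export
filter_by_synteny <- function(pairs, genes_a, genes_b,
                              min_neighbors = 1, window_genes = 5) {
  if (!nrow(pairs)) {
    pairs$synteny_support <- integer()
    return(pairs)
  }
  oa <- gene_order(genes_a)
  ob <- gene_order(genes_b)
  ia <- match(pairs$gene_a, oa$gene_id)
  ib <- match(pairs$gene_b, ob$gene_id)
  if (anyNA(ia) || anyNA(ib)) {
    abort_bad_arg("pair member absent from the supplied gene tables")
  }
  ca <- oa$contig_id[ia]; pa <- oa$order[ia]
  cb <- ob$contig_id[ib]; pb <- ob$order[ib]
  n <- nrow(pairs)
  support <- integer(n)
  for (i in seq_len(n)) {
    near <- ca == ca[i] & cb == cb[i] &
      abs(pa - pa[i]) <= window_genes & abs(pb - pb[i]) <= window_genes
    near[i] <- FALSE
    # concordant relative order: neighbours must sit on a consistent side
    # (collinear either direct or inverted)
    if (any(near)) {
      da <- sign(pa[near] - pa[i])
      db <- sign(pb[near] - pb[i])
      support[i] <- max(sum(da == db), sum(da == -db))
    }
  }
  pairs$synteny_support <- support
  dplyr::filter(pairs, .data$synteny_support >= min_neighbors)
}

#' Drop multi-copy and repeat-class pairs
#'
#' Removes every pair in which a gene participates in more than one
#' candidate pair of the input table, and every pair touching a gene of a
#' dispersed-repeat class (5S rDNA, tRNA) — the classes that produce
#' non-syntenic repetitive matches.
#'
#' @param pairs candidate pair tibble (columns `gene_a`, `gene_b`).
#' @param genes_a,genes_b gene tables carrying `marker_class`.
#' @return filtered pair tibble.
#' @export
drop_multicopy <- function(pairs, genes_a, genes_b) {
  if (!nrow(pairs)) return(pairs)
  multi_a <- pairs$gene_a[duplicated(pairs$gene_a)]
  multi_b <- pairs$gene_b[duplicated(pairs$gene_b)]
  cls_a <- genes_a$marker_class[match(pairs$gene_a, genes_a$gene_id)]
  cls_b <- genes_b$marker_class[match(pairs$gene_b, genes_b$gene_id)]
  repeat_classes <- c("rdna5S", "trna")
  keep <- !(pairs$gene_a %in% multi_a) & !(pairs$gene_b %in% multi_b) &
    !(cls_a %in% repeat_classes) & !(cls_b %in% repeat_classes)
  pairs[keep, , drop = FALSE]
}

#' Write an orthologue pair table
#'
#' @param pairs pair tibble.
#' @param path TSV output path.
#' @return `pairs`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(pairs)
}
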