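# Core containers and on-disk formats shared by every analysis stage.
#
# Coordinate convention: all internal coordinates are 0-based half-open
# [start, end). GFF3 (1-based closed) is converted at the I/O boundary and
# nowhere else.

MARKER_CLASSES <- c("subtelomeric", "pericentromeric", "rdna5S",
                    "rdna_large", "trna", "none")

#' Construct a genome container
#'
#' A genome bundles an ordered contig table, a gene table and (optionally)
#' sequences. Genes use 0-based half-open coordinates and carry a marker
#' class (`subtelomeric`, `pericentromeric`, `rdna5S`, `rdna_large`, `trna`
#' or `none`) used by the scaffolding and breakpoint stages.
#'
#' @param genes tibble with columns `gene_id`, `contig_id`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`) and optionally `marker_class`.
#' @param contigs tibble with columns `contig_id`, `length` (bp), in
#'   assembly order.
#' @param name genome name.
#' @param seqs optional `Biostrings::DNAStringSet` named by contig id.
#' @return an object of class `genome`: a list with elements `name`,
#'   `contigs`, `genes`, `seqs`.
#' @export
#' @examples
#' g <- genome(
#'   genes = tibble::tibble(gene_id = "g1", contig_id = "c1",
#'                          start = 10, end = 50, strand = "+"),
#'   contigs = tibble::tibble(contig_id = "c1", length = 100),
#'   name = "toy"
#' )
#' g$genes
genome <- function(genes, contigs, name = "genome", seqs = NULL) {
  contigs <- tibble::as_tibble(contigs)
  genes <- tibble::as_tibble(genes)
  if (!all(c("contig_id", "length") %in% names(contigs))) {
    abort_bad_arg("`contigs` needs columns contig_id, length")
  }
  need <- c("gene_id", "contig_id", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    abort_bad_arg(paste("`genes` needs columns", paste(need, collapse = ", ")))
  }
  if (!"marker_class" %in% names(genes)) genes$marker_class <- "none"
  genes$marker_class[is.na(genes$marker_class)] <- "none"
  if (anyDuplicated(contigs$contig_id)) {
    abort_bad_arg("duplicate contig ids")
  }
  if (anyDuplicated(genes$gene_id)) {
    abort_bad_arg(paste("duplicate gene ids:",
                        paste(unique(genes$gene_id[duplicated(genes$gene_id)])[1:3],
                              collapse = ", ")))
  }
  unknown <- setdiff(genes$contig_id, contigs$contig_id)
  if (length(unknown)) {
    abort_bad_arg(paste0("gene(s) on unknown contig(s): ",
                         paste(unknown, collapse = ", ")))
  }
  if (any(genes$start >= genes$end)) {
    abort_bad_arg("gene with start >= end (coordinates are 0-based half-open)")
  }
  len <- contigs$length[match(genes$contig_id, contigs$contig_id)]
  bad <- genes$start < 0 | genes$end > len
  if (any(bad)) {
    abort_bad_arg(paste0("gene(s) exceeding contig bounds: ",
                         paste(genes$gene_id[bad][seq_len(min(3, sum(bad)))],
                               collapse = ", ")))
  }
  if (!all(genes$marker_class %in% MARKER_CLASSES)) {
    abort_bad_arg("unknown marker_class value")
  }
  genes <- dplyr::arrange(genes, match(.data$contig_id, contigs$contig_id),
                          .data$start)
  structure(list(name = name, contigs = contigs, genes = genes, seqs = seqs),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", x$name, ": ", nrow(x$contigs), " contig(s), ",
      nrow(x$genes), " gene(s)\n", sep = "")
  invisible(x)
}

#' Tidy a genome into its gene table
#'
#' @param x a `genome`.
#' @param ... unused.
#' @return tibble of genes (one row per gene).
#' @export
tidy.genome <- function(x, ...) x$genes

#' Analysis configuration defaults
#'
#' Central place for the thresholds used across stages. All values are
#' strictly positive.
#'
#' @param evalue_max maximum E-value for a similarity hit to count (1e-3).
#' @param min_block_anchors minimum anchors to keep a chained block (3).
#' @param max_anchor_gap_bp maximum gap between consecutive anchors of a
#'   block, on both genomes (30000).
#' @param gross_min_block_bp blocks longer than this count as "gross" (20000).
#' @param subtelomere_margin_bp distance from a contig end within which
#'   subtelomeric markers label the end and blocks are excluded from the
#'   gross set (50000).
#' @param breakpoint_margin_bp margin for associating features with a
#'   breakpoint region (5000).
#' @param min_neighbors,window_genes synteny support filter for orthologue
#'   pairs (1 neighbour within 5 gene positions).
#' @param max_reference_gap_bp maximum gap on a reference chromosome between
#'   two blocks that bridge a contig junction (30000).
#' @param bootstrap_reps parametric bootstrap replicates for the random
#'   breakage test (999).
#' @param rng_seed integer seed threaded through stochastic steps.
#' @return named list of class `analysis_config`.
#' @export
analysis_config <- function(evalue_max = 1e-3,
                            min_block_anchors = 3,
                            max_anchor_gap_bp = 30000,
                            gross_min_block_bp = 20000,
                            subtelomere_margin_bp = 50000,
                            breakpoint_margin_bp = 5000,
                            min_neighbors = 1,
                            window_genes = 5,
                            max_reference_gap_bp = 30000,
                            bootstrap_reps = 999,
                            rng_seed = 1L) {
  cfg <- list(evalue_max = evalue_max,
              min_block_anchors = min_block_anchors,
              max_anchor_gap_bp = max_anchor_gap_bp,
              gross_min_block_bp = gross_min_block_bp,
              subtelomere_margin_bp = subtelomere_margin_bp,
              breakpoint_margin_bp = breakpoint_margin_bp,
              min_neighbors = min_neighbors,
              window_genes = window_genes,
              max_reference_gap_bp = max_reference_gap_bp,
              bootstrap_reps = bootstrap_reps,
              rng_seed = rng_seed)
  num <- vapply(cfg[setdiff(names(cfg), "rng_seed")], as.numeric, 0)
  if (any(num <= 0)) abort_bad_arg("all analysis_config thresholds must be > 0")
  structure(cfg, class = c("analysis_config", "list"))
}

#' Read a genome from FASTA + GFF3 (+ marker table)
#'
#' GFF3 rows of the requested feature types become genes; the 1-based closed
#' GFF interval `[start, end]` is converted to the internal 0-based
#' half-open convention. Marker classes are attached from a two-column
#' sidecar table (`gene_id`, `class`) rather than parsed out of GFF
#' attributes, because marker sets are curated lists.
#'
#' @param fasta_path path to a FASTA file of contig/chromosome sequences.
#' @param gff_path path to a GFF3 annotation file; may contain zero genes.
#' @param marker_path optional path to a TSV with columns `gene_id`, `class`.
#' @param name genome name (defaults to the FASTA basename).
#' @param feature_types GFF3 `type` values treated as genes.
#' @return a `genome` object (sequences retained in `$seqs`).
#' @export
read_genome <- function(fasta_path, gff_path, marker_path = NULL,
                        name = NULL, feature_types = "gene") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  contigs <- tibble::tibble(contig_id = names(seqs),
                            length = as.numeric(Biostrings::width(seqs)))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  df <- as.data.frame(gr)
  if (nrow(df)) df <- df[df$type %in% feature_types, , drop = FALSE]
  if (nrow(df)) {
    ids <- df$ID
    if (is.null(ids) || all(is.na(ids))) ids <- paste0("gene", seq_len(nrow(df)))
    genes <- tibble::tibble(
      gene_id = as.character(ids),
      contig_id = as.character(df$seqnames),
      start = as.numeric(df$start) - 1,  # GFF3 1-based closed -> 0-based half-open
      end = as.numeric(df$end),
      strand = ifelse(as.character(df$strand) == "-", "-", "+")
    )
  } else {
    genes <- tibble::tibble(gene_id = character(), contig_id = character(),
                            start = numeric(), end = numeric(),
                            strand = character())
  }
  if (!is.null(marker_path)) {
    mk <- read_marker_table(marker_path)
    genes$marker_class <- mk$class[match(genes$gene_id, mk$gene_id)]
  }
  genome(genes, contigs, name = name %||% sub("\\.[^.]*$", "", basename(fasta_path)),
         seqs = seqs)
}

#' Write a genome to FASTA + GFF3
#'
#' Inverse of [read_genome()]: internal 0-based half-open gene coordinates
#' are converted back to GFF3's 1-based closed intervals at the boundary.
#' When the genome holds no sequences, placeholder `N` runs of the recorded
#' contig lengths are written so the pair of files round-trips.
#'
#' @param g a `genome`.
#' @param fasta_path,gff_path output paths.
#' @return `g`, invisibly.
#' @export
write_genome <- function(g, fasta_path, gff_path) {
  seqs <- g$seqs
  if (is.null(seqs)) {
    seqs <- Biostrings::DNAStringSet(vapply(g$contigs$length, function(n)
      paste(rep("N", n), collapse = ""), ""))
    names(seqs) <- g$contigs$contig_id
  }
  Biostrings::writeXStringSet(seqs, fasta_path)
  con <- file(gff_path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(g$genes)) {
    rows <- sprintf("%s\tsyntenica\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                    g$genes$contig_id,
                    as.integer(g$genes$start + 1), as.integer(g$genes$end),
                    g$genes$strand, g$genes$gene_id)
    writeLines(rows, con)
  }
  invisible(g)
}

#' Read / write a marker-class table
#'
#' @param path TSV with columns `gene_id`, `class`.
#' @return tibble with those two columns.
#' @export
read_marker_table <- function(path) {
  mk <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), class = readr::col_character()))
  if (!all(mk$class %in% MARKER_CLASSES)) {
    abort_bad_arg("marker table contains unknown class values")
  }
  mk
}

#' @rdname read_marker_table
#' @param markers tibble with columns `gene_id`, `class`.
#' @export
write_marker_table <- function(markers, path) {
  readr::write_tsv(markers[, c("gene_id", "class")], path)
  invisible(markers)
}

#' Read / write a similarity hit table
#'
#' Tab-separated with columns `query_id`, `subject_id`, `evalue`,
#' `bitscore` — the precomputed pairwise protein similarity input; the
#' package never runs a search engine itself. Malformed rows (missing
#' fields, negative E-values) are dropped with a message giving the count.
#'
#' @param path TSV path.
#' @return tibble of hits.
#' @export
read_hit_table <- function(path) {
  h <- readr::read_tsv(path, col_types = readr::cols(
    query_id = readr::col_character(), subject_id = readr::col_character(),
    evalue = readr::col_double(), bitscore = readr::col_double()))
  bad <- is.na(h$query_id) | is.na(h$subject_id) | is.na(h$evalue) |
    is.na(h$bitscore) | h$evalue < 0
  if (any(bad)) {
    message(sum(bad), " malformed hit row(s) dropped")
    h <- h[!bad, , drop = FALSE]
  }
  h
}

#' @rdname read_hit_table
#' @param hits tibble with columns `query_id`, `subject_id`, `evalue`,
#'   `bitscore`.
#' @export
write_hit_table <- function(hits, path) {
  readr::write_tsv(hits[, c("query_id", "subject_id", "evalue", "bitscore")],
                   path)
  invisible(hits)
}

# ---- signed genomes (GRIMM text format) -------------------------------------

#' Construct a signed genome
#'
#' A multichromosomal genome abstracted to ordered signed integer markers,
#' the input representation for rearrangement-distance work. Each absolute
#' marker id may appear at most once genome-wide.
#'
#' @param chromosomes list of integer vectors (one per chromosome); signs
#'   encode orientation. Empty list allowed.
#' @param circular logical vector flagging circular chromosomes. Input
#'   genomes are linear; circular entries only arise transiently inside
#'   sorting scenarios.
#' @param name genome name.
#' @return object of class `signed_genome`.
#' @export
#' @examples
#' signed_genome(list(c(1L, -2L), 3L))
signed_genome <- function(chromosomes, circular = NULL, name = "genome") {
  chromosomes <- lapply(chromosomes, as.integer)
  ids <- abs(unlist(chromosomes, use.names = FALSE) %||% integer(0))
  if (any(ids == 0)) abort_bad_arg("marker id 0 is not allowed")
  if (anyDuplicated(ids)) {
    abort_bad_arg(paste("duplicate marker id(s):",
                        paste(unique(ids[duplicated(ids)])[1:3], collapse = ", ")))
  }
  circular <- circular %||% rep(FALSE, length(chromosomes))
  structure(list(chromosomes = chromosomes,
                 circular = circular, name = name),
            class = "signed_genome")
}

#' @export
print.signed_genome <- function(x, ...) {
  cat("<signed_genome> ", x$name, ": ", length(x$chromosomes),
      " chromosome(s), ", length(unlist(x$chromosomes)), " marker(s)\n",
      sep = "")
  invisible(x)
}

#' Tidy a signed genome
#'
#' @param x a `signed_genome`.
#' @param ... unused.
#' @return tibble with columns `chromosome`, `position`, `marker`, `sign`.
#' @export
tidy.signed_genome <- function(x, ...) {
  purrr::imap_dfr(x$chromosomes, function(v, i) {
    tibble::tibble(chromosome = i, position = seq_along(v),
                   marker = abs(v), sign = ifelse(v >= 0, "+", "-"))
  })
}

#' Write a signed genome in GRIMM genome format
#'
#' One line per chromosome: signed integers space-separated, terminated by
#' `$`. `read_signed_genome(write_signed_genome(g, p))` reproduces `g`.
#'
#' @param g a `signed_genome` (linear chromosomes only).
#' @param path output path.
#' @return `g`, invisibly.
#' @export
write_signed_genome <- function(g, path) {
  stopifnot(inherits(g, "signed_genome"))
  if (any(g$circular)) abort_bad_arg("GRIMM export supports linear chromosomes only")
  lines <- c(paste0(">", g$name),
             vapply(g$chromosomes, function(v)
               if (length(v)) paste(paste(v, collapse = " "), "$")
               else "$", ""))
  writeLines(lines, path)
  invisible(g)
}

#' @rdname write_signed_genome
#' @export
read_signed_genome <- function(path) {
  lines <- readLines(path)
  name <- "genome"
  if (length(lines) && startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  lines <- lines[nzchar(trimws(lines))]
  chroms <- lapply(lines, function(l) {
    toks <- strsplit(trimws(l), "\\s+")[[1]]
    toks <- toks[toks != "$"]
    as.integer(toks)
  })
  chroms <- chroms[vapply(chroms, length, 0L) > 0 | length(chroms) == 0]
  signed_genome(chroms, name = name)
}
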