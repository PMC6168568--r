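# helper: lay n anchors on two toy genomes with given b-side order/strand
toy_anchor_genomes <- function(a_pos, b_pos, strand_b = NULL, spacing = 1000,
                               width = 400) {
  n <- length(a_pos)
  strand_b <- strand_b %||% rep("+", n)
  genes_a <- make_genes(gene_id = sprintf("a%d", seq_len(n)),
                        contig_id = rep("cA", n),
                        start = a_pos, end = a_pos + width)
  genes_b <- make_genes(gene_id = sprintf("b%d", seq_len(n)),
                        contig_id = rep("cB", n),
                        start = b_pos, end = b_pos + width,
                        strand = strand_b)
  list(a = genes_a, b = genes_b,
       pairs = tibble::tibble(gene_a = sprintf("a%d", seq_len(n)),
                              gene_b = sprintf("b%d", seq_len(n))))
}

test_that("no pairs produce no blocks", {
  g <- toy_anchor_genomes(numeric(0), numeric(0))
  expect_equal(nrow(chain_anchors(g$pairs, g$a, g$b)), 0)
})

test_that("collinear anchors chain into one forward block", {
  pos <- (0:4) * 2000
  g <- toy_anchor_genomes(pos, pos)
  out <- chain_anchors(g$pairs, g$a, g$b, max_gap_bp = 30000, min_anchors = 3)
  expect_equal(nrow(out), 1)
  expect_equal(out$sign, "+")
  expect_equal(out$weight, 5L)
  expect_equal(out$a_start, 0)
  expect_equal(out$a_end, 8400)      # first-to-last anchor span
  # exhaustive chain enumeration agrees with the DP weight
  expect_equal(oracle_best_chain(pos, pos + 400, pos, pos + 400, "+", 30000),
               5L)
})

test_that("forward and reversed runs split into + and - blocks", {
  a_pos <- (0:5) * 2000
  b_pos <- c(0, 2000, 4000, 10000, 8000, 6000)
  strand_b <- c("+", "+", "+", "-", "-", "-")
  g <- toy_anchor_genomes(a_pos, b_pos, strand_b)
  out <- chain_anchors(g$pairs, g$a, g$b, min_anchors = 3)
  expect_equal(nrow(out), 2)
  expect_setequal(out$sign, c("+", "-"))
  expect_equal(out$weight, c(3L, 3L))
  expect_equal(oracle_best_chain(a_pos[4:6], a_pos[4:6] + 400,
                                 b_pos[4:6], b_pos[4:6] + 400, "-", 30000),
               3L)
})

test_that("the gap bound splits distant anchors into separate blocks", {
  a_pos <- c(0, 2000, 4000, 80000, 82000, 84000)
  g <- toy_anchor_genomes(a_pos, a_pos)
  out <- chain_anchors(g$pairs, g$a, g$b, max_gap_bp = 30000,
                       min_anchors = 3)
  expect_equal(nrow(out), 2)
})

test_that("chaining is invariant under input order and blocks never overlap", {
  spec <- sim_spec(n_blocks = 120, n_contigs = 4, rng_seed = 21)
  sim <- simulate_pair(spec, avoid_rearranged_cuts = TRUE)
  pairs <- infer_rbh(sim$hits$ab, sim$hits$ba) |>
    drop_multicopy(sim$draft_genome$genes, sim$ancestor_genome$genes) |>
    filter_by_synteny(sim$draft_genome$genes, sim$ancestor_genome$genes)
  b1 <- chain_anchors(pairs, sim$draft_genome$genes,
                      sim$ancestor_genome$genes)
  set.seed(1)
  b2 <- chain_anchors(pairs[sample(nrow(pairs)), ],
                      sim$draft_genome$genes, sim$ancestor_genome$genes)
  expect_equal(dplyr::select(b2, -"anchors"), dplyr::select(b1, -"anchors"))
  expect_lte(sum(b1$weight), nrow(pairs))
  for (side in c("a", "b")) {
    cg <- paste0("contig_", side)
    s <- paste0(side, "_start"); e <- paste0(side, "_end")
    for (cc in unique(b1[[cg]])) {
      bb <- b1[b1[[cg]] == cc, , drop = FALSE]
      bb <- bb[order(bb[[s]]), , drop = FALSE]
      if (nrow(bb) > 1) {
        expect_true(all(bb[[s]][-1] >= bb[[e]][-nrow(bb)]))
      }
    }
  }
})

test_that("block count equals the conserved segments of the true history", {
  # dense anchors relative to the gap bound, so chains only break at true
  # breakpoints or contig boundaries
  spec <- sim_spec(n_blocks = 300, block_len_mean = 15000,
                   block_len_sd = 8000, genes_per_block = 6,
                   n_contigs = 6, rng_seed = 31)
  sim <- simulate_pair(spec, avoid_rearranged_cuts = TRUE)
  pairs <- infer_rbh(sim$hits$ab, sim$hits$ba) |>
    drop_multicopy(sim$draft_genome$genes, sim$ancestor_genome$genes) |>
    filter_by_synteny(sim$draft_genome$genes, sim$ancestor_genome$genes)
  # gap bound well below the typical block size, so a chain can never step
  # over a whole skipped block
  blocks <- chain_anchors(pairs, sim$draft_genome$genes,
                          sim$ancestor_genome$genes, max_gap_bp = 10000)
  # expected: maximal runs of ancestrally-adjacent, consistently oriented
  # blocks within the draft contigs (diff == 1 covers both orientations;
  # consecutive ids on different ancestor chromosomes are not adjacent)
  anc_chrom <- sim$ancestor$blocks$chrom[order(sim$ancestor$blocks$block_id)]
  vecs <- lapply(sim$draft$chrom_names, function(cn) {
    b <- sim$draft$blocks[sim$draft$blocks$chrom == cn, ]
    as.integer(b$sign[order(b$pos)] * b$block_id[order(b$pos)])
  })
  expected <- sum(vapply(vecs, function(v) {
    if (length(v) < 2) return(1L)
    conserved <- diff(v) == 1L &
      anc_chrom[abs(v[-length(v)])] == anc_chrom[abs(v[-1])]
    1L + sum(!conserved)
  }, 0L))
  expect_equal(nrow(blocks), expected)
})

test_that("gross classification applies the >20 kb rule and end margins", {
  expect_equal(nrow(classify_blocks(chain_anchors(
    tibble::tibble(gene_a = character(), gene_b = character()),
    make_genes(gene_id = character(), contig_id = character(),
               start = numeric(), end = numeric()),
    make_genes(gene_id = character(), contig_id = character(),
               start = numeric(), end = numeric())),
    tibble::tibble(contig_id = character(), length = numeric()))), 0)
  blocks <- tibble::tibble(
    block_id = 1:3, contig_a = "c1",
    a_start = c(100000, 200000, 951000),
    a_end = c(119999, 225000, 976000),
    contig_b = "r1", b_start = c(0, 1, 2), b_end = c(3, 4, 5),
    sign = "+", weight = 5L,
    length_bp = c(19999, 25000, 25000))
  contigs <- tibble::tibble(contig_id = "c1", length = 1000000)
  ends <- tibble::tibble(contig_id = "c1", end = c("left", "right"),
                         label = c("internal", "subtelomeric"),
                         evidence = "", has_pericentromeric = TRUE)
  out <- classify_blocks(blocks, contigs, ends,
                         gross_min_block_bp = 20000,
                         subtelomere_margin_bp = 50000)
  # 19999 bp fails the strict >20 kb rule; 25 kb block within the
  # subtelomeric margin is kept in "all" but not "gross"
  expect_equal(out$gross, c(FALSE, TRUE, FALSE))
  expect_equal(nrow(out), 3)
})

test_that("dot-plot export offsets equal cumulative contig lengths", {
  blocks <- tibble::tibble(block_id = 1:2,
                           contig_a = c("c1", "c2"),
                           a_start = c(10, 20), a_end = c(100, 200),
                           contig_b = c("r1", "r2"),
                           b_start = c(5, 15), b_end = c(50, 150),
                           sign = c("+", "-"), weight = 3L,
                           length_bp = c(45, 135))
  ca <- tibble::tibble(contig_id = c("c1", "c2"), length = c(1000, 2000))
  cb <- tibble::tibble(contig_id = c("r1", "r2"), length = c(500, 700))
  d <- export_dotplot(blocks, ca, cb)
  expect_equal(d$x_start, c(10, 1020))
  expect_equal(d$y_start, c(5, 650))     # inverted block starts at its b_end
  expect_equal(d$y_end, c(50, 515))
  expect_equal(d$sign, c("+", "-"))
  p <- plot_dotplot(blocks, ca, cb)
  expect_s3_class(p, "ggplot")
})
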