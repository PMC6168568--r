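test_that("contig ends are labelled from marker content", {
  contigs <- tibble::tibble(contig_id = "c1", length = 500000)
  genes <- make_genes(gene_id = c("s1", "s2", "x1"), contig_id = "c1",
                      start = c(10000, 25000, 300000),
                      end = c(11000, 26000, 301000),
                      marker_class = c("subtelomeric", "subtelomeric", "none"))
  el <- classify_contig_ends(genes, contigs, margin_bp = 50000)
  expect_equal(el$label[el$end == "left"], "subtelomeric")
  expect_equal(el$label[el$end == "right"], "internal")
  expect_true(grepl("s1", el$evidence[el$end == "left"]))

  bare <- classify_contig_ends(
    make_genes(gene_id = "x", contig_id = "c1",
               start = 100, end = 200), contigs)
  expect_equal(bare$label, c("internal", "internal"))
  expect_false(any(bare$has_pericentromeric))

  centro <- classify_contig_ends(
    make_genes(gene_id = "p1", contig_id = "c1",
               start = 250000, end = 251000,
               marker_class = "pericentromeric"), contigs,
    margin_bp = 50000)
  expect_equal(centro$label, c("internal", "internal"))
  expect_true(all(centro$has_pericentromeric))
})

test_that("reference continuity proposes the right end pairs", {
  contigs <- tibble::tibble(contig_id = c("c1", "c2"),
                            length = c(100000, 120000))
  mk_blocks <- function(sign2, b2_start = 101000) tibble::tibble(
    block_id = 1:2, contig_a = c("c1", "c2"),
    a_start = c(20000, if (sign2 == "+") 1000 else 60000),
    a_end = c(99000, if (sign2 == "+") 60000 else 119000),
    contig_b = "r1",
    b_start = c(10000, b2_start), b_end = c(89000, 160000),
    sign = c("+", sign2), weight = c(10L, 8L), length_bp = 50000)
  cand <- build_adjacency_graph(list(ref = mk_blocks("+")), contigs)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$end_1, cand$end_2), c("c1:R", "c2:L"))
  expect_equal(cand$support, 18)
  # gap beyond the window: no candidate
  far <- build_adjacency_graph(list(ref = mk_blocks("+", 200000)), contigs,
                               max_reference_gap_bp = 30000)
  expect_equal(nrow(far), 0)
  # inverted second block pairs c1:R with c2:R (c2 to be flipped)
  inv <- build_adjacency_graph(list(ref = mk_blocks("-")), contigs)
  expect_equal(c(inv$end_1, inv$end_2), c("c1:R", "c2:R"))
})

test_that("a single contig with marker support assembles as one chromosome", {
  contigs <- tibble::tibble(contig_id = "c1", length = 200000)
  el <- tibble::tibble(contig_id = "c1", end = c("left", "right"),
                       label = "subtelomeric", evidence = "",
                       has_pericentromeric = TRUE)
  cand <- tibble::tibble(end_1 = character(), end_2 = character(),
                         support = numeric(), reference = character())
  asm <- order_contigs(cand, el, contigs, n_chromosomes = 1)
  expect_equal(asm$assemblies$contig_id, "c1")
  expect_equal(asm$assemblies$orientation, "+")
  expect_true(asm$unique)
})

test_that("missing subtelomeric evidence is a hard error naming contigs", {
  contigs <- tibble::tibble(contig_id = c("c1", "c2"),
                            length = c(1000, 2000))
  el <- tibble::tibble(contig_id = rep(c("c1", "c2"), each = 2),
                       end = rep(c("left", "right"), 2),
                       label = "internal", evidence = "",
                       has_pericentromeric = TRUE)
  cand <- tibble::tibble(end_1 = "c1:R", end_2 = "c2:L",
                         support = 5, reference = "ref")
  expect_error(order_contigs(cand, el, contigs, 1), "infeasible.*c1")
})

test_that("reference priority resolves conflicting partners and reports them", {
  contigs <- tibble::tibble(contig_id = c("c1", "c2", "c3"),
                            length = c(1e5, 1e5, 1e5))
  el <- tibble::tibble(
    contig_id = rep(c("c1", "c2", "c3"), each = 2),
    end = rep(c("left", "right"), 3),
    label = c("subtelomeric", "internal",     # c1
              "internal", "subtelomeric",     # c2
              "subtelomeric", "subtelomeric"),# c3 (own chromosome)
    evidence = "",
    has_pericentromeric = TRUE)
  # close reference says c1:R - c2:L; distant one says c1:R - c3:L, with
  # higher support; the closer reference must win and the conflict logged
  cand <- tibble::tibble(end_1 = c("c1:R", "c1:R"),
                         end_2 = c("c2:L", "c3:L"),
                         support = c(50, 80),
                         reference = c("close", "distant"))
  asm <- order_contigs(cand, el, contigs, n_chromosomes = 2,
                       reference_priority = c("close", "distant"))
  got <- asm$assemblies
  expect_equal(sort(unique(got$contig_id)), c("c1", "c2", "c3"))
  joined <- got$chromosome[match(c("c1", "c2"), got$contig_id)]
  expect_equal(joined[1], joined[2])     # c1 and c2 share a chromosome
  expect_equal(nrow(asm$conflicts), 1)
  expect_equal(asm$conflicts$winner_reference, "close")
  expect_equal(asm$conflicts$loser_reference, "distant")
})

test_that("equally supported alternative covers are reported as non-unique", {
  contigs <- tibble::tibble(contig_id = c("c1", "c2"),
                            length = c(1e5, 1e5))
  # no marker constraints: both ends of both contigs look subtelomeric
  el <- tibble::tibble(contig_id = rep(c("c1", "c2"), each = 2),
                       end = rep(c("left", "right"), 2),
                       label = "subtelomeric", evidence = "",
                       has_pericentromeric = TRUE)
  cand <- tibble::tibble(end_1 = c("c1:R", "c1:R"),
                         end_2 = c("c2:L", "c2:R"),
                         support = c(10, 10),
                         reference = "ref")
  asm <- order_contigs(cand, el, contigs, n_chromosomes = 1)
  expect_false(asm$unique)
})

test_that("every contig appears exactly once and paths are canonical", {
  spec <- sim_spec(rng_seed = 3)
  sim <- simulate_pair(spec, avoid_rearranged_cuts = TRUE)
  pairs <- infer_rbh(sim$hits$ab, sim$hits$ba) |>
    drop_multicopy(sim$draft_genome$genes, sim$ancestor_genome$genes) |>
    filter_by_synteny(sim$draft_genome$genes, sim$ancestor_genome$genes)
  blocks <- chain_anchors(pairs, sim$draft_genome$genes,
                          sim$ancestor_genome$genes)
  el <- classify_contig_ends(sim$draft_genome$genes,
                             sim$draft_genome$contigs)
  cand <- build_adjacency_graph(list(reference = blocks),
                                sim$draft_genome$contigs)
  asm <- order_contigs(cand, el, sim$draft_genome$contigs, 3)
  expect_equal(sort(asm$assemblies$contig_id),
               sort(sim$draft_genome$contigs$contig_id))
  expect_equal(anyDuplicated(asm$assemblies$contig_id), 0L)
  # chromosome names by descending assembled length
  lens <- asm$assemblies |>
    dplyr::left_join(sim$draft_genome$contigs,
                     by = dplyr::join_by(contig_id)) |>
    dplyr::group_by(chromosome) |>
    dplyr::summarise(len = sum(length))
  expect_true(all(diff(lens$len[order(lens$chromosome)]) <= 0))
})
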