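test_that("distance handles the canonical small cases", {
  a <- signed_genome(list(c(1L, 2L, 3L)))
  expect_equal(rearrangement_distance(a, a), 0L)
  expect_equal(rearrangement_distance(
    a, signed_genome(list(c(1L, -2L, 3L)))), 1L)
  # one translocation between two chromosomes
  expect_equal(rearrangement_distance(
    signed_genome(list(c(1L, 2L, 3L), c(4L, 5L))),
    signed_genome(list(c(1L, 2L, 5L), c(4L, 3L)))), 1L)
  # equal up to chromosome order and reflection -> 0
  expect_equal(rearrangement_distance(
    signed_genome(list(c(1L, 2L), c(3L, 4L))),
    signed_genome(list(c(-4L, -3L), c(1L, 2L)))), 0L)
})

test_that("differing marker universes raise an error listing the difference", {
  expect_error(rearrangement_distance(
    signed_genome(list(c(1L, 2L))), signed_genome(list(c(1L, 3L)))),
    "only in first.*2.*only in second.*3")
})

test_that("distance agrees with brute-force BFS on random small instances", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(4:6, 1)
    a <- random_genome_chroms(n, sample(1:2, 1))
    b <- scramble_chroms(a, sample(1:3, 1))
    d <- rearrangement_distance(signed_genome(a), signed_genome(b))
    expect_equal(d, bfs_dcj_distance(a, b), info = paste("instance", i))
  }
})

test_that("distance is a metric on canonicalised genomes", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    a <- random_genome_chroms(n, sample(1:3, 1))
    b <- scramble_chroms(a, sample(0:4, 1))
    c_ <- scramble_chroms(a, sample(0:4, 1))
    ga <- signed_genome(a); gb <- signed_genome(b); gc <- signed_genome(c_)
    expect_equal(rearrangement_distance(ga, ga), 0L)
    expect_equal(rearrangement_distance(ga, gb),
                 rearrangement_distance(gb, ga))
    expect_lte(rearrangement_distance(ga, gc),
               rearrangement_distance(ga, gb) +
                 rearrangement_distance(gb, gc))
  }
})

test_that("scenarios are optimal, replayable and typed", {
  a <- signed_genome(list(c(1L, 2L, 3L)))
  expect_equal(nrow(sort_scenario(a, a)), 0)
  inv <- sort_scenario(a, signed_genome(list(c(1L, -2L, 3L))))
  expect_equal(nrow(inv), 1)
  expect_equal(inv$kind, "inversion")
  tr <- sort_scenario(signed_genome(list(c(1L, 2L, 3L), c(4L, 5L))),
                      signed_genome(list(c(1L, 2L, 5L), c(4L, 3L))))
  expect_equal(tr$kind, "translocation")

  set.seed(55)
  for (i in 1:15) {
    n <- sample(6:12, 1)
    a_ch <- random_genome_chroms(n, sample(1:3, 1))
    b_ch <- scramble_chroms(a_ch, sample(1:4, 1))
    ga <- signed_genome(a_ch); gb <- signed_genome(b_ch)
    sc <- sort_scenario(ga, gb)
    expect_equal(nrow(sc), rearrangement_distance(ga, gb))
    final <- replay_scenario(ga, sc)
    expect_equal(rearrangement_distance(final, gb), 0L)
  }
})

test_that("a planted inversion/translocation history is typed correctly", {
  spec <- sim_spec(n_blocks = 200, n_inversions = 3, n_translocations = 2,
                   n_contigs = 3, rng_seed = 17)
  anc <- generate_ancestor(spec)
  ev <- evolve(anc, spec)
  sg <- sim_signed_genomes(anc, ev$genome)
  d <- rearrangement_distance(sg$a, sg$b)
  expect_equal(d, 5L)                       # no breakpoint reuse at this density
  sc <- sort_scenario(sg$a, sg$b)
  expect_equal(nrow(sc), 5)
  expect_equal(sort(table(sc$kind), decreasing = TRUE),
               sort(table(c(rep("inversion", 3), rep("translocation", 2))),
                    decreasing = TRUE), ignore_attr = TRUE)
  expect_setequal(unique(sc$kind), c("inversion", "translocation"))
})

test_that("sign-discordant markers increase with inversion count", {
  mean_discordant <- function(k) {
    vals <- vapply(1:6, function(s) {
      spec <- sim_spec(n_blocks = 200, n_inversions = k,
                       n_translocations = 0, n_contigs = 3, rng_seed = s)
      anc <- generate_ancestor(spec)
      ev <- evolve(anc, spec)
      sum(vapply(sim_chrom_vectors(ev$genome), function(v) sum(v < 0), 0L))
    }, 0L)
    mean(vals)
  }
  m <- vapply(c(2, 15, 60), mean_discordant, 0)
  expect_true(all(diff(m) > 0))
})

test_that("blocks convert to signed genomes with induced signs", {
  ca <- tibble::tibble(contig_id = c("a1", "a2"), length = c(10, 10))
  cb <- tibble::tibble(contig_id = c("b1", "b2"), length = c(10, 10))
  collinear <- tibble::tibble(
    block_id = 1:4, contig_a = c("a1", "a1", "a2", "a2"),
    a_start = c(0, 5, 0, 5), a_end = c(4, 9, 4, 9),
    contig_b = c("b1", "b1", "b2", "b2"),
    b_start = c(0, 5, 0, 5), b_end = c(4, 9, 4, 9),
    sign = "+", weight = 3L, length_bp = 4)
  sg <- blocks_to_signed_genomes(collinear, ca, cb)
  expect_equal(sg$a$chromosomes, list(c(1L, 2L), c(3L, 4L)))
  expect_equal(sg$b$chromosomes, list(c(1L, 2L), c(3L, 4L)))

  inverted <- collinear
  inverted$sign[2] <- "-"
  sg2 <- blocks_to_signed_genomes(inverted, ca, cb)
  expect_equal(sg2$b$chromosomes[[1]], c(1L, -2L))

  # shuffled fixture over 6 blocks, signed orders computed by hand
  shuffled <- tibble::tibble(
    block_id = 1:6,
    contig_a = c("a1", "a1", "a1", "a2", "a2", "a2"),
    a_start = c(0, 3, 6, 0, 3, 6), a_end = c(2, 5, 8, 2, 5, 8),
    contig_b = c("b1", "b2", "b1", "b2", "b1", "b2"),
    b_start = c(0, 6, 3, 0, 6, 3), b_end = c(2, 8, 5, 2, 8, 5),
    sign = c("+", "-", "+", "+", "-", "+"),
    weight = 3L, length_bp = 2)
  sg3 <- blocks_to_signed_genomes(shuffled, ca, cb)
  expect_equal(sg3$a$chromosomes, list(c(1L, 2L, 3L), c(4L, 5L, 6L)))
  # b1 carries markers 1,3,5 at b_start 0,3,6 -> order 1,3,-5;
  # b2 carries 4,6,2 at 0,3,6 -> order 4,6,-2
  expect_equal(sg3$b$chromosomes, list(c(1L, 3L, -5L), c(4L, 6L, -2L)))
})

test_that("missing coordinates on one genome are a hard error", {
  ca <- tibble::tibble(contig_id = "a1", length = 10)
  blocks <- tibble::tibble(block_id = 1L, contig_a = "a1", a_start = 0,
                           a_end = 5, contig_b = NA_character_,
                           b_start = NA_real_, b_end = NA_real_,
                           sign = "+", weight = 3L, length_bp = 5)
  expect_error(blocks_to_signed_genomes(blocks, ca, ca), "only one genome")
})

test_that("mcd summaries reproduce the printed table arithmetic", {
  row1 <- mcd_summary(46, 11, 3)
  expect_equal(row1$per_chromosome_all, 15.33)
  expect_equal(row1$per_chromosome_gross, 3.67)
  expect_equal(row1$gross_over_all_pct, 24)
  row2 <- mcd_summary(150, 63, 3)
  expect_equal(row2$per_chromosome_all, 50.00)
  expect_equal(row2$per_chromosome_gross, 21.00)
  expect_equal(row2$gross_over_all_pct, 42)
  expect_warning(row0 <- mcd_summary(0, 0, 3, 10), "undefined")
  expect_equal(row0$gross_over_all_pct, 0)
  expect_equal(row0$per_mb_all, 0)
})
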