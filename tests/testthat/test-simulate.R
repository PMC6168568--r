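test_that("the generator is deterministic and honours the spec", {
  spec <- sim_spec(n_blocks = 50, n_contigs = 3, rng_seed = 13)
  a1 <- generate_ancestor(spec)
  a2 <- generate_ancestor(spec)
  expect_equal(a1, a2)
  expect_equal(nrow(a1$blocks), 50)
  expect_equal(length(a1$chrom_names), 3)
  tiny <- generate_ancestor(sim_spec(n_chromosomes = 1, n_blocks = 1,
                                     n_rdna = 0, n_trna = 0,
                                     subtel_blocks = 1))
  expect_equal(nrow(tiny$blocks), 1)
  expect_error(sim_spec(n_blocks = 2, n_chromosomes = 3), "n_blocks")
})

test_that("block lengths match the requested log-normal moments", {
  spec <- sim_spec(n_blocks = 1000, n_contigs = 3, rng_seed = 99)
  a <- generate_ancestor(spec)
  se <- spec$block_len_sd / sqrt(1000)
  expect_lt(abs(mean(a$blocks$length) - spec$block_len_mean), 3 * se)
})

test_that("zero operations leave the genome unchanged", {
  spec <- sim_spec(n_blocks = 40, n_inversions = 0, n_translocations = 0,
                   n_contigs = 3, rng_seed = 5)
  anc <- generate_ancestor(spec)
  ev <- evolve(anc, spec)
  expect_equal(sim_chrom_vectors(ev$genome), sim_chrom_vectors(anc))
  expect_equal(nrow(ev$operations), 0)
})

test_that("one inversion produces exactly one maximal reversed segment", {
  for (s in 1:5) {
    spec <- sim_spec(n_blocks = 60, n_inversions = 1, n_translocations = 0,
                     n_contigs = 3, rng_seed = s)
    anc <- generate_ancestor(spec)
    ev <- evolve(anc, spec)
    va <- sim_chrom_vectors(anc); vb <- sim_chrom_vectors(ev$genome)
    diffs <- mapply(function(x, y) any(x != y), va, vb)
    expect_equal(sum(diffs), 1)
    i <- which(diffs)
    x <- va[[i]]; y <- vb[[i]]
    run <- which(x != y)
    seg <- min(run):max(run)
    expect_equal(y[seg], rev(-x[seg]))     # segment-diff oracle
    expect_equal(y[-seg], x[-seg])
  }
})

test_that("repeat-biased cuts concentrate on repeat-flanking adjacencies", {
  spec <- sim_spec(n_blocks = 300, n_inversions = 50, n_translocations = 50,
                   breakpoint_model = "repeat_biased", bias_weight = 10,
                   n_contigs = 3, rng_seed = 42)
  anc <- generate_ancestor(spec)
  ev <- evolve(anc, spec)
  hosts <- unique(anc$genes$block_id[anc$genes$marker_class == "rdna5S"])
  cuts <- rbind(as.matrix(ev$operations[, c("cut1_left", "cut1_right")]),
                as.matrix(ev$operations[, c("cut2_left", "cut2_right")]))
  at_repeat <- apply(cuts, 1, function(p) any(p %in% hosts))
  # null fraction of repeat-flanking adjacencies is ~2 * 20/300
  p0 <- 2 * length(hosts) / 300
  test <- stats::binom.test(sum(at_repeat), nrow(cuts), p0,
                            alternative = "greater")
  expect_lt(test$p.value, 0.01)
})

test_that("fragmentation is invertible given the recorded truth", {
  spec <- sim_spec(n_blocks = 60, n_contigs = 9, rng_seed = 19)
  anc <- generate_ancestor(spec)
  ev <- evolve(anc, spec)
  frag <- fragment_genome(ev$genome, 9)
  expect_equal(length(frag$genome$chrom_names), 9)
  # reassemble according to truth and compare to the derived genome
  der <- sim_chrom_vectors(ev$genome)
  ctg <- sim_chrom_vectors(frag$genome)
  names(ctg) <- frag$genome$chrom_names
  rebuilt <- lapply(split(frag$truth, frag$truth$chromosome), function(tr) {
    tr <- tr[order(tr$position), ]
    unlist(lapply(seq_len(nrow(tr)), function(i) {
      v <- ctg[[tr$contig_id[i]]]
      if (tr$orientation[i] == "-") rev(-v) else v
    }))
  })
  expect_equal(unname(rebuilt[paste0("chr", 1:3)]), der)
  # same seed -> same fragmentation; contigs = chromosomes when counts match
  frag2 <- fragment_genome(ev$genome, 9)
  expect_equal(frag2$genome, frag$genome)
  whole <- fragment_genome(ev$genome, 3)
  expect_setequal(
    vapply(sim_chrom_vectors(whole$genome), function(v)
      min(paste(v, collapse = " "), paste(rev(-v), collapse = " ")), ""),
    vapply(der, function(v)
      min(paste(v, collapse = " "), paste(rev(-v), collapse = " ")), ""))
})

test_that("noise-free hit tables are exactly the doubled true map", {
  spec <- sim_spec(n_blocks = 40, n_contigs = 3, n_rdna = 0, n_trna = 0,
                   decoy_rate = 0, rng_seed = 3)
  sim <- simulate_pair(spec)
  expect_equal(nrow(sim$hits$ab), nrow(sim$map))
  expect_equal(nrow(sim$hits$ba), nrow(sim$map))
  out <- infer_rbh(sim$hits$ab, sim$hits$ba)
  expect_setequal(paste(out$gene_a, out$gene_b),
                  paste(sim$map$gene_a, sim$map$gene_b))
})

test_that("repeat genes hit every class member in the other genome", {
  spec <- sim_spec(n_blocks = 60, n_contigs = 3, n_rdna = 5, n_trna = 0,
                   decoy_rate = 0, rng_seed = 3)
  sim <- simulate_pair(spec)
  rd <- sim$draft_genome$genes$gene_id[
    sim$draft_genome$genes$marker_class == "rdna5S"]
  hits_per_repeat <- table(sim$hits$ab$query_id[sim$hits$ab$query_id %in% rd])
  expect_true(all(hits_per_repeat >= 2))
})
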