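# Synthetic multichromosomal genomes with known rearrangement histories:
# ordered signed blocks carrying genes and marker classes, evolved by
# inversions/translocations with uniform or repeat-biased breakpoints,
# fragmented into shuffled randomly-oriented contigs, with noisy
# orthologue hit tables. Ground truth is returned for every step.

#' Simulation specification
#'
#' Defaults echo the study scale this package is aimed at: a ~12 Mb genome
#' of three chromosomes in ~500 conserved blocks, a draft assembly of nine
#' supercontigs, and a history of 4 inversions plus 7 translocations
#' (translocations outnumbering inversions, as seen between closely
#' related fission yeasts). Block lengths are log-normal with the given
#' mean/sd in bp.
#'
#' @param n_chromosomes chromosomes in the ancestor (3).
#' @param n_blocks conserved blocks genome-wide (500).
#' @param block_len_mean,block_len_sd log-normal block length moments in bp
#'   (25000 / 20000).
#' @param genes_per_block anchor genes placed in each block (4).
#' @param n_inversions,n_translocations history composition (4 / 7).
#' @param breakpoint_model `"uniform"` or `"repeat_biased"`.
#' @param bias_weight relative cut weight of repeat-flanking adjacencies
#'   under `repeat_biased` (10).
#' @param n_contigs fragments the derived genome is split into (9).
#' @param subtel_blocks terminal blocks per chromosome end whose genes are
#'   subtelomeric markers (2).
#' @param pericent_blocks central blocks per chromosome whose genes are
#'   pericentromeric markers (1).
#' @param n_rdna,n_trna dispersed 5S rDNA / tRNA repeat loci (20 / 10).
#' @param decoy_rate probability a gene gets an extra spurious hit (0.1).
#' @param gap_bp intergenic gap between consecutive blocks (200).
#' @param rng_seed master seed; every stage derives its own stream from it.
#' @return named list of class `sim_spec`.
#' @export
sim_spec <- function(n_chromosomes = 3, n_blocks = 500,
                     block_len_mean = 25000, block_len_sd = 20000,
                     genes_per_block = 4, n_inversions = 4,
                     n_translocations = 7,
                     breakpoint_model = c("uniform", "repeat_biased"),
                     bias_weight = 10, n_contigs = 9, subtel_blocks = 2,
                     pericent_blocks = 1, n_rdna = 20, n_trna = 10,
                     decoy_rate = 0.1, gap_bp = 200, rng_seed = 1L) {
  breakpoint_model <- match.arg(breakpoint_model)
  if (n_blocks < n_chromosomes) abort_bad_arg("n_blocks < n_chromosomes")
  if (n_contigs < n_chromosomes) abort_bad_arg("n_contigs < n_chromosomes")
  stopifnot(n_inversions >= 0, n_translocations >= 0)
  structure(as.list(environment()), class = c("sim_spec", "list"))
}

#' Generate an ancestral genome of signed blocks
#'
#' Blocks are laid contiguously (with small intergenic gaps) on
#' near-equal-sized chromosomes; each block carries `genes_per_block`
#' anchor genes. Marker classes follow the placement rule: subtelomeric
#' genes in the terminal blocks of each chromosome, pericentromeric genes
#' in the central blocks, and dispersed 5S rDNA / tRNA repeat genes at
#' randomly chosen internal host blocks. Deterministic given the seed.
#'
#' @param spec a [sim_spec()].
#' @return object of class `sim_genome`: list with `name`, `blocks`
#'   (tibble `block_id`, `chrom`, `pos`, `sign`, `length`), `genes`
#'   (block-relative gene table), `chrom_names`, `spec`.
#' @export
generate_ancestor <- function(spec) {
  set.seed(derive_seed(spec$rng_seed, "ancestor"))
  B <- spec$n_blocks; K <- spec$n_chromosomes
  cv <- spec$block_len_sd / spec$block_len_mean
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(spec$block_len_mean) - sdlog^2 / 2
  len <- pmax(2000, round(stats::rlnorm(B, meanlog, sdlog)))
  sizes <- diff(round(seq(0, B, length.out = K + 1)))
  chrom_names <- paste0("chr", seq_len(K))
  chrom <- rep(chrom_names, sizes)
  pos <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  blocks <- tibble::tibble(block_id = seq_len(B), chrom = chrom, pos = pos,
                           sign = 1L, length = len)

  k <- spec$genes_per_block
  b_rep <- rep(seq_len(B), each = k)
  j_rep <- rep(seq_len(k), B)
  slot <- len[b_rep] / k
  width <- pmax(200, floor(slot / 2))
  genes <- tibble::tibble(
    core = sprintf("g%05d_%d", b_rep, j_rep), block_id = b_rep,
    offset = pmax(0, floor((j_rep - 1) * slot + (slot - width) / 2)),
    width = width,
    strand = sample(c("+", "-"), B * k, replace = TRUE),
    marker_class = "none")

  # marker placement: terminal blocks subtelomeric, central pericentromeric
  for (ci in seq_len(K)) {
    bl <- blocks$block_id[blocks$chrom == chrom_names[ci]]
    nb <- length(bl)
    m <- min(spec$subtel_blocks, nb)
    sub <- c(bl[seq_len(m)], bl[seq(nb - m + 1, nb)])
    mid <- bl[ceiling(nb / 2) + seq_len(spec$pericent_blocks) -
                ceiling(spec$pericent_blocks / 2)]
    genes$marker_class[genes$block_id %in% sub] <- "subtelomeric"
    genes$marker_class[genes$block_id %in% mid] <- "pericentromeric"
  }

  # dispersed repeats appended at the tail of random internal host blocks
  marker_blocks <- unique(genes$block_id[genes$marker_class != "none"])
  hosts <- setdiff(blocks$block_id, marker_blocks)
  n_rep <- spec$n_rdna + spec$n_trna
  if (n_rep > 0 && length(hosts) >= n_rep) {
    picked <- sample(hosts, n_rep)
    rd <- picked[seq_len(spec$n_rdna)]
    tr <- picked[spec$n_rdna + seq_len(spec$n_trna)]
    rep_genes <- dplyr::bind_rows(
      tibble::tibble(core = sprintf("r5S%03d", seq_along(rd)), block_id = rd,
                     offset = len[rd] - 140, width = 120, strand = "+",
                     marker_class = "rdna5S"),
      tibble::tibble(core = sprintf("tRNA%03d", seq_along(tr)), block_id = tr,
                     offset = len[tr] - 300, width = 80, strand = "+",
                     marker_class = "trna"))
    genes <- dplyr::bind_rows(genes, rep_genes)
  }
  structure(list(name = "ref", blocks = blocks, genes = genes,
                 chrom_names = chrom_names, spec = spec),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome> ", x$name, ": ", length(x$chrom_names),
      " chromosome(s)/contig(s), ", nrow(x$blocks), " blocks, ",
      nrow(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Signed block vectors of a simulated genome
#'
#' @param sim a `sim_genome`.
#' @return list of integer vectors (signed block ids), one per
#'   chromosome/contig, in `chrom_names` order.
#' @export
sim_chrom_vectors <- function(sim) {
  lapply(sim$chrom_names, function(cn) {
    b <- sim$blocks[sim$blocks$chrom == cn, , drop = FALSE]
    b <- b[order(b$pos), , drop = FALSE]
    as.integer(b$sign * b$block_id)
  })
}

sim_from_vectors <- function(sim, vectors, chrom_names) {
  blocks <- purrr::map_dfr(seq_along(vectors), function(i) {
    v <- vectors[[i]]
    tibble::tibble(block_id = abs(v), chrom = chrom_names[i],
                   pos = seq_along(v), sign = as.integer(sign(v)))
  })
  blocks$length <- sim$blocks$length[match(blocks$block_id,
                                           sim$blocks$block_id)]
  sim$blocks <- blocks
  sim$chrom_names <- chrom_names
  sim
}

# internal inter-block adjacencies with repeat-bias weights:
# (chrom index, position) of the gap between pos and pos+1
sim_adjacencies <- function(vectors, repeat_hosts, bias_weight) {
  purrr::map_dfr(seq_along(vectors), function(i) {
    v <- vectors[[i]]
    if (length(v) < 2) return(tibble::tibble())
    j <- seq_len(length(v) - 1)
    tibble::tibble(chrom = i, pos = j,
                   left_block = abs(v[j]), right_block = abs(v[j + 1]),
                   weight = ifelse(abs(v[j]) %in% repeat_hosts |
                                     abs(v[j + 1]) %in% repeat_hosts,
                                   bias_weight, 1))
  })
}

#' Apply a rearrangement history
#'
#' Applies `n_inversions + n_translocations` operations in random order.
#' Cut sites are drawn over the internal inter-block adjacencies —
#' uniformly, or with `bias_weight`-fold mass on adjacencies flanking
#' repeat (5S rDNA) host blocks under the `repeat_biased` model.
#' Translocations exchange chromosome arms between two chromosomes (in
#' direct or inverted mode); inversions reverse the segment between two
#' cuts of one chromosome. The exact history is returned.
#'
#' @param sim ancestor `sim_genome`.
#' @param spec a [sim_spec()] (counts, breakpoint model, seed).
#' @param name name of the derived genome (default `"der"`).
#' @return list: `genome` (derived `sim_genome`) and `operations` (tibble
#'   `step`, `kind`, `chrom_1`, `pos_1`, `chrom_2`, `pos_2`, and the block
#'   pairs flanking each cut `cut1_left`, `cut1_right`, `cut2_left`,
#'   `cut2_right`).
#' @export
evolve <- function(sim, spec, name = "der") {
  set.seed(derive_seed(spec$rng_seed, "evolve"))
  vectors <- sim_chrom_vectors(sim)
  repeat_hosts <- if (spec$breakpoint_model == "repeat_biased")
    unique(sim$genes$block_id[sim$genes$marker_class == "rdna5S"])
  else integer(0)
  kinds <- sample(c(rep("inversion", spec$n_inversions),
                    rep("translocation", spec$n_translocations)))
  ops <- tibble::tibble(step = integer(), kind = character(),
                        chrom_1 = integer(), pos_1 = integer(),
                        chrom_2 = integer(), pos_2 = integer(),
                        cut1_left = integer(), cut1_right = integer(),
                        cut2_left = integer(), cut2_right = integer())
  for (s in seq_along(kinds)) {
    adj <- sim_adjacencies(vectors, repeat_hosts, spec$bias_weight)
    if (kinds[s] == "inversion") {
      ok <- adj$chrom %in% which(vapply(vectors, length, 0L) >= 3)
      a1 <- adj[ok, , drop = FALSE][
        sample(sum(ok), 1, prob = adj$weight[ok]), ]
      same <- adj[adj$chrom == a1$chrom & adj$pos != a1$pos, , drop = FALSE]
      a2 <- same[sample(nrow(same), 1, prob = same$weight), ]
      j1 <- min(a1$pos, a2$pos); j2 <- max(a1$pos, a2$pos)
      v <- vectors[[a1$chrom]]
      v[(j1 + 1):j2] <- rev(-v[(j1 + 1):j2])
      vectors[[a1$chrom]] <- v
      ops <- dplyr::bind_rows(ops, tibble::tibble(
        step = s, kind = "inversion", chrom_1 = a1$chrom, pos_1 = j1,
        chrom_2 = a1$chrom, pos_2 = j2,
        cut1_left = min(a1$left_block, a1$right_block),
        cut1_right = max(a1$left_block, a1$right_block),
        cut2_left = min(a2$left_block, a2$right_block),
        cut2_right = max(a2$left_block, a2$right_block)))
    } else {
      # reciprocal translocation; products carrying zero or two centromeres
      # are inviable, so such draws are rejected and resampled
      centro <- unique(sim$genes$block_id[sim$genes$marker_class ==
                                            "pericentromeric"])
      repeat {
        a1 <- adj[sample(nrow(adj), 1, prob = adj$weight), ]
        other <- adj[adj$chrom != a1$chrom, , drop = FALSE]
        a2 <- other[sample(nrow(other), 1, prob = other$weight), ]
        v1 <- vectors[[a1$chrom]]; v2 <- vectors[[a2$chrom]]
        L1 <- v1[seq_len(a1$pos)]; R1 <- v1[seq(a1$pos + 1, length(v1))]
        L2 <- v2[seq_len(a2$pos)]; R2 <- v2[seq(a2$pos + 1, length(v2))]
        if (stats::runif(1) < 0.5) {
          n1 <- c(L1, R2); n2 <- c(L2, R1)
        } else {
          n1 <- c(L1, rev(-L2)); n2 <- c(rev(-R1), R2)
        }
        viable <- any(abs(n1) %in% centro) && any(abs(n2) %in% centro)
        if (viable) break
      }
      vectors[[a1$chrom]] <- n1
      vectors[[a2$chrom]] <- n2
      ops <- dplyr::bind_rows(ops, tibble::tibble(
        step = s, kind = "translocation", chrom_1 = a1$chrom, pos_1 = a1$pos,
        chrom_2 = a2$chrom, pos_2 = a2$pos,
        cut1_left = min(a1$left_block, a1$right_block),
        cut1_right = max(a1$left_block, a1$right_block),
        cut2_left = min(a2$left_block, a2$right_block),
        cut2_right = max(a2$left_block, a2$right_block)))
    }
  }
  out <- sim_from_vectors(sim, vectors, sim$chrom_names)
  out$name <- name
  list(genome = out, operations = ops)
}

#' Fragment a genome into shuffled, randomly oriented contigs
#'
#' Cut points fall between blocks only (never inside one); the pieces are
#' shuffled and each is flipped with probability 0.5. The true order and
#' orientation is returned. Adjacencies listed in `avoid_adjacencies`
#' (block-id pairs, e.g. the cut sites of a known rearrangement history)
#' are never chosen as contig boundaries.
#'
#' @param sim a `sim_genome`.
#' @param n_contigs number of contigs (>= number of chromosomes).
#' @param seed integer seed (default: the spec's).
#' @param avoid_adjacencies optional two-column matrix/tibble of block-id
#'   pairs to exclude as cut sites.
#' @param name name of the fragmented genome (default `"draft"`).
#' @return list: `genome` (fragmented `sim_genome`, contigs in shuffled
#'   order) and `truth` (tibble `chromosome`, `position`, `contig_id`,
#'   `orientation`).
#' @export
fragment_genome <- function(sim, n_contigs, seed = NULL,
                            avoid_adjacencies = NULL, name = "draft") {
  set.seed(derive_seed(seed %||% sim$spec$rng_seed, "fragment"))
  vectors <- sim_chrom_vectors(sim)
  K <- length(vectors)
  stopifnot(n_contigs >= K)
  adj <- sim_adjacencies(vectors, integer(0), 1)
  if (!is.null(avoid_adjacencies) && length(avoid_adjacencies)) {
    av <- as.matrix(avoid_adjacencies)
    keys <- paste(pmin(av[, 1], av[, 2]), pmax(av[, 1], av[, 2]))
    adj <- adj[!(paste(pmin(adj$left_block, adj$right_block),
                       pmax(adj$left_block, adj$right_block)) %in% keys), ,
               drop = FALSE]
  }
  n_cuts <- n_contigs - K
  if (nrow(adj) < n_cuts) abort_bad_arg("not enough cuttable adjacencies")
  cuts <- adj[sample(nrow(adj), n_cuts), , drop = FALSE]
  pieces <- list(); origin <- list()
  for (ci in seq_len(K)) {
    v <- vectors[[ci]]
    cp <- sort(cuts$pos[cuts$chrom == ci])
    bounds <- c(0, cp, length(v))
    for (pi in seq_len(length(bounds) - 1)) {
      pieces[[length(pieces) + 1L]] <- v[(bounds[pi] + 1):bounds[pi + 1]]
      origin[[length(origin) + 1L]] <- c(ci, pi)
    }
  }
  ord <- sample(length(pieces))
  flip <- stats::runif(length(pieces)) < 0.5
  ctg_names <- sprintf("ctg%02d", seq_along(pieces))
  out_vecs <- vector("list", length(pieces))
  truth <- tibble::tibble(chromosome = character(), position = integer(),
                          contig_id = character(), orientation = character())
  for (k in seq_along(ord)) {
    src <- ord[k]
    v <- pieces[[src]]
    if (flip[k]) v <- rev(-v)
    out_vecs[[k]] <- v
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      chromosome = sim$chrom_names[origin[[src]][1]],
      position = origin[[src]][2], contig_id = ctg_names[k],
      orientation = ifelse(flip[k], "-", "+")))
  }
  out <- sim_from_vectors(sim, out_vecs, ctg_names)
  out$name <- name
  truth <- dplyr::arrange(truth, .data$chromosome, .data$position)
  list(genome = out, truth = truth)
}

#' Materialise a simulated genome as a `genome` object
#'
#' Lays blocks out physically (in order, separated by the spec's
#' intergenic gap) and places each block's genes inside its span; a
#' flipped block reverses its genes' order and strands. Gene ids are
#' `<name>.<core>`, so orthologous genes of two emitted genomes share the
#' core.
#'
#' @param sim a `sim_genome`.
#' @return a [genome()] object (no sequences).
#' @export
as_genome <- function(sim) {
  gap <- sim$spec$gap_bp
  contigs <- purrr::map_dfr(sim$chrom_names, function(cn) {
    b <- sim$blocks[sim$blocks$chrom == cn, , drop = FALSE]
    tibble::tibble(contig_id = cn,
                   length = sum(b$length) + gap * max(0, nrow(b) - 1))
  })
  b_all <- sim$blocks |>
    dplyr::arrange(match(.data$chrom, sim$chrom_names), .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(block_start = cumsum(c(0, utils::head(.data$length + gap,
                                                        -1)))) |>
    dplyr::ungroup()
  idx <- match(sim$genes$block_id, b_all$block_id)
  g <- sim$genes
  fwd <- b_all$sign[idx] > 0
  st <- ifelse(fwd, b_all$block_start[idx] + g$offset,
               b_all$block_start[idx] + b_all$length[idx] - g$offset - g$width)
  genes <- tibble::tibble(
    gene_id = paste0(sim$name, ".", g$core),
    contig_id = b_all$chrom[idx],
    start = st, end = st + g$width,
    strand = ifelse(fwd, g$strand, ifelse(g$strand == "+", "-", "+")),
    marker_class = g$marker_class)
  genome(genes, contigs, name = sim$name)
}

#' Block-level signed genomes of a simulated pair
#'
#' @param sim_a,sim_b two `sim_genome`s over the same block universe.
#' @return list of two `signed_genome`s named `a`, `b`.
#' @export
sim_signed_genomes <- function(sim_a, sim_b) {
  list(a = signed_genome(sim_chrom_vectors(sim_a), name = sim_a$name),
       b = signed_genome(sim_chrom_vectors(sim_b), name = sim_b$name))
}

#' True orthologue map between two emitted genomes
#'
#' Pairs genes sharing the simulator core id; dispersed repeat classes
#' (5S rDNA, tRNA) are excluded — they have no one-to-one orthology.
#'
#' @param genome_a,genome_b [genome()] objects emitted by [as_genome()].
#' @return tibble `gene_a`, `gene_b`.
#' @export
true_orthologue_map <- function(genome_a, genome_b) {
  ga <- genome_a$genes[!genome_a$genes$marker_class %in%
                         c("rdna5S", "trna"), , drop = FALSE]
  gb <- genome_b$genes[!genome_b$genes$marker_class %in%
                         c("rdna5S", "trna"), , drop = FALSE]
  ca <- sub("^[^.]*\\.", "", ga$gene_id)
  cb <- sub("^[^.]*\\.", "", gb$gene_id)
  common <- intersect(ca, cb)
  tibble::tibble(gene_a = ga$gene_id[match(common, ca)],
                 gene_b = gb$gene_id[match(common, cb)])
}

#' Emit noisy reciprocal hit tables
#'
#' Every true pair receives strong mutual hits (E-values far below any
#' sensible threshold, top bitscores); with probability `decoy_rate` a gene
#' additionally gets a spurious hit with a worse bitscore and higher
#' E-value; dispersed repeat genes (5S rDNA, tRNA) hit every member of
#' their class in the other genome with near-equal scores, producing the
#' many-to-many pattern that the multi-copy filter must remove.
#'
#' @param genome_a,genome_b [genome()] objects.
#' @param map true pair tibble from [true_orthologue_map()].
#' @param decoy_rate spurious-hit probability per gene (default 0.1).
#' @param seed integer seed.
#' @return list of two hit tibbles `ab`, `ba`.
#' @export
emit_hit_tables <- function(genome_a, genome_b, map, decoy_rate = 0.1,
                            seed = 1L) {
  set.seed(derive_seed(seed, "hits"))
  n <- nrow(map)
  ab <- tibble::tibble(query_id = map$gene_a, subject_id = map$gene_b,
                       evalue = 10^-stats::runif(n, 60, 180),
                       bitscore = stats::runif(n, 800, 2500))
  ba <- tibble::tibble(query_id = map$gene_b, subject_id = map$gene_a,
                       evalue = 10^-stats::runif(n, 60, 180),
                       bitscore = stats::runif(n, 800, 2500))
  decoy <- function(queries, subjects_pool, truth) {
    pick <- stats::runif(length(queries)) < decoy_rate
    q <- queries[pick]
    if (!length(q)) return(tibble::tibble())
    s <- vapply(seq_along(q), function(i)
      sample(setdiff(subjects_pool, truth[pick][i]), 1), "")
    tibble::tibble(query_id = q, subject_id = s,
                   evalue = 10^-stats::runif(length(q), 1, 6),
                   bitscore = stats::runif(length(q), 100, 700))
  }
  ab <- dplyr::bind_rows(ab, decoy(map$gene_a, genome_b$genes$gene_id,
                                   map$gene_b))
  ba <- dplyr::bind_rows(ba, decoy(map$gene_b, genome_a$genes$gene_id,
                                   map$gene_a))
  for (cls in c("rdna5S", "trna")) {
    ra <- genome_a$genes$gene_id[genome_a$genes$marker_class == cls]
    rb <- genome_b$genes$gene_id[genome_b$genes$marker_class == cls]
    if (!length(ra) || !length(rb)) next
    grid <- expand.grid(query_id = ra, subject_id = rb,
                        stringsAsFactors = FALSE)
    m <- nrow(grid)
    ab <- dplyr::bind_rows(ab, tibble::tibble(
      query_id = grid$query_id, subject_id = grid$subject_id,
      evalue = 10^-stats::runif(m, 10, 20),
      bitscore = stats::runif(m, 250, 350)))
    ba <- dplyr::bind_rows(ba, tibble::tibble(
      query_id = grid$subject_id, subject_id = grid$query_id,
      evalue = 10^-stats::runif(m, 10, 20),
      bitscore = stats::runif(m, 250, 350)))
  }
  list(ab = ab, ba = ba)
}

#' Simulate a full comparison: reference, derived genome, draft contigs
#'
#' Convenience wrapper chaining [generate_ancestor()], [evolve()],
#' [fragment_genome()] and [emit_hit_tables()] into the complete
#' ground-truth bundle the pipeline stages consume.
#'
#' @param spec a [sim_spec()].
#' @param avoid_rearranged_cuts when TRUE, contig boundaries avoid the
#'   adjacencies broken by the rearrangement history, so every contig
#'   junction of the true assembly is bridgeable on the reference.
#' @return list: `spec`, `ancestor`, `derived`, `operations`, `draft`,
#'   `truth`, `ancestor_genome`, `draft_genome`, `derived_genome`, `map`,
#'   `hits` (list `ab`, `ba`).
#' @export
simulate_pair <- function(spec = sim_spec(), avoid_rearranged_cuts = FALSE) {
  anc <- generate_ancestor(spec)
  ev <- evolve(anc, spec)
  avoid <- NULL
  if (avoid_rearranged_cuts && nrow(ev$operations)) {
    # contig boundaries must fall at adjacencies the reference can bridge:
    # exclude every derived adjacency that is not also ancestral (both the
    # broken sites and the novel joins the history created)
    adj_pairs <- function(s) {
      do.call(rbind, lapply(sim_chrom_vectors(s), function(v) {
        if (length(v) < 2) return(NULL)
        cbind(pmin(abs(v[-length(v)]), abs(v[-1])),
              pmax(abs(v[-length(v)]), abs(v[-1])))
      }))
    }
    anc_adj <- adj_pairs(anc)
    der_adj <- adj_pairs(ev$genome)
    novel <- !(paste(der_adj[, 1], der_adj[, 2]) %in%
                 paste(anc_adj[, 1], anc_adj[, 2]))
    avoid <- der_adj[novel, , drop = FALSE]
  }
  frag <- fragment_genome(ev$genome, spec$n_contigs,
                          avoid_adjacencies = avoid)
  ancestor_genome <- as_genome(anc)
  draft_genome <- as_genome(frag$genome)
  map <- true_orthologue_map(draft_genome, ancestor_genome)
  hits <- emit_hit_tables(draft_genome, ancestor_genome, map,
                          decoy_rate = spec$decoy_rate,
                          seed = spec$rng_seed)
  list(spec = spec, ancestor = anc, derived = ev$genome,
       operations = ev$operations, draft = frag$genome, truth = frag$truth,
       ancestor_genome = ancestor_genome, draft_genome = draft_genome,
       derived_genome = as_genome(ev$genome), map = map, hits = hits)
}
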