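# Independent oracles used by the tests. These deliberately re-derive the
# genome combinatorics from first principles (their own extremity encoding,
# exhaustive enumeration, BFS) so they share no code with the package
# implementation they check.

hx_left <- function(g) ifelse(g > 0, 2L * g - 1L, -2L * g)
hx_right <- function(g) ifelse(g > 0, 2L * g, -2L * g - 1L)

# state: list(v = list of integer vectors, circ = logical)
oracle_state <- function(chroms, circ = NULL) {
  list(v = lapply(chroms, as.integer),
       circ = circ %||% rep(FALSE, length(chroms)))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

oracle_adj <- function(st, n) {
  adj <- integer(2L * n)
  for (i in seq_along(st$v)) {
    v <- st$v[[i]]
    if (length(v) > 1) {
      x <- hx_right(v[-length(v)]); y <- hx_left(v[-1])
      adj[x] <- y; adj[y] <- x
    }
    if (st$circ[i]) {
      x <- hx_right(v[length(v)]); y <- hx_left(v[1])
      adj[x] <- y; adj[y] <- x
    }
  }
  adj
}

# rebuild chromosomes from an adjacency map (telomere-first walk, then
# leftover circular chromosomes)
oracle_rebuild <- function(adj, n) {
  used <- logical(n)
  vs <- list(); circ <- logical(0)
  walk <- function(start_ext) {
    v <- integer(0)
    e <- start_ext
    repeat {
      m <- (e + 1L) %/% 2L
      s <- if (e %% 2L == 1L) m else -m     # entered at tail -> forward
      v <- c(v, s)
      used[m] <<- TRUE
      out <- if (e %% 2L == 1L) 2L * m else 2L * m - 1L
      nxt <- adj[out]
      if (nxt == 0L) return(list(v = v, end = 0L))
      if (used[(nxt + 1L) %/% 2L]) return(list(v = v, end = nxt))
      e <- nxt
    }
  }
  for (t in seq_len(2L * n)) {
    m <- (t + 1L) %/% 2L
    if (used[m] || adj[t] != 0L) next
    r <- walk(t)
    vs[[length(vs) + 1L]] <- r$v
    circ <- c(circ, FALSE)
  }
  for (m in seq_len(n)) {
    if (used[m]) next
    r <- walk(2L * m - 1L)
    vs[[length(vs) + 1L]] <- r$v
    circ <- c(circ, TRUE)
  }
  list(v = vs, circ = circ)
}

oracle_canon <- function(st) {
  lin <- character(0); cir <- character(0)
  for (i in seq_along(st$v)) {
    v <- st$v[[i]]
    if (!st$circ[i]) {
      lin <- c(lin, min(paste(v, collapse = " "),
                        paste(rev(-v), collapse = " ")))
    } else {
      reps <- character(0)
      for (w in list(v, rev(-v))) {
        for (r in seq_along(w)) {
          rot <- c(w[r:length(w)], w[seq_len(r - 1)])
          reps <- c(reps, paste(rot, collapse = " "))
        }
      }
      cir <- c(cir, min(reps))
    }
  }
  paste(c(sort(lin), paste0("(", sort(cir), ")")), collapse = " | ")
}

# every genome reachable by one DCJ operation
oracle_neighbors <- function(adj, n) {
  pairs <- which(adj > seq_len(2L * n))      # adjacency reps p with adj[p] > p
  adjacencies <- lapply(which(adj > 0 & adj > seq_len(2L * n)),
                        function(p) c(p, adj[p]))
  telomeres <- setdiff(which(adj[seq_len(2L * n)] == 0L), integer(0))
  out <- list()
  push <- function(a) out[[length(out) + 1L]] <<- a
  nA <- length(adjacencies)
  if (nA >= 2) {
    for (i in seq_len(nA - 1)) for (j in seq(i + 1, nA)) {
      ab <- adjacencies[[i]]; cd <- adjacencies[[j]]
      for (opt in 1:2) {
        a2 <- adj
        if (opt == 1) { x <- c(ab[1], cd[1]); y <- c(ab[2], cd[2]) }
        else { x <- c(ab[1], cd[2]); y <- c(ab[2], cd[1]) }
        a2[x[1]] <- x[2]; a2[x[2]] <- x[1]
        a2[y[1]] <- y[2]; a2[y[2]] <- y[1]
        push(a2)
      }
    }
  }
  for (i in seq_len(nA)) for (t in telomeres) {
    ab <- adjacencies[[i]]
    for (keep in 1:2) {
      a2 <- adj
      a2[ab[1]] <- 0L; a2[ab[2]] <- 0L
      a2[ab[keep]] <- t; a2[t] <- ab[keep]
      push(a2)
    }
  }
  nT <- length(telomeres)
  if (nT >= 2) {
    for (i in seq_len(nT - 1)) for (j in seq(i + 1, nT)) {
      a2 <- adj
      a2[telomeres[i]] <- telomeres[j]; a2[telomeres[j]] <- telomeres[i]
      push(a2)
    }
  }
  for (i in seq_len(nA)) {
    ab <- adjacencies[[i]]
    a2 <- adj
    a2[ab[1]] <- 0L; a2[ab[2]] <- 0L
    push(a2)
  }
  out
}

# brute-force DCJ distance by breadth-first search over genomes (circular
# intermediates allowed, as in the unrestricted DCJ model)
bfs_dcj_distance <- function(chroms_a, chroms_b, max_depth = 6) {
  n <- length(unlist(chroms_a))
  target <- oracle_canon(oracle_state(chroms_b))
  start <- oracle_state(chroms_a)
  if (oracle_canon(start) == target) return(0L)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(oracle_canon(start), TRUE, visited)
  frontier <- list(oracle_adj(start, n))
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (adj in frontier) {
      for (a2 in oracle_neighbors(adj, n)) {
        st2 <- oracle_rebuild(a2, n)
        key <- oracle_canon(st2)
        if (key == target) return(depth)
        if (!exists(key, visited)) {
          assign(key, TRUE, visited)
          nxt[[length(nxt) + 1L]] <- a2
        }
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  stop("BFS exceeded max_depth")
}

# random linear multichromosomal genome over markers 1..n
random_genome_chroms <- function(n, k) {
  perm <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
  if (k == 1) return(list(perm))
  cuts <- sort(sample(n - 1, k - 1))
  unname(split(perm, cut(seq_len(n), c(0, cuts, n))))
}

# apply r random DCJ-style operations (inversions/translocations) to chroms
scramble_chroms <- function(chroms, r) {
  for (i in seq_len(r)) {
    if (length(chroms) >= 2 && stats::runif(1) < 0.5) {
      ij <- sample(length(chroms), 2)
      v1 <- chroms[[ij[1]]]; v2 <- chroms[[ij[2]]]
      p1 <- sample(0:length(v1), 1); p2 <- sample(0:length(v2), 1)
      chroms[[ij[1]]] <- c(v1[seq_len(p1)], v2[seq(p2 + 1, length.out = length(v2) - p2)])
      chroms[[ij[2]]] <- c(v2[seq_len(p2)], v1[seq(p1 + 1, length.out = length(v1) - p1)])
      chroms <- chroms[vapply(chroms, length, 0L) > 0]
    } else {
      ci <- sample(length(chroms), 1)
      v <- chroms[[ci]]
      if (length(v) < 1) next
      ab <- sort(sample(length(v), 2, replace = TRUE))
      chroms[[ci]] <- c(v[seq_len(ab[1] - 1)], rev(-v[ab[1]:ab[2]]),
                        v[seq(ab[2] + 1, length.out = length(v) - ab[2])])
    }
  }
  chroms
}

# exhaustive maximal-chain size for anchors of one contig pair/orientation:
# enumerates every strictly-collinear subsequence satisfying the gap bound
oracle_best_chain <- function(a_start, a_end, b_start, b_end, sign,
                              max_gap) {
  n <- length(a_start)
  best <- 0L
  recurse <- function(chain, last) {
    best <<- max(best, length(chain))
    for (i in seq_len(n)) {
      if (i %in% chain) next
      if (length(chain)) {
        if (a_start[i] <= a_start[last]) next
        if (a_start[i] - a_end[last] > max_gap) next
        if (sign == "+") {
          if (b_start[i] <= b_start[last]) next
          if (b_start[i] - b_end[last] > max_gap) next
        } else {
          if (b_start[i] >= b_start[last]) next
          if (b_start[last] - b_end[i] > max_gap) next
        }
      }
      recurse(c(chain, i), i)
    }
  }
  recurse(integer(0), 0L)
  best
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all_v <- c(x, y)
  combos <- utils::combn(nx + ny, nx)
  u_obs <- sum(rank(all_v)[seq_len(nx)]) - nx * (nx + 1) / 2
  us <- apply(combos, 2, function(idx) {
    sum(rank(all_v)[idx]) - nx * (nx + 1) / 2
  })
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# canonical form of an assembly path set, for truth comparison up to
# whole-chromosome reflection
canon_paths <- function(df, chrom_col) {
  sp <- split(df, df[[chrom_col]])
  sort(unname(vapply(sp, function(p) {
    fwd <- paste(paste0(p$contig_id, p$orientation), collapse = " ")
    rv <- paste(paste0(rev(p$contig_id),
                       ifelse(rev(p$orientation) == "+", "-", "+")),
                collapse = " ")
    min(fwd, rv)
  }, "")))
}

# run the full simulate -> orthology -> synteny -> scaffold chain and
# report whether the true order/orientation was recovered
run_scaffold_recovery <- function(seed, spec = NULL) {
  spec <- spec %||% sim_spec(rng_seed = seed)
  sim <- simulate_pair(spec, avoid_rearranged_cuts = TRUE)
  pairs <- infer_rbh(sim$hits$ab, sim$hits$ba) |>
    drop_multicopy(sim$draft_genome$genes, sim$ancestor_genome$genes) |>
    filter_by_synteny(sim$draft_genome$genes, sim$ancestor_genome$genes)
  blocks <- chain_anchors(pairs, sim$draft_genome$genes,
                          sim$ancestor_genome$genes)
  el <- classify_contig_ends(sim$draft_genome$genes,
                             sim$draft_genome$contigs)
  blocks <- classify_blocks(blocks, sim$draft_genome$contigs, el)
  cand <- build_adjacency_graph(list(reference = blocks),
                                sim$draft_genome$contigs)
  asm <- order_contigs(cand, el, sim$draft_genome$contigs,
                       spec$n_chromosomes)
  identical(canon_paths(sim$truth, "chromosome"),
            canon_paths(asm$assemblies, "chromosome"))
}

make_genes <- function(...) {
  g <- tibble::tibble(...)
  if (!"marker_class" %in% names(g)) g$marker_class <- "none"
  if (!"strand" %in% names(g)) g$strand <- "+"
  g
}
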