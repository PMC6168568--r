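# Breakpoint regions between large collinear blocks, their repeat
# association, and the random breakage model test.

#' Find breakpoint regions between adjacent blocks
#'
#' Walks the gross blocks along one genome and emits a region for every
#' pair of neighbouring blocks whose counterparts are *not* neighbouring
#' and equally oriented on the other genome — i.e. positions where synteny
#' is interrupted by a rearrangement. Chromosome ends are excluded. Run
#' once per direction (`side = "a"` then `"b"`) for the reciprocal check.
#'
#' @param blocks block tibble (typically the `gross` subset of
#'   [classify_blocks()]).
#' @param side `"a"` or `"b"`: the genome on which regions are reported.
#' @return tibble: `contig_id`, `start`, `end` (the gap between the two
#'   flanking blocks, 0-based half-open), `left_block`, `right_block`.
#' @export
find_breakpoints <- function(blocks, side = c("a", "b")) {
  side <- match.arg(side)
  other <- if (side == "a") "b" else "a"
  cg <- paste0("contig_", side); s <- paste0(side, "_start")
  e <- paste0(side, "_end")
  co <- paste0("contig_", other); so <- paste0(other, "_start")
  out <- tibble::tibble(contig_id = character(), start = numeric(),
                        end = numeric(), left_block = integer(),
                        right_block = integer())
  if (nrow(blocks) < 2) return(out)
  b <- blocks[order(blocks[[cg]], blocks[[s]]), , drop = FALSE]
  # rank of each block along the other genome, to test counterpart adjacency
  ord_other <- order(b[[co]], b[[so]])
  rank_other <- integer(nrow(b)); rank_other[ord_other] <- seq_len(nrow(b))
  for (i in seq_len(nrow(b) - 1)) {
    j <- i + 1
    if (b[[cg]][i] != b[[cg]][j]) next      # chromosome end, not a breakpoint
    conserved <- b[[co]][i] == b[[co]][j] &&
      b$sign[i] == b$sign[j] &&
      abs(rank_other[i] - rank_other[j]) == 1 &&
      ((b$sign[i] == "+" && rank_other[j] == rank_other[i] + 1) ||
         (b$sign[i] == "-" && rank_other[j] == rank_other[i] - 1))
    if (conserved) next
    out <- dplyr::bind_rows(out, tibble::tibble(
      contig_id = b[[cg]][i], start = b[[e]][i], end = b[[s]][j],
      left_block = b$block_id[i], right_block = b$block_id[j]))
  }
  out
}

#' Associate annotated features with breakpoint regions
#'
#' A feature is associated with a region when its span intersects the
#' region extended by `margin_bp` on both sides. Regions longer than
#' 1000 bp that contain no gene at all inside the unextended interval are
#' flagged `large_intergenic` — rearrangements there fell in large gene
#' deserts rather than at annotated repeats.
#'
#' @param regions tibble from [find_breakpoints()].
#' @param genes gene table carrying `marker_class`.
#' @param margin_bp association margin in bp (default 5000).
#' @return `regions` with `n_features`, `classes` (comma-joined feature
#'   classes), `large_intergenic`, and a list-column `features` of
#'   per-region association tables (`gene_id`, `class`, `distance_bp`).
#'   The per-class association counts (number of regions with at least one
#'   feature of the class) are attached as attribute `class_counts`.
#' @export
annotate_breakpoints <- function(regions, genes, margin_bp = 5000) {
  feats <- vector("list", nrow(regions))
  n_features <- integer(nrow(regions))
  classes <- character(nrow(regions))
  large <- logical(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    lo <- regions$start[i] - margin_bp
    hi <- regions$end[i] + margin_bp
    hit <- genes$contig_id == regions$contig_id[i] &
      genes$start < hi & genes$end > lo
    f <- genes[hit, , drop = FALSE]
    dist <- pmax(0, pmax(regions$start[i] - f$end, f$start - regions$end[i]))
    feats[[i]] <- tibble::tibble(gene_id = f$gene_id, class = f$marker_class,
                                 distance_bp = dist)
    n_features[i] <- nrow(f)
    classes[i] <- paste(sort(unique(f$marker_class)), collapse = ",")
    inside <- genes$contig_id == regions$contig_id[i] &
      genes$start < regions$end[i] & genes$end > regions$start[i]
    large[i] <- !any(inside) && (regions$end[i] - regions$start[i]) > 1000
  }
  regions$n_features <- n_features
  regions$classes <- classes
  regions$large_intergenic <- large
  regions$features <- feats
  cls <- unlist(lapply(feats, function(f) unique(f$class)))
  attr(regions, "class_counts") <-
    if (length(cls)) sort(table(cls), decreasing = TRUE) else table(character())
  regions
}

# one-sample Kolmogorov-Smirnov statistic against Exponential(rate)
ks_stat_exp <- function(x, rate) {
  n <- length(x)
  f <- stats::pexp(sort(x), rate)
  i <- seq_len(n)
  max(max(i / n - f), max(f - (i - 1) / n))
}

#' Random breakage model test for segment lengths
#'
#' Under random (uniform) breakage, the lengths of syntenic segments
#' between breakpoints follow an exponential law f(x) = 1/L exp(-x/L) with
#' L the mean segment length. The test compares the empirical distribution
#' with Exponential(mean = L) by the Kolmogorov-Smirnov statistic and
#' calibrates its p-value by parametric bootstrap (Lilliefors-style: L is
#' re-estimated in every replicate, because it was estimated from the same
#' data being tested).
#'
#' @param segment_lengths numeric vector of segment lengths in bp
#'   (at least 5; fewer makes the test meaningless and is refused).
#' @param bootstrap_reps bootstrap replicates (default 999).
#' @param seed optional integer seed for the bootstrap.
#' @param n_bins histogram bins for the exported Fig-style summary
#'   (default 15).
#' @return object of class `breakage_test`: a list with `L` (mean segment
#'   length), `n_segments`, `statistic` (KS D), `p_value`, `bootstrap_reps`
#'   and `histogram` (tibble `bin_start`, `bin_end`, `count`,
#'   `expected_exponential`).
#' @export
random_breakage_test <- function(segment_lengths, bootstrap_reps = 999,
                                 seed = NULL, n_bins = 15) {
  x <- as.numeric(segment_lengths)
  if (length(x) < 5) {
    abort_bad_arg("need at least 5 segment lengths for the breakage test")
  }
  if (any(x <= 0)) abort_bad_arg("segment lengths must be positive")
  L <- mean(x)
  n <- length(x)
  d_obs <- ks_stat_exp(x, 1 / L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  d_boot <- vapply(seq_len(bootstrap_reps), function(r) {
    y <- stats::rexp(n, 1 / L)
    ks_stat_exp(y, 1 / mean(y))
  }, 0)
  p <- (1 + sum(d_boot >= d_obs)) / (bootstrap_reps + 1)
  breaks <- seq(0, max(x) * 1.0001, length.out = n_bins + 1)
  counts <- as.integer(table(cut(x, breaks, include.lowest = TRUE)))
  expected <- n * (stats::pexp(breaks[-1], 1 / L) -
                     stats::pexp(breaks[-length(breaks)], 1 / L))
  structure(list(L = L, n_segments = n, statistic = d_obs, p_value = p,
                 bootstrap_reps = bootstrap_reps,
                 histogram = tibble::tibble(
                   bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
                   count = counts, expected_exponential = expected)),
            class = "breakage_test")
}

#' @export
print.breakage_test <- function(x, ...) {
  cat("Random breakage model test\n")
  cat(sprintf("  n = %d segments, mean length L = %.1f\n", x$n_segments, x$L))
  cat(sprintf("  KS D = %.4f, bootstrap p = %.4g (%d replicates)\n",
              x$statistic, x$p_value, x$bootstrap_reps))
  invisible(x)
}

#' @rdname random_breakage_test
#' @param x a `breakage_test`.
#' @param ... unused.
#' @return `tidy()`: the histogram tibble; `glance()`: a one-row summary.
#' @export
tidy.breakage_test <- function(x, ...) x$histogram

#' @rdname random_breakage_test
#' @export
glance.breakage_test <- function(x, ...) {
  tibble::tibble(L = x$L, n_segments = x$n_segments,
                 statistic = x$statistic, p_value = x$p_value,
                 bootstrap_reps = x$bootstrap_reps)
}

#' @rdname random_breakage_test
#' @param object a `breakage_test`.
#' @export
autoplot.breakage_test <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h) +
    ggplot2::geom_col(ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                                   y = .data$count),
                      fill = "grey70", width = h$bin_end[1] - h$bin_start[1]) +
    ggplot2::geom_line(ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                                    y = .data$expected_exponential),
                       linetype = "dashed", colour = "#b2182b") +
    ggplot2::labs(x = "segment length (bp)", y = "count",
                  subtitle = sprintf("KS D = %.3f, bootstrap p = %.3g",
                                     object$statistic, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Write breakpoint and histogram tables
#'
#' @param regions annotated breakpoint tibble.
#' @param path TSV output path.
#' @return input, invisibly.
#' @export
write_breakpoint_table <- function(regions, path) {
  readr::write_tsv(dplyr::select(regions, -dplyr::any_of("features")), path)
  invisible(regions)
}
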