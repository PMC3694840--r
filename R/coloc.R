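# Peak-to-hotspot colocalization statistics: nearest-edge distances,
# cumulative distance curves, 600 bp matching, a seeded random-placement
# Monte-Carlo null with percentile envelopes, and Fisher's exact test.

# distance from each position to the nearest block edge on one chromosome.
# Edge convention: the distance of a peak to a block is the distance to the
# nearer of its two edges (start and end-1) even when the peak lies inside
# the block. With inside_zero = TRUE positions inside a block get 0 instead
# (interval distance; sensitivity variant).
.nearest_edge_dist <- function(pos, starts, ends, inside_zero = FALSE) {
  if (!length(starts)) return(rep(Inf, length(pos)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  edges <- sort(c(starts, ends - 1))
  i <- findInterval(pos, edges)
  dl <- ifelse(i >= 1L, pos - edges[pmax(i, 1L)], Inf)
  dr <- ifelse(i < length(edges), edges[pmin(i + 1L, length(edges))] - pos, Inf)
  d <- pmin(dl, dr)
  if (inside_zero) {
    j <- findInterval(pos, starts)
    inside <- j >= 1L & pos <= ends[pmax(j, 1L)] - 1
    d[inside] <- 0
  }
  d
}

#' Distance from each peak to the nearest hotspot-block edge
#'
#' For each peak, the minimum over all same-chromosome blocks of the distance
#' to the nearer block edge — even when the peak maps inside the block, its
#' distance is to the nearer edge, not zero. Peaks on a chromosome without
#' blocks get `Inf`.
#'
#' @param peaks Tibble with columns `chrom`, `pos`.
#' @param blocks Hotspot block tibble.
#' @param inside_is_zero If `TRUE`, peaks inside a block get distance 0
#'   (plain interval distance) instead of the nearest-edge rule; exposed for
#'   sensitivity analysis and ground-truth recovery checks.
#' @return The `peaks` tibble with an added `distance` column (bp).
#' @export
distance_to_nearest_block <- function(peaks, blocks, inside_is_zero = FALSE) {
  stopifnot(all(c("chrom", "pos") %in% names(peaks)))
  d <- rep(Inf, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    bi <- which(blocks$chrom == ch)
    d[pi] <- .nearest_edge_dist(peaks$pos[pi], blocks$start[bi],
                                blocks$end[bi], inside_is_zero)
  }
  peaks$distance <- d
  peaks
}

#' Cumulative distance curve
#'
#' `curve(d)` = fraction of peaks whose distance to the nearest block edge is
#' at most `d`, evaluated on a distance grid; the cumulative fraction plotted
#' against distance-to-nearest-hotspot in the classical colocalization
#' figures.
#'
#' @inheritParams distance_to_nearest_block
#' @param grid Ascending distances (bp) at which to evaluate the curve
#'   (default 0 to 5000 in steps of 100).
#' @return A tibble with columns `distance` and `fraction` (nondecreasing,
#'   in \[0, 1\]).
#' @export
cumulative_distance_curve <- function(peaks, blocks, grid = seq(0, 5000, 100),
                                      inside_is_zero = FALSE) {
  if (nrow(peaks) == 0L) abort("cannot compute a distance curve for 0 peaks")
  stopifnot(!is.unsorted(grid))
  d <- distance_to_nearest_block(peaks, blocks, inside_is_zero)$distance
  tibble(distance = grid,
         fraction = vapply(grid, function(g) mean(d <= g), numeric(1)))
}

#' Fraction of peaks matched to a hotspot block
#'
#' A peak is matched when its distance to the nearest block edge is at most
#' `match_distance` (600 bp by default).
#'
#' @inheritParams distance_to_nearest_block
#' @param match_distance Matching distance, bp (default 600).
#' @return A one-row tibble: `n`, `matched`, `unmatched`, `fraction`.
#' @export
matched_fraction <- function(peaks, blocks, match_distance = 600,
                             inside_is_zero = FALSE) {
  if (nrow(peaks) == 0L) abort("cannot compute a matched fraction for 0 peaks")
  d <- distance_to_nearest_block(peaks, blocks, inside_is_zero)$distance
  m <- sum(d <= match_distance)
  tibble(n = length(d), matched = m, unmatched = length(d) - m,
         fraction = m / length(d))
}

#' Random-placement null model
#'
#' Repeatedly places `n_peaks` positions uniformly at random over the genome
#' (chromosome chosen proportional to its length, position uniform, integer
#' bp) and maps them to the hotspot blocks exactly the way the experimental
#' peaks are mapped. Returns the mean matched fraction over repetitions and
#' pointwise percentile envelopes of the repetition cumulative curves.
#'
#' @param n_peaks Number of random positions per repetition.
#' @param blocks Hotspot block tibble.
#' @param genome Genome tibble.
#' @param match_distance Matching distance, bp (default 600).
#' @param grid Distance grid for the envelope curves.
#' @param repetitions Number of repetitions (default 100).
#' @param percentiles Lower/upper envelope percentiles (default `c(2, 98)`).
#' @param seed Integer seed.
#' @inheritParams distance_to_nearest_block
#' @return A list of class `coloc_null`: `mean_fraction`, `fractions`
#'   (per repetition), and `envelope` — a tibble with columns `distance`,
#'   `lower`, `mean`, `upper`.
#' @export
random_null <- function(n_peaks, blocks, genome, match_distance = 600,
                        grid = seq(0, 5000, 100), repetitions = 100,
                        percentiles = c(2, 98), seed = 1,
                        inside_is_zero = FALSE) {
  validate_genome(genome)
  stopifnot(n_peaks >= 1, repetitions >= 1, length(percentiles) == 2L,
            percentiles[1] >= 0, percentiles[1] < percentiles[2],
            percentiles[2] <= 100)
  lens <- as.numeric(genome$length)
  blocks_by <- split(blocks[c("start", "end")], blocks$chrom)

  dist_one_rep <- function() {
    ci <- sample.int(nrow(genome), n_peaks, replace = TRUE, prob = lens)
    pos <- floor(runif(n_peaks) * lens[ci])
    d <- rep(Inf, n_peaks)
    for (ch in unique(genome$chrom[ci])) {
      pi <- which(genome$chrom[ci] == ch)
      b <- blocks_by[[ch]]
      d[pi] <- if (is.null(b)) Inf else
        .nearest_edge_dist(pos[pi], b$start, b$end, inside_is_zero)
    }
    d
  }

  withr::with_seed(seed, {
    fractions <- numeric(repetitions)
    curves <- matrix(0, nrow = repetitions, ncol = length(grid))
    for (r in seq_len(repetitions)) {
      d <- dist_one_rep()
      fractions[r] <- mean(d <= match_distance)
      curves[r, ] <- vapply(grid, function(g) mean(d <= g), numeric(1))
    }
    structure(list(
      mean_fraction = mean(fractions),
      fractions = fractions,
      envelope = tibble(
        distance = grid,
        lower = apply(curves, 2, quantile, probs = percentiles[1] / 100,
                      type = 7, names = FALSE),
        mean = colMeans(curves),
        upper = apply(curves, 2, quantile, probs = percentiles[2] / 100,
                      type = 7, names = FALSE)
      ),
      n_peaks = n_peaks, repetitions = repetitions,
      match_distance = match_distance, percentiles = percentiles,
      seed = seed
    ), class = "coloc_null")
  })
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value: over the hypergeometric distribution fixed by the
#' table margins, the probabilities of all tables at most as probable as the
#' observed one (with a 1e-7 relative tolerance for ties) are summed.
#' Delegates to `stats::fisher.test()`.
#'
#' @param table A 2x2 matrix of nonnegative counts, or a vector of four
#'   counts `(matched_a, unmatched_a, matched_b, unmatched_b)` filled
#'   column-wise.
#' @return The two-sided p-value in (0, 1\].
#' @examples
#' fisher_exact(c(5, 5, 5, 5))   # 1
#' fisher_exact(c(3, 1, 1, 3))   # 34/70
#' @export
fisher_exact <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, nrow = 2)
  if (!identical(dim(table), c(2L, 2L))) abort("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be nonnegative integers")
  }
  if (sum(table) == 0) abort("table has no observations")
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Compare the strongest peaks with the strongest hotspot blocks
#'
#' Implements the top-N colocalization comparison: the blocks are sorted by
#' heat and the peaks by height, the top `n_blocks` and `n_peaks` of each
#' list are selected, the nearest-edge distance of every selected peak is
#' computed, and the observed matched fraction and cumulative curve are
#' compared against the random-placement null (same `n_peaks`, same mapping).
#' Significance is a two-sided Fisher's exact test of the observed
#' matched/unmatched counts against the null-expected counts (mean null
#' fraction scaled to `n_peaks` and rounded to integers).
#'
#' @param peaks Peak tibble from [call_peaks()].
#' @param blocks Hotspot block tibble.
#' @param genome Genome tibble (needed for the random null).
#' @param n_peaks,n_blocks How many of the strongest peaks/blocks to compare
#'   (default 500 each). If fewer are available, all are used with a warning.
#' @inheritParams random_null
#' @return An object of class `coloc_result`; see [tidy.coloc_result()],
#'   [glance.coloc_result()] and [autoplot.coloc_result()].
#' @export
compare_top_n <- function(peaks, blocks, genome, n_peaks = 500, n_blocks = 500,
                          match_distance = 600, grid = seq(0, 5000, 100),
                          repetitions = 100, percentiles = c(2, 98), seed = 1,
                          inside_is_zero = FALSE) {
  if (nrow(peaks) < n_peaks) {
    warn(sprintf("only %d peaks available (requested %d); using all",
                 nrow(peaks), n_peaks))
    n_peaks <- nrow(peaks)
  }
  if (nrow(blocks) < n_blocks) {
    warn(sprintf("only %d blocks available (requested %d); using all",
                 nrow(blocks), n_blocks))
    n_blocks <- nrow(blocks)
  }
  if (n_peaks < 1L) abort("no peaks to compare")
  top_peaks <- top_n_peaks(peaks, n_peaks)
  ob <- blocks[order(-blocks$heat, match(blocks$chrom, unique(blocks$chrom)),
                     blocks$start), ]
  top_blocks <- head(ob, n_blocks)

  dists <- distance_to_nearest_block(top_peaks, top_blocks, inside_is_zero)
  curve <- cumulative_distance_curve(top_peaks, top_blocks, grid,
                                     inside_is_zero)
  mf <- matched_fraction(top_peaks, top_blocks, match_distance,
                         inside_is_zero)
  null <- random_null(n_peaks, top_blocks, genome, match_distance, grid,
                      repetitions, percentiles, seed, inside_is_zero)
  exp_matched <- as.integer(round(null$mean_fraction * n_peaks))
  tab <- matrix(c(mf$matched, mf$unmatched,
                  exp_matched, n_peaks - exp_matched), nrow = 2)
  p <- fisher_exact(tab)

  structure(list(
    peaks = dists, blocks = top_blocks, curve = curve, matched = mf,
    null = null, fisher_p = p,
    config = list(n_peaks = n_peaks, n_blocks = n_blocks,
                  match_distance = match_distance, repetitions = repetitions,
                  percentiles = percentiles, seed = seed,
                  inside_is_zero = inside_is_zero)
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "# colocalization: top %d peaks vs top %d blocks at %g bp\n",
    cfg$n_peaks, cfg$n_blocks, cfg$match_distance))
  cat(sprintf("#   matched: %d/%d (%.1f%%); null mean %.1f%%; Fisher p = %.3g\n",
              x$matched$matched, x$matched$n, 100 * x$matched$fraction,
              100 * x$null$mean_fraction, x$fisher_p))
  invisible(x)
}

#' Tidy a colocalization result
#'
#' @param x A `coloc_result` from [compare_top_n()].
#' @param ... Unused.
#' @return A tibble with one row per grid distance: `distance`, `fraction`
#'   (observed cumulative), `null_lower`, `null_mean`, `null_upper`.
#' @method tidy coloc_result
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(distance = x$curve$distance,
         fraction = x$curve$fraction,
         null_lower = x$null$envelope$lower,
         null_mean = x$null$envelope$mean,
         null_upper = x$null$envelope$upper)
}

#' One-row summary of a colocalization result
#'
#' @inheritParams tidy.coloc_result
#' @return A one-row tibble: `n_peaks`, `n_blocks`, `match_distance`,
#'   `matched`, `unmatched`, `fraction`, `null_fraction`, `p_value`.
#' @method glance coloc_result
#' @export
glance.coloc_result <- function(x, ...) {
  tibble(n_peaks = x$config$n_peaks, n_blocks = x$config$n_blocks,
         match_distance = x$config$match_distance,
         matched = x$matched$matched, unmatched = x$matched$unmatched,
         fraction = x$matched$fraction,
         null_fraction = x$null$mean_fraction,
         p_value = x$fisher_p)
}

#' Label axis sites by a ratio threshold
#'
#' Binary axis-domain classification: a site is labelled 1 when the ratio
#' profile value at the probe nearest the site strictly exceeds `threshold`
#' (default 0.5), and 0 otherwise. Applied to an 8D/8A ratio profile at axis
#' sites, runs of 1s and 0s delineate hot and cold DSB domains.
#'
#' @param profile A ratio `tiling_profile`.
#' @param sites Tibble of axis sites with columns `chrom`, `pos`.
#' @param threshold Strict threshold (default 0.5); a ratio exactly equal to
#'   the threshold is labelled 0.
#' @param genome Optional genome tibble for bounds checking (defaults to the
#'   genome recorded on the profile, if any).
#' @return The `sites` tibble with added columns `ratio` and `label` (0/1).
#' @export
classify_axis_domains <- function(profile, sites, threshold = 0.5,
                                  genome = NULL) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  genome <- genome %||% attr(profile, "genome")
  ratio <- numeric(nrow(sites))
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    pi <- which(profile$chrom == ch)
    if (!length(pi)) {
      abort(paste0("profile has no probes on chromosome '", ch, "'"))
    }
    if (!is.null(genome)) {
      L <- genome$length[match(ch, genome$chrom)]
      if (is.na(L)) abort(paste0("unknown chromosome '", ch, "'"))
      if (any(sites$pos[si] < 0 | sites$pos[si] >= L)) {
        abort(paste0("axis site beyond the end of ", ch))
      }
    }
    pp <- profile$pos[pi]
    i <- findInterval(sites$pos[si], pp, all.inside = TRUE)
    left <- pp[i]; right <- pp[pmin(i + 1L, length(pp))]
    nearest <- ifelse(sites$pos[si] - left <= right - sites$pos[si],
                      i, pmin(i + 1L, length(pp)))
    ratio[si] <- profile$value[pi][nearest]
  }
  sites$ratio <- ratio
  sites$label <- as.integer(ratio > threshold)
  sites
}
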