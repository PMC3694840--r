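# Shared fixtures and small independent oracles, all built in code.

toy_genome <- function() make_genome("toy")

one_chrom_genome <- function(len = 100000) make_genome(c(chr1 = len))

# a hand-made block table
blocks_tbl <- function(chrom, start, end, heat = NULL, genome = NULL) {
  b <- tibble::tibble(chrom = chrom, start = start, end = end,
                      name = sprintf("hs%04d", seq_along(start)),
                      heat = heat %||% rep(1, length(start)))
  b[, c("chrom", "start", "end", "name", "heat")]
}

# profile value at the probe nearest each query position (independent of
# classify_axis_domains)
value_at <- function(profile, chrom, pos) {
  v <- numeric(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pi <- which(profile$chrom == ch)
    pp <- profile$pos[pi]
    k <- findInterval(pos[i], pp, all.inside = TRUE)
    k2 <- pmin(k + 1L, length(pp))
    nearest <- ifelse(pos[i] - pp[k] <= pp[k2] - pos[i], k, k2)
    v[i] <- profile$value[pi][nearest]
  }
  v
}

# brute-force nearest-edge distance: loop over every block
oracle_edge_distance <- function(chrom, pos, blocks, inside_zero = FALSE) {
  vapply(seq_along(pos), function(i) {
    bi <- which(blocks$chrom == chrom[i])
    if (!length(bi)) return(Inf)
    d <- Inf
    for (j in bi) {
      s <- blocks$start[j]; e <- blocks$end[j] - 1
      dj <- min(abs(pos[i] - s), abs(pos[i] - e))
      if (inside_zero && pos[i] >= s && pos[i] <= e) dj <- 0
      d <- min(d, dj)
    }
    d
  }, numeric(1))
}

# exhaustive two-sided Fisher p by hypergeometric enumeration over all
# tables with the observed margins (choose() arithmetic only)
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c) / choose(n, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small smoothed+normalized profile constructed directly (for ops that
# require the processing flags)
flagged_profile <- function(chrom, pos, value, label = "p", bandwidth = 500) {
  tiling_profile(tibble::tibble(chrom = chrom, pos = pos, value = value),
                 label = label, smoothed = TRUE, bandwidth = bandwidth,
                 normalized = TRUE, norm_factor = 1)
}

`%||%` <- rlang::`%||%`
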