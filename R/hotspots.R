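#' Configuration for the synthetic hotspot-block generator
#'
#' Widths are lognormal. The defaults (`width_log_mu = log(180)`,
#' `width_log_sigma = 0.82`) are calibrated so the analytic median, mean and
#' 0.9 quantile of the width distribution reproduce the summary statistics of
#' the published 3600-block DSB hotspot map (median 180 bp, mean
#' 180 * exp(0.82^2 / 2) ~ 252 bp, 0.9 quantile 180 * exp(1.2816 * 0.82)
#' ~ 514 bp). Heats (per-block mapped 5'-end counts) are lognormal and coupled
#' to widths through a Gaussian copula with rank correlation driven by
#' `heat_width_correlation`, so the strongest blocks are wider than average.
#'
#' @param n_blocks Number of blocks to place (default 3600).
#' @param width_log_mu,width_log_sigma Lognormal parameters of block width (bp).
#' @param heat_log_mu,heat_log_sigma Lognormal parameters of block heat
#'   (arbitrary count scale; only relative heats matter downstream).
#' @param heat_width_correlation Gaussian-copula correlation between width and
#'   heat, in \[0, 1\] (default 0.5).
#' @param min_gap Minimum gap in bp enforced between placed blocks (default 500).
#' @param seed Integer seed; every stochastic operation in the package is
#'   explicitly seeded.
#' @return A list of class `hotspot_config`.
#' @export
hotspot_config <- function(n_blocks = 3600,
                           width_log_mu = log(180),
                           width_log_sigma = 0.82,
                           heat_log_mu = log(50),
                           heat_log_sigma = 1.0,
                           heat_width_correlation = 0.5,
                           min_gap = 500,
                           seed = 1) {
  stopifnot(n_blocks >= 0, width_log_sigma >= 0, heat_log_sigma >= 0,
            heat_width_correlation >= 0, heat_width_correlation <= 1,
            min_gap >= 0)
  structure(list(
    n_blocks = as.integer(n_blocks),
    width_log_mu = width_log_mu,
    width_log_sigma = width_log_sigma,
    heat_log_mu = heat_log_mu,
    heat_log_sigma = heat_log_sigma,
    heat_width_correlation = heat_width_correlation,
    min_gap = as.integer(min_gap),
    seed = as.integer(seed)
  ), class = "hotspot_config")
}

#' Generate synthetic DSB hotspot blocks
#'
#' Draws `n_blocks` block widths and heats from the configured (coupled)
#' lognormal model and places the blocks on the genome: block centers are
#' uniform over the genome (chromosome chosen proportional to its length),
#' and a draw whose block would extend past a chromosome end or come within
#' `min_gap` bp of an already placed block is rejected and resampled. If the
#' genome cannot accommodate all blocks a shorter list is returned with a
#' warning.
#'
#' @param genome A genome tibble from [make_genome()].
#' @param config A [hotspot_config()].
#' @param max_attempts Placement attempts per block before giving up.
#' @return A tibble of blocks with columns `chrom`, `start`, `end`
#'   (0-based half-open), `name`, `heat`, sorted by chromosome and start.
#' @examples
#' g <- make_genome("toy")
#' generate_hotspots(g, hotspot_config(n_blocks = 50, seed = 7))
#' @export
generate_hotspots <- function(genome, config = hotspot_config(),
                              max_attempts = 200L) {
  validate_genome(genome)
  n <- config$n_blocks
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), heat = numeric())
  if (n == 0L) return(empty)

  rho <- config$heat_width_correlation
  lens <- as.numeric(genome$length)
  nchrom <- nrow(genome)

  placed <- withr::with_seed(config$seed, {
    z_w <- rnorm(n)
    z_h <- rho * z_w + sqrt(1 - rho^2) * rnorm(n)
    widths <- pmax(1L, as.integer(round(exp(
      config$width_log_mu + config$width_log_sigma * z_w))))
    heats <- exp(config$heat_log_mu + config$heat_log_sigma * z_h)

    starts_by <- rep(list(integer(0)), nchrom)
    ends_by <- rep(list(integer(0)), nchrom)
    out_chrom <- integer(n); out_start <- integer(n); out_end <- integer(n)
    out_heat <- numeric(n); k <- 0L

    for (i in seq_len(n)) {
      w <- widths[i]
      for (a in seq_len(max_attempts)) {
        ci <- sample.int(nchrom, 1L, prob = lens)
        center <- sample.int(genome$length[ci], 1L) - 1L
        start <- center - w %/% 2L
        end <- start + w
        if (start < 0L || end > genome$length[ci]) next
        s <- starts_by[[ci]]; e <- ends_by[[ci]]
        if (length(s) && any(start < e + config$min_gap &
                             end > s - config$min_gap)) next
        starts_by[[ci]] <- c(s, start)
        ends_by[[ci]] <- c(e, end)
        k <- k + 1L
        out_chrom[k] <- ci; out_start[k] <- start
        out_end[k] <- end; out_heat[k] <- heats[i]
        break
      }
    }
    list(chrom = out_chrom[seq_len(k)], start = out_start[seq_len(k)],
         end = out_end[seq_len(k)], heat = out_heat[seq_len(k)])
  })

  if (length(placed$chrom) < n) {
    warn(paste0("placed only ", length(placed$chrom), " of ", n,
                " blocks; genome too small for the requested density"))
  }
  blocks <- tibble(
    chrom = genome$chrom[placed$chrom],
    start = placed$start,
    end = placed$end,
    heat = placed$heat
  )
  blocks <- blocks[order(match(blocks$chrom, genome$chrom), blocks$start), ]
  blocks$name <- sprintf("hs%04d", seq_len(nrow(blocks)))
  blocks[, c("chrom", "start", "end", "name", "heat")]
}

validate_blocks <- function(blocks, genome = NULL) {
  need <- c("chrom", "start", "end", "heat")
  if (!is.data.frame(blocks) || !all(need %in% names(blocks))) {
    abort("blocks must have columns chrom, start, end, heat")
  }
  bad <- which(blocks$end <= blocks$start | blocks$start < 0)
  if (length(bad)) {
    abort(paste0("invalid block interval at row ", bad[1],
                 " (need 0 <= start < end)"))
  }
  if (any(blocks$heat <= 0)) abort("block heats must be > 0")
  if (!is.null(genome)) {
    validate_genome(genome)
    m <- match(blocks$chrom, genome$chrom)
    if (anyNA(m)) {
      abort(paste0("unknown chromosome '", blocks$chrom[which(is.na(m))[1]],
                   "' in blocks"))
    }
    over <- which(blocks$end > genome$length[m])
    if (length(over)) {
      abort(paste0("block at row ", over[1], " extends past the end of ",
                   blocks$chrom[over[1]]))
    }
  }
  invisible(blocks)
}

#' Read / write hotspot blocks as BED5
#'
#' Columns: chrom, start, end, name, score (= heat). Coordinates are 0-based,
#' half-open. Reading validates every record and reports the offending line
#' number on failure; a write/read round trip is the identity.
#'
#' @param path File path.
#' @param genome Optional genome tibble; if supplied, chromosome names and
#'   bounds are checked.
#' @return `read_blocks_bed()` returns a block tibble
#'   (`chrom`, `start`, `end`, `name`, `heat`).
#' @export
read_blocks_bed <- function(path, genome = NULL) {
  df <- read.table(path, header = FALSE,
                   col.names = c("chrom", "start", "end", "name", "heat"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "numeric"))
  bad <- which(df$end <= df$start | df$start < 0 | !is.finite(df$heat) |
                 df$heat <= 0)
  if (length(bad)) {
    abort(paste0("malformed BED record at line ", bad[1], " of ", path))
  }
  if (!is.null(genome)) {
    validate_genome(genome)
    m <- match(df$chrom, genome$chrom)
    if (anyNA(m)) {
      ln <- which(is.na(m))[1]
      abort(paste0("unknown chromosome '", df$chrom[ln], "' at line ", ln,
                   " of ", path))
    }
    over <- which(df$end > genome$length[m])
    if (length(over)) {
      abort(paste0("interval past chromosome end at line ", over[1],
                   " of ", path))
    }
  }
  as_tibble(df)
}

#' @rdname read_blocks_bed
#' @param blocks A block tibble.
#' @export
write_blocks_bed <- function(blocks, path) {
  validate_blocks(blocks)
  lines <- sprintf("%s\t%d\t%d\t%s\t%.17g", blocks$chrom,
                   as.integer(blocks$start), as.integer(blocks$end),
                   blocks$name, blocks$heat)
  writeLines(lines, path)
  invisible(path)
}
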