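#' Call peaks on a smoothed, normalized tiling profile
#'
#' A probe is a peak candidate if its value is the strict maximum among all
#' probes within +/-`local_window` bp and is at least `min_height`.
#' Candidates closer than `min_separation` bp are then merged, keeping the
#' higher one (ties: leftmost). Peak strength is the apex height; the output
#' is sorted by height (descending) with 1-based ranks, ties broken by
#' chromosome order and then leftmost position, so results are fully
#' deterministic.
#'
#' @param profile A smoothed, decile-normalized `tiling_profile` (peak
#'   calling on raw probe noise is rejected).
#' @param min_separation Minimum distance between reported peaks, bp
#'   (default 1000).
#' @param min_height Minimum apex height on the normalized scale
#'   (default 1.1).
#' @param local_window Half-width of the strict-maximum window, bp; defaults
#'   to the profile's smoothing bandwidth.
#' @return A tibble with columns `chrom`, `pos`, `height`, `rank`, sorted by
#'   rank.
#' @export
call_peaks <- function(profile, min_separation = 1000, min_height = 1.1,
                       local_window = NULL) {
  if (!isTRUE(attr(profile, "smoothed"))) {
    abort("peak calling requires a smoothed profile")
  }
  if (!isTRUE(attr(profile, "normalized"))) {
    abort("peak calling requires a decile-normalized (or ratio) profile")
  }
  local_window <- local_window %||% attr(profile, "bandwidth")
  if (is.null(local_window) || !is.finite(local_window)) {
    abort("local_window not given and no bandwidth recorded on the profile")
  }
  stopifnot(min_separation >= 0, min_height > 0, local_window >= 0)

  chrom_levels <- unique(profile$chrom)
  cand <- list()
  for (ch in chrom_levels) {
    idx <- which(profile$chrom == ch)
    pos <- profile$pos[idx]; v <- profile$value[idx]
    keep <- .strict_local_max(pos, v, local_window) & v >= min_height
    if (any(keep)) {
      cand[[ch]] <- tibble(chrom = ch, pos = pos[keep], height = v[keep])
    }
  }
  if (!length(cand)) {
    return(tibble(chrom = character(), pos = numeric(),
                  height = numeric(), rank = integer()))
  }
  cand <- dplyr::bind_rows(cand)

  # greedy merge: visit by descending height (ties leftmost), keep a
  # candidate only if no stronger kept peak lies within min_separation
  ord <- order(-cand$height, match(cand$chrom, chrom_levels), cand$pos)
  kept_pos <- split(numeric(0), character(0))
  keep_idx <- integer(0)
  for (i in ord) {
    ch <- cand$chrom[i]; p <- cand$pos[i]
    kp <- kept_pos[[ch]]
    if (is.null(kp) || !length(kp) || all(abs(kp - p) >= min_separation)) {
      kept_pos[[ch]] <- c(kp, p)
      keep_idx <- c(keep_idx, i)
    }
  }
  out <- cand[keep_idx, ]
  out$rank <- seq_len(nrow(out))
  out
}

# strict local maximum within +/- window bp (positions sorted ascending)
.strict_local_max <- function(pos, v, window) {
  n <- length(v)
  if (n == 0L) return(logical(0))
  if (n == 1L) return(TRUE)
  d <- diff(pos)
  out <- rep(TRUE, n)
  if (all(abs(d - d[1]) < 1e-9)) {
    m <- floor(window / d[1])
    for (k in seq_len(max(m, 0))) {
      if (k >= n) break
      i <- (k + 1L):n
      out[i] <- out[i] & (v[i] > v[i - k])        # left neighbours
      j <- 1L:(n - k)
      out[j] <- out[j] & (v[j] > v[j + k])        # right neighbours
    }
  } else {
    lo <- findInterval(pos - window, pos) + 1L
    hi <- findInterval(pos + window, pos)
    for (i in seq_len(n)) {
      nb <- setdiff(lo[i]:hi[i], i)
      out[i] <- !length(nb) || all(v[i] > v[nb])
    }
  }
  out
}

#' Keep the top n peaks by rank
#'
#' @param peaks A peak tibble from [call_peaks()].
#' @param n Number of peaks to keep (`n >= 0`); if `n` exceeds the number of
#'   peaks, all are returned.
#' @return The first `min(n, nrow(peaks))` peaks by rank (stable).
#' @export
top_n_peaks <- function(peaks, n) {
  stopifnot(n >= 0)
  peaks <- peaks[order(peaks$rank), ]
  head(peaks, n)
}

#' Write peaks as BED5
#'
#' One record per peak: chrom, pos, pos + 1, `"peak_rank<N>"`, height.
#'
#' @param peaks A peak tibble.
#' @param path File path.
#' @export
write_peaks_bed <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\tpeak_rank%d\t%.17g",
                   peaks$chrom, as.integer(peaks$pos),
                   as.integer(peaks$pos) + 1L, peaks$rank, peaks$height)
  writeLines(lines, path)
  invisible(path)
}
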