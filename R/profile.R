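# A tiling profile is a tibble (chrom, pos, value) carrying processing
# metadata in attributes: label, smoothed flag + bandwidth, normalized flag +
# last applied correction factor, probe spacing, and (optionally) the parent
# genome for bounds checking.

PROFILE_ATTRS <- c("label", "smoothed", "bandwidth", "normalized",
                   "norm_factor", "spacing", "genome")

#' Construct a tiling profile
#'
#' @param df Data frame with columns `chrom` (character), `pos` (bp, 0-based
#'   probe position) and `value` (positive intensity, e.g. ChIP/WCE ratio).
#' @param label Free-text label (allele, antibody, or ratio name).
#' @param genome Optional genome tibble; probe positions are validated
#'   against it and it is carried along for downstream checks.
#' @param smoothed,bandwidth,normalized,norm_factor Processing metadata;
#'   normally left at their defaults and set by [smooth_profile()] and
#'   [decile_normalize()].
#' @param spacing Probe spacing in bp (inferred from the positions if omitted).
#' @return A `tiling_profile` (a tibble subclass).
#' @export
tiling_profile <- function(df, label = "profile", genome = NULL,
                           smoothed = FALSE, bandwidth = NA_real_,
                           normalized = FALSE, norm_factor = NA_real_,
                           spacing = NULL) {
  if (!all(c("chrom", "pos", "value") %in% names(df))) {
    abort("a tiling profile needs columns chrom, pos, value")
  }
  out <- tibble(chrom = as.character(df$chrom),
                pos = as.numeric(df$pos),
                value = as.numeric(df$value))
  for (ch in unique(out$chrom)) {
    p <- out$pos[out$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      abort(paste0("probe positions on ", ch,
                   " must be strictly increasing"))
    }
  }
  if (any(!is.finite(out$value) | out$value <= 0)) {
    abort("profile intensities must be finite and > 0")
  }
  if (!is.null(genome)) {
    validate_genome(genome)
    m <- match(out$chrom, genome$chrom)
    if (anyNA(m)) {
      abort(paste0("unknown chromosome '", out$chrom[which(is.na(m))[1]],
                   "' in profile"))
    }
    if (any(out$pos < 0 | out$pos >= genome$length[m])) {
      abort("probe position outside chromosome bounds")
    }
  }
  if (is.null(spacing)) {
    d <- unlist(lapply(split(out$pos, out$chrom), diff), use.names = FALSE)
    spacing <- if (length(d)) min(d) else NA_real_
  }
  structure(out,
            class = c("tiling_profile", class(out)),
            label = label, smoothed = smoothed, bandwidth = bandwidth,
            normalized = normalized, norm_factor = norm_factor,
            spacing = spacing, genome = genome)
}

#' Profile processing metadata
#'
#' @param profile A `tiling_profile`.
#' @return A list with elements `label`, `smoothed`, `bandwidth`,
#'   `normalized`, `norm_factor`, `spacing`.
#' @export
profile_meta <- function(profile) {
  out <- lapply(setNames(PROFILE_ATTRS, PROFILE_ATTRS),
                function(a) attr(profile, a, exact = TRUE))
  out$genome <- NULL
  out
}

# rebuild a profile with the same metadata but new values / overridden attrs
.with_profile_attrs <- function(df, template, ...) {
  over <- list(...)
  args <- lapply(setNames(PROFILE_ATTRS, PROFILE_ATTRS),
                 function(a) attr(template, a, exact = TRUE))
  args[names(over)] <- over
  tiling_profile(df, label = args$label, genome = args$genome,
                 smoothed = args$smoothed, bandwidth = args$bandwidth,
                 normalized = args$normalized, norm_factor = args$norm_factor,
                 spacing = args$spacing)
}

#' @export
print.tiling_profile <- function(x, ...) {
  m <- profile_meta(x)
  cat(sprintf(
    "# tiling profile '%s': %d probes on %d chromosome(s)\n",
    m$label, nrow(x), length(unique(x$chrom))))
  cat(sprintf("# smoothed: %s%s; normalized: %s%s\n",
              m$smoothed,
              if (isTRUE(m$smoothed)) sprintf(" (bandwidth %g bp)", m$bandwidth) else "",
              m$normalized,
              if (isTRUE(m$normalized)) sprintf(" (F = %.6g)", m$norm_factor) else ""))
  NextMethod()
}

# Gaussian kernel sd for a given bandwidth: kernel quartiles at
# +/- bandwidth/4, the convention of stats::ksmooth(kernel = "normal"),
# so "bandwidth 500" means the same thing as in the classical tiling
# analyses that used ksmooth.
kernel_sd <- function(bandwidth) 0.25 * bandwidth / qnorm(0.75)

# kernel support radius, in sd units; beyond this the Gaussian weight
# (< 1.3e-14 relative) is dropped
KERNEL_CUTOFF_SD <- 8

#' Smooth a tiling profile
#'
#' Nadaraya-Watson kernel regression with a Gaussian kernel, evaluated at the
#' probe positions, independently per chromosome (no smoothing across
#' chromosome boundaries). The kernel standard deviation is
#' `0.25 * bandwidth / qnorm(0.75)` (~ `0.3706 * bandwidth`), i.e. kernel
#' quartiles at +/- bandwidth/4 — the same bandwidth convention as
#' `stats::ksmooth(kernel = "normal")`. Kernel weights beyond 8 standard
#' deviations (relative weight < 1.3e-14) are dropped.
#'
#' @param profile A `tiling_profile`.
#' @param bandwidth Kernel bandwidth in bp (default 500; bandwidths between
#'   250 and 1000 bp are the documented working range for yeast tiling data).
#' @param allow_resmooth Set `TRUE` to smooth an already smoothed profile.
#' @return The smoothed `tiling_profile` (flagged, bandwidth recorded).
#' @export
smooth_profile <- function(profile, bandwidth = 500, allow_resmooth = FALSE) {
  stopifnot(bandwidth > 0)
  if (isTRUE(attr(profile, "smoothed")) && !allow_resmooth) {
    abort("profile is already smoothed; pass allow_resmooth = TRUE to re-smooth")
  }
  sd <- kernel_sd(bandwidth)
  out_value <- profile$value
  for (ch in unique(profile$chrom)) {
    idx <- which(profile$chrom == ch)
    if (length(idx) == 0L) next
    out_value[idx] <- .smooth_chrom(profile$pos[idx], profile$value[idx], sd)
  }
  df <- tibble(chrom = profile$chrom, pos = profile$pos, value = out_value)
  .with_profile_attrs(df, profile, smoothed = TRUE, bandwidth = bandwidth)
}

.smooth_chrom <- function(pos, y, sd) {
  n <- length(y)
  if (n <= 1L) return(y)
  d <- diff(pos)
  if (all(abs(d - d[1]) < 1e-9)) {
    .smooth_regular(y, d[1], sd)
  } else {
    .smooth_irregular(pos, y, sd)
  }
}

# regularly spaced probes: shift-and-accumulate discrete convolution with
# edge renormalization
.smooth_regular <- function(y, spacing, sd) {
  n <- length(y)
  K <- min(n - 1L, ceiling(KERNEL_CUTOFF_SD * sd / spacing))
  w <- dnorm((-K:K) * spacing, 0, sd)
  num <- numeric(n)
  den <- numeric(n)
  for (j in -K:K) {
    wj <- w[j + K + 1L]
    i <- max(1L, 1L - j):min(n, n - j)
    num[i] <- num[i] + wj * y[i + j]
    den[i] <- den[i] + wj
  }
  num / den
}

.smooth_irregular <- function(pos, y, sd) {
  n <- length(y)
  out <- numeric(n)
  r <- KERNEL_CUTOFF_SD * sd
  lo <- findInterval(pos - r, pos) + 1L
  hi <- findInterval(pos + r, pos)
  for (i in seq_len(n)) {
    j <- lo[i]:hi[i]
    w <- dnorm(pos[j], pos[i], sd)
    out[i] <- sum(w * y[j]) / sum(w)
  }
  out
}

#' Decile-normalize a tiling profile
#'
#' Computes one correction factor per profile, `F = 1 / q`, where `q` is the
#' 0.10 quantile (first decile) of all probe intensities genome-wide
#' (linear-interpolation quantile, `stats::quantile(type = 7)`), and
#' multiplies every intensity by `F`. After normalization the 0.10 quantile
#' equals 1, which superimposes profiles of parallel samples at their shared
#' DSB-unspecific background peaks. For ChIP/WCE profiles whose background
#' sits near 1 the factor is close to 1.
#'
#' @param profile A `tiling_profile` with at least 10 probes.
#' @return The normalized `tiling_profile`; the applied factor is recorded in
#'   the metadata and available as `profile_meta(x)$norm_factor`.
#' @export
decile_normalize <- function(profile) {
  if (nrow(profile) < 10L) {
    abort("decile normalization needs at least 10 probes genome-wide")
  }
  q <- quantile(profile$value, 0.10, type = 7, names = FALSE)
  if (!is.finite(q) || q <= 0) {
    abort("0.10 quantile of the intensities is not positive; cannot normalize")
  }
  f <- 1 / q
  df <- tibble(chrom = profile$chrom, pos = profile$pos,
               value = profile$value * f)
  .with_profile_attrs(df, profile, normalized = TRUE, norm_factor = f)
}

#' Ratio of two tiling profiles
#'
#' Elementwise `numerator / max(denominator, floor)` on identical probe
#' grids. Both inputs must be smoothed and normalized; no implicit
#' resampling is performed. The floor guards against spurious ratio peaks
#' where the denominator approaches zero.
#'
#' @param numerator,denominator Smoothed, normalized `tiling_profile`s on the
#'   same probe grid.
#' @param floor Denominator floor on the normalized intensity scale
#'   (default 0.25).
#' @return A `tiling_profile` labelled `"<num>/<den>"`.
#' @export
ratio_profile <- function(numerator, denominator, floor = 0.25) {
  .check_ratio_ready(numerator, "numerator")
  .check_ratio_ready(denominator, "denominator")
  if (nrow(numerator) != nrow(denominator) ||
      !identical(numerator$chrom, denominator$chrom) ||
      !isTRUE(all.equal(numerator$pos, denominator$pos, tolerance = 0))) {
    abort("numerator and denominator are not on identical probe grids")
  }
  df <- tibble(chrom = numerator$chrom, pos = numerator$pos,
               value = numerator$value / pmax(denominator$value, floor))
  .with_profile_attrs(df, numerator,
                      label = paste0(attr(numerator, "label"), "/",
                                     attr(denominator, "label")),
                      normalized = TRUE, norm_factor = NA_real_)
}

.check_ratio_ready <- function(profile, what) {
  if (!isTRUE(attr(profile, "smoothed"))) {
    abort(paste0(what, " profile must be smoothed before taking ratios"))
  }
  if (!isTRUE(attr(profile, "normalized"))) {
    abort(paste0(what, " profile must be decile-normalized before taking ratios"))
  }
}

#' Invert a tiling profile
#'
#' Returns `1 / max(value, floor)`, the unit profile divided by the input;
#' used to test whether the inverse of an anti-correlated profile recovers a
#' positive correlation with hotspots.
#'
#' @inheritParams ratio_profile
#' @param profile A smoothed, normalized `tiling_profile`.
#' @return A `tiling_profile` labelled `"1/<label>"`.
#' @export
invert_profile <- function(profile, floor = 0.25) {
  .check_ratio_ready(profile, "input")
  df <- tibble(chrom = profile$chrom, pos = profile$pos,
               value = 1 / pmax(profile$value, floor))
  .with_profile_attrs(df, profile,
                      label = paste0("1/", attr(profile, "label")),
                      normalized = TRUE, norm_factor = NA_real_)
}

#' Read / write a tiling profile as bedGraph
#'
#' Four whitespace-separated columns: chrom, start, end, value. Intervals are
#' fixed-width probes; on reading, each interval collapses to a probe at its
#' start. Intervals must be sorted and non-overlapping within each
#' chromosome; violations are reported with their line number. A metadata
#' sidecar `<path>.meta.json` (label, smoothing/normalization state, spacing)
#' is written alongside and picked up again on reading, making a write/read
#' round trip the identity.
#'
#' @param path File path.
#' @param genome Genome tibble used to validate chromosomes and bounds.
#' @param label Label override (defaults to the sidecar's, or the file name).
#' @return `read_bedgraph()` returns a `tiling_profile`.
#' @export
read_bedgraph <- function(path, genome = NULL, label = NULL) {
  df <- read.table(path, header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "numeric", "numeric", "numeric"))
  bad <- which(df$end <= df$start)
  if (length(bad)) {
    abort(paste0("bedGraph interval with end <= start at line ", bad[1],
                 " of ", path))
  }
  for (ch in unique(df$chrom)) {
    idx <- which(df$chrom == ch)
    s <- df$start[idx]; e <- df$end[idx]
    if (is.unsorted(s, strictly = TRUE)) {
      ln <- idx[which(diff(s) <= 0)[1] + 1L]
      abort(paste0("unsorted bedGraph intervals at line ", ln, " of ", path))
    }
    if (length(idx) > 1L && any(e[-length(e)] > s[-1L])) {
      ln <- idx[which(e[-length(e)] > s[-1L])[1] + 1L]
      abort(paste0("overlapping bedGraph intervals at line ", ln, " of ", path))
    }
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
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  tiling_profile(
    tibble(chrom = df$chrom, pos = df$start, value = df$value),
    label = label %||% meta$label %||% basename(path),
    genome = genome,
    smoothed = isTRUE(meta$smoothed),
    bandwidth = meta$bandwidth %||% NA_real_,
    normalized = isTRUE(meta$normalized),
    norm_factor = meta$norm_factor %||% NA_real_,
    spacing = meta$spacing %||% NULL
  )
}

#' @rdname read_bedgraph
#' @param profile A `tiling_profile`.
#' @param write_meta Write the JSON metadata sidecar (default `TRUE`).
#' @export
write_bedgraph <- function(profile, path, write_meta = TRUE) {
  spacing <- attr(profile, "spacing")
  ends <- numeric(nrow(profile))
  for (ch in unique(profile$chrom)) {
    idx <- which(profile$chrom == ch)
    p <- profile$pos[idx]
    step <- if (length(p) > 1L) c(diff(p), min(diff(p))) else
      rep(if (is.finite(spacing %||% NA_real_)) spacing else 1, length(p))
    ends[idx] <- p + step
  }
  lines <- sprintf("%s\t%.17g\t%.17g\t%.17g",
                   profile$chrom, profile$pos, ends, profile$value)
  writeLines(lines, path)
  if (write_meta) {
    m <- profile_meta(profile)
    jsonlite::write_json(m[c("label", "smoothed", "bandwidth",
                             "normalized", "norm_factor", "spacing")],
                         paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
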