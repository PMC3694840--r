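#' Plot a colocalization result
#'
#' Cumulative fraction of peaks against distance to the nearest hotspot-block
#' edge, with the random-placement percentile envelope as a ribbon and the
#' matching distance as a vertical line.
#'
#' @param object A `coloc_result` from [compare_top_n()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coloc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance / 1000)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$null_lower, ymax = .data$null_upper),
      fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_mean),
                       colour = "grey40", linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fraction), colour = "#1b7837",
                       linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$config$match_distance / 1000,
                        linetype = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "distance to nearest hotspot block (kb)",
                  y = "cumulative fraction of peaks",
                  title = sprintf("top %d peaks vs top %d blocks",
                                  object$config$n_peaks,
                                  object$config$n_blocks)) +
    ggplot2::theme_minimal()
}

#' Plot a stretch of one or more tiling profiles
#'
#' @param ... One or more `tiling_profile`s (named arguments become legend
#'   labels; unnamed ones use their profile labels).
#' @param chrom Chromosome to plot (default: the first in the first profile).
#' @param xlim Optional position range in bp.
#' @return A ggplot object.
#' @export
plot_profiles <- function(..., chrom = NULL, xlim = NULL) {
  profiles <- list(...)
  if (!length(profiles)) abort("supply at least one profile")
  nms <- names(profiles) %||% rep("", length(profiles))
  labs <- vapply(seq_along(profiles), function(i) {
    if (nzchar(nms[i])) nms[i] else
      attr(profiles[[i]], "label") %||% paste0("profile", i)
  }, character(1))
  chrom <- chrom %||% profiles[[1]]$chrom[1]
  df <- dplyr::bind_rows(lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    tibble(profile = labs[i], pos = p$pos[p$chrom == chrom],
           value = p$value[p$chrom == chrom])
  }))
  if (!is.null(xlim)) df <- df[df$pos >= xlim[1] & df$pos <= xlim[2], ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1000, y = .data$value,
                                   colour = .data$profile)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = paste0(chrom, " position (kb)"), y = "intensity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
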