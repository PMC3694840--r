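# Standard 16-chromosome budding-yeast karyotype (nuclear chromosomes only).
# Total 12,071,326 bp.
.sk1_like_lengths <- c(
  chrI    = 230218L,
  chrII   = 813184L,
  chrIII  = 316620L,
  chrIV   = 1531933L,
  chrV    = 576874L,
  chrVI   = 270161L,
  chrVII  = 1090940L,
  chrVIII = 562643L,
  chrIX   = 439888L,
  chrX    = 745751L,
  chrXI   = 666816L,
  chrXII  = 1078177L,
  chrXIII = 924431L,
  chrXIV  = 784333L,
  chrXV   = 1091291L,
  chrXVI  = 948066L
)

#' Build a genome description
#'
#' A genome is a tibble with one row per chromosome, in a fixed order, holding
#' the chromosome name and its length in bp. It is the substrate for the
#' synthetic hotspot/profile generators and validates all interval inputs.
#'
#' @param spec Either a preset name (`"sk1-like"`: the 16-chromosome
#'   budding-yeast karyotype, 12.07 Mb total; `"toy"`: two chromosomes of
#'   300 kb and 200 kb), a data frame with columns `chrom` and `length`, or a
#'   named numeric vector of chromosome lengths.
#'
#' @return A tibble with columns `chrom` (character) and `length` (integer bp).
#' @examples
#' make_genome("toy")
#' make_genome(c(chr1 = 1000))
#' @export
make_genome <- function(spec = "sk1-like") {
  if (is.character(spec) && length(spec) == 1L && is.null(names(spec))) {
    lens <- switch(spec,
      "sk1-like" = .sk1_like_lengths,
      "toy" = c(chrA = 300000L, chrB = 200000L),
      abort(paste0("unknown genome preset: '", spec, "'"))
    )
    genome <- tibble(chrom = names(lens), length = as.integer(lens))
  } else if (is.data.frame(spec)) {
    if (!all(c("chrom", "length") %in% names(spec))) {
      abort("explicit genome needs columns 'chrom' and 'length'")
    }
    genome <- tibble(chrom = as.character(spec$chrom),
                     length = as.integer(round(spec$length)))
  } else if (is.numeric(spec) && !is.null(names(spec))) {
    genome <- tibble(chrom = names(spec), length = as.integer(round(spec)))
  } else if (is.list(spec)) {
    # list of (name, length) pairs
    genome <- tibble(
      chrom = vapply(spec, function(x) as.character(x[[1]]), character(1)),
      length = vapply(spec, function(x) as.integer(x[[2]]), integer(1))
    )
  } else {
    abort("spec must be a preset name, a data frame, or a named length vector")
  }
  validate_genome(genome)
  genome
}

validate_genome <- function(genome) {
  if (!is.data.frame(genome) || !all(c("chrom", "length") %in% names(genome))) {
    abort("genome must be a data frame with columns 'chrom' and 'length'")
  }
  if (anyDuplicated(genome$chrom)) {
    abort(paste0("duplicated chromosome name: '",
                 genome$chrom[duplicated(genome$chrom)][1], "'"))
  }
  bad <- which(!is.finite(genome$length) | genome$length <= 0)
  if (length(bad)) {
    abort(paste0("chromosome '", genome$chrom[bad[1]],
                 "' has non-positive length"))
  }
  invisible(genome)
}

#' Total genome length
#'
#' @param genome A genome tibble from [make_genome()].
#' @return Total length in bp (numeric scalar).
#' @export
genome_size <- function(genome) {
  validate_genome(genome)
  sum(as.numeric(genome$length))
}

#' Read / write a chrom.sizes file
#'
#' Two whitespace-separated columns: chromosome name, length in bp.
#'
#' @param path File path.
#' @return `read_chrom_sizes()` returns a genome tibble.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, header = FALSE, col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  make_genome(setNames(df$length, df$chrom))
}

#' @rdname read_chrom_sizes
#' @param genome A genome tibble.
#' @export
write_chrom_sizes <- function(genome, path) {
  validate_genome(genome)
  write.table(genome, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
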