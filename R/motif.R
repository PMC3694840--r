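# [S/T]Q motif and SQ/TQ cluster-domain (SCD) scanning. ATM/ATR-family
# kinases phosphorylate serine or threonine residues immediately preceding a
# glutamine; substrates often carry SCDs, regions with three or more SQ/TQ
# dipeptides within a tract of at most 100 residues.

.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Find [S/T]Q motifs in a protein sequence
#'
#' Position `i` (0-based) is reported when residue `i` is S or T and residue
#' `i + 1` is Q. Matching is case-insensitive; characters outside the
#' 20-letter amino-acid alphabet are rejected with their position.
#'
#' @param sequence Protein sequence, one-letter code.
#' @return Sorted integer vector of 0-based motif positions.
#' @examples
#' find_stq_motifs("SQTQAQSQ")  # 0, 2, 6
#' @export
find_stq_motifs <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  chars <- strsplit(s, "")[[1]]
  bad <- which(!(chars %in% .AA_ALPHABET))
  if (length(bad)) {
    abort(sprintf("illegal character '%s' at position %d (1-based)",
                  chars[bad[1]], bad[1]))
  }
  m <- gregexpr("(?=[ST]Q)", s, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Find SQ/TQ cluster domains (SCDs)
#'
#' An SCD is a tract of at most `max_tract` residues containing at least
#' `min_motifs` SQ/TQ motifs. The tract is measured from the first motif's
#' S/T residue to the last motif's Q residue, inclusive. Motifs are grouped
#' by a left-to-right greedy maximal-run decomposition: starting at the
#' leftmost unassigned motif, the run is extended while the tract stays
#' within `max_tract`; runs with at least `min_motifs` motifs are reported.
#' Reported regions never overlap, every region satisfies both bounds, and
#' nested qualifying windows are reported once.
#'
#' @param motif_positions Sorted 0-based motif positions (from
#'   [find_stq_motifs()]).
#' @param min_motifs Minimum number of motifs per cluster (default 3).
#' @param max_tract Maximum tract length in residues (default 100).
#' @return A tibble with columns `start`, `end` (0-based, half-open residue
#'   indices covering first S/T to last Q), `n_motifs`, and a list column
#'   `motifs` of the member positions.
#' @examples
#' find_scds(c(0L, 50L, 98L))   # one SCD covering [0, 100)
#' find_scds(c(0L, 50L, 101L))  # none: tract 103 > 100
#' @export
find_scds <- function(motif_positions, min_motifs = 3, max_tract = 100) {
  stopifnot(min_motifs >= 1, max_tract >= 2)
  p <- sort(unique(as.integer(motif_positions)))
  rows <- list()
  i <- 1L
  n <- length(p)
  while (i <= n) {
    j <- i
    # tract from S/T at p[i] to Q at p[j] + 1, inclusive: p[j] + 2 - p[i]
    while (j + 1L <= n && p[j + 1L] + 2L - p[i] <= max_tract) j <- j + 1L
    if (j - i + 1L >= min_motifs) {
      rows[[length(rows) + 1L]] <- tibble(
        start = p[i], end = p[j] + 2L, n_motifs = j - i + 1L,
        motifs = list(p[i:j]))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(rows)) {
    tibble(start = integer(), end = integer(), n_motifs = integer(),
           motifs = list())
  } else {
    dplyr::bind_rows(rows)
  }
}

#' Scan protein sequences for [S/T]Q motifs and SCDs
#'
#' Accepts a FASTA file path (read with Biostrings) or a named character
#' vector of sequences.
#'
#' @param x FASTA path or named character vector of protein sequences.
#' @param min_motifs,max_tract SCD parameters, see [find_scds()].
#' @return A list of two tibbles: `motifs` (`seq`, `pos`) and `scds`
#'   (`seq`, `start`, `end`, `n_motifs`).
#' @export
scan_scd <- function(x, min_motifs = 3, max_tract = 100) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("reading FASTA requires the Biostrings package")
    }
    aa <- Biostrings::readAAStringSet(x)
    seqs <- setNames(as.character(aa), names(aa))
  } else if (is.character(x)) {
    if (is.null(names(x)) && length(x)) {
      names(x) <- paste0("seq", seq_along(x))
    }
    seqs <- x
  } else {
    abort("x must be a FASTA file path or a character vector of sequences")
  }
  motifs <- purrr::map_dfr(names(seqs), function(nm) {
    pos <- find_stq_motifs(seqs[[nm]])
    if (length(pos)) tibble(seq = nm, pos = pos) else
      tibble(seq = character(), pos = integer())
  })
  scds <- purrr::map_dfr(names(seqs), function(nm) {
    pos <- find_stq_motifs(seqs[[nm]])
    sc <- find_scds(pos, min_motifs, max_tract)
    if (nrow(sc)) tibble(seq = nm, start = sc$start, end = sc$end,
                         n_motifs = sc$n_motifs) else
      tibble(seq = character(), start = integer(), end = integer(),
             n_motifs = integer())
  })
  if (!nrow(motifs)) motifs <- tibble(seq = character(), pos = integer())
  if (!nrow(scds)) scds <- tibble(seq = character(), start = integer(),
                                  end = integer(), n_motifs = integer())
  list(motifs = motifs, scds = scds)
}

#' Scan a FASTA file and write motif / SCD tables
#'
#' Writes `<out_prefix>_motifs.tsv` and `<out_prefix>_scds.tsv` (headers are
#' written even when no motif or cluster is found).
#'
#' @param fasta FASTA file path.
#' @param out_prefix Output path prefix.
#' @inheritParams scan_scd
#' @return Invisibly, the [scan_scd()] result.
#' @export
scan_scd_file <- function(fasta, out_prefix, min_motifs = 3, max_tract = 100) {
  res <- scan_scd(fasta, min_motifs, max_tract)
  write.table(res$motifs, paste0(out_prefix, "_motifs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$scds, paste0(out_prefix, "_scds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(res)
}
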