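#' Per-locus alignment blocks
#'
#' An alignment block is one trimmed multiple alignment of a single locus:
#' equal-length gapped residue strings named by taxon.
#'
#' @param locus_id locus identifier.
#' @param seqs named character vector of equal-length gapped residue
#'   strings (alphabet: the 20 residues, `X`, `-`); names are taxa and
#'   must be unique.
#' @return An object of class `alignment_block` with fields `locus_id`,
#'   `taxa`, `seqs`, `length`.
#' @export
alignment_block <- function(locus_id, seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("alignment rows must be named by taxon")
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon within block ", locus_id, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("rows of block ", locus_id, " differ in length")
  bad <- grepl(paste0("[^-X", paste(AA_ALPHABET20, collapse = ""), "]"),
               toupper(seqs))
  if (any(bad))
    stop("block ", locus_id, " contains characters outside residues/gap")
  structure(list(locus_id = locus_id, taxa = names(seqs), seqs = seqs,
                 length = unname(widths[1L])),
            class = "alignment_block")
}

block_matrix <- function(block) {
  do.call(rbind, strsplit(block$seqs, "", fixed = TRUE))
}

#' Remove gap-rich alignment columns
#'
#' Retains columns whose gap fraction is at most `max_gap_fraction`; row
#' order is preserved. Applying the trim twice equals applying it once.
#'
#' @param block an [alignment_block()].
#' @param max_gap_fraction maximum tolerated fraction of `-` per column
#'   (default 0.5).
#' @return The trimmed `alignment_block` (possibly of length 0).
#' @export
trim_columns <- function(block, max_gap_fraction = 0.5) {
  stopifnot(inherits(block, "alignment_block"))
  if (block$length == 0L) return(block)
  m <- block_matrix(block)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= max_gap_fraction
  seqs <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  out <- block
  out$seqs <- stats::setNames(as.character(seqs), block$taxa)
  out$length <- sum(keep)
  out
}

#' Discard short alignments
#'
#' Keeps blocks of at least `min_length` columns (a 49-column alignment is
#' discarded, a 50-column one kept under the default).
#'
#' @param blocks list of [alignment_block()]s.
#' @param min_length minimum retained alignment length (default 50
#'   columns).
#' @return List with `kept` (the surviving blocks), `n_kept`,
#'   `n_discarded`, and `discarded_ids`.
#' @export
filter_alignments <- function(blocks, min_length = 50L) {
  lens <- vapply(blocks, `[[`, numeric(1), "length")
  keep <- lens >= min_length
  list(kept = blocks[keep], n_kept = sum(keep),
       n_discarded = sum(!keep),
       discarded_ids = vapply(blocks[!keep], `[[`, character(1),
                              "locus_id"))
}

#' Concatenate alignment blocks into a supermatrix
#'
#' One row per taxon of `taxon_universe`; a taxon missing from a block is
#' filled with `-` across that block's columns. The partition table gives
#' each locus's 1-based inclusive column range, so every locus slice of
#' the supermatrix reproduces the source block exactly.
#'
#' @param blocks list of [alignment_block()]s (each block's taxa must be a
#'   subset of `taxon_universe`).
#' @param taxon_universe taxa to appear as supermatrix rows, in order.
#' @return List with `alignment` (named character vector, one gapped
#'   string per taxon) and `partitions` (`data.frame`: `locus_id`,
#'   `start`, `end`).
#' @export
concatenate <- function(blocks, taxon_universe) {
  stopifnot(length(blocks) >= 1L, !anyDuplicated(taxon_universe))
  for (b in blocks) {
    extra <- setdiff(b$taxa, taxon_universe)
    if (length(extra))
      stop("block ", b$locus_id, " has taxa outside the universe: ",
           paste(extra, collapse = ", "))
  }
  lens <- vapply(blocks, `[[`, numeric(1), "length")
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  rows <- lapply(taxon_universe, function(t) {
    paste(vapply(blocks, function(b) {
      if (t %in% b$taxa) b$seqs[[t]] else strrep("-", b$length)
    }, character(1)), collapse = "")
  })
  list(alignment = stats::setNames(unlist(rows), taxon_universe),
       partitions = data.frame(
         locus_id = vapply(blocks, `[[`, character(1), "locus_id"),
         start = as.integer(starts), end = as.integer(ends),
         stringsAsFactors = FALSE))
}

#' Read and write supermatrix artifacts
#'
#' `read_alignment_block()` reads one aligned FASTA into an
#' [alignment_block()]; `write_supermatrix()` writes the concatenated
#' alignment as FASTA plus a plain-text partition table with lines
#' `"<locus_id> = <start>-<end>"`.
#'
#' @param path an aligned FASTA file.
#' @param locus_id locus identifier (default: file name without
#'   extension).
#' @return `read_alignment_block()` returns an `alignment_block`;
#'   `write_supermatrix()` returns `prefix` invisibly.
#' @export
read_alignment_block <- function(path, locus_id = NULL) {
  if (is.null(locus_id))
    locus_id <- sub("\\.[^.]*$", "", basename(path))
  aa <- Biostrings::readAAStringSet(path)
  alignment_block(locus_id, stats::setNames(as.character(aa), names(aa)))
}

#' @rdname read_alignment_block
#' @param supermatrix a [concatenate()] result.
#' @param prefix output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.partitions.txt`.
#' @export
write_supermatrix <- function(supermatrix, prefix) {
  aa <- Biostrings::AAStringSet(supermatrix$alignment)
  Biostrings::writeXStringSet(aa, paste0(prefix, ".fasta"), width = 60L)
  p <- supermatrix$partitions
  writeLines(sprintf("%s = %d-%d", p$locus_id, p$start, p$end),
             paste0(prefix, ".partitions.txt"))
  invisible(prefix)
}
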