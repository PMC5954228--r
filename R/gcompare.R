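#' Read and write genome-alignment match tables
#'
#' The seven-column tab-separated layout mirrors a flattened MUMmer
#' `show-coords` listing: `ref_start ref_end qry_start qry_end ref_len
#' qry_len pct_identity` with 1-based inclusive coordinates. Malformed
#' rows (wrong column count, non-numeric fields, identities outside
#' 0-100, lengths below 1) are rejected with their line number.
#'
#' @param path file path (header line optional on read).
#' @return `read_coords()` returns a `data.frame` of match records;
#'   `write_coords()` returns `path` invisibly.
#' @export
read_coords <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("ref_start", "ref_end", "qry_start", "qry_end",
            "ref_len", "qry_len", "pct_identity")
  offset <- 0L
  if (length(lines) && identical(strsplit(lines[1L], "\t")[[1L]], cols)) {
    lines <- lines[-1L]
    offset <- 1L
  }
  if (length(lines) == 0L)
    return(stats::setNames(data.frame(matrix(numeric(), 0L, 7L)), cols))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 7L))
    stop("line ", which(nc != 7L)[1L] + offset,
         ": expected 7 tab-separated columns, found ", nc[nc != 7L][1L])
  suppressWarnings(
    m <- matrix(as.numeric(unlist(parts)), ncol = 7L, byrow = TRUE))
  if (anyNA(m))
    stop("line ", which(rowSums(is.na(m)) > 0)[1L] + offset,
         ": non-numeric value")
  out <- stats::setNames(as.data.frame(m), cols)
  if (any(out$pct_identity < 0 | out$pct_identity > 100))
    stop("line ",
         which(out$pct_identity < 0 | out$pct_identity > 100)[1L] + offset,
         ": percent identity outside [0, 100]")
  if (any(out$ref_len < 1 | out$qry_len < 1))
    stop("line ", which(out$ref_len < 1 | out$qry_len < 1)[1L] + offset,
         ": match length < 1")
  out
}

#' @rdname read_coords
#' @param matches a match `data.frame` with the seven columns above.
#' @export
write_coords <- function(matches, path) {
  cols <- c("ref_start", "ref_end", "qry_start", "qry_end",
            "ref_len", "qry_len", "pct_identity")
  stopifnot(is.data.frame(matches), all(cols %in% names(matches)))
  utils::write.table(matches[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Aggregate match-identity statistics for one genome pair
#'
#' Sums matches on the reference coordinate system: `aligned_bases` is the
#' plain sum of reference match lengths (overlaps are not merged), and the
#' summary identity is the length-weighted mean of per-match identities
#' (`weighting = "length"`, the default) or their plain mean
#' (`weighting = "plain"`).
#'
#' @param matches a match table ([read_coords()]).
#' @param weighting `"length"` or `"plain"`.
#' @return An object of class `comparison_summary`: list with
#'   `n_matches`, `aligned_bases`, `weighted_identity` and
#'   `is_close_pair` (filled by [flag_close_pairs()], initially under the
#'   default 100-kb rule).
#' @export
aggregate_identity <- function(matches, weighting = c("length", "plain")) {
  weighting <- match.arg(weighting)
  if (!is.data.frame(matches) || nrow(matches) == 0L)
    stop("need at least one match record")
  aligned <- sum(matches$ref_len)
  wid <- if (weighting == "length")
    sum(matches$ref_len * matches$pct_identity) / aligned
  else mean(matches$pct_identity)
  structure(list(n_matches = nrow(matches), aligned_bases = aligned,
                 weighted_identity = wid,
                 is_close_pair = flag_close_pairs(aligned)),
            class = "comparison_summary")
}

#' The 100-kb close-pair rule
#'
#' A genome pair is flagged closely related when its total matched bases
#' are strictly longer than the threshold (exactly 100,000 bp is not
#' flagged).
#'
#' @param summary a `comparison_summary` or a numeric aligned-base count.
#' @param threshold_bp strict lower bound in bp (default 100,000).
#' @return Logical flag.
#' @export
flag_close_pairs <- function(summary, threshold_bp = 100000) {
  aligned <- if (inherits(summary, "comparison_summary"))
    summary$aligned_bases else summary
  stopifnot(is.numeric(aligned))
  aligned > threshold_bp
}

#' Assembly scaffold statistics
#'
#' Counts and sizes only scaffolds strictly longer than `min_scaffold_bp`
#' (the ">1 kb" convention). GC is `(G + C) / (A + C + G + T)` over the
#' retained scaffolds, with ambiguous bases excluded from the denominator.
#'
#' @param assembly a nucleotide FASTA path (gzip accepted) or a
#'   [Biostrings::DNAStringSet].
#' @param min_scaffold_bp strict scaffold length cutoff (default 1000).
#' @return An object of class `assembly_stats`: list with `n_scaffolds`,
#'   `total_bp`, `total_mb` (Mb, rounded to 2 decimals) and `gc_ratio`
#'   (percent).
#' @export
assembly_stats <- function(assembly, min_scaffold_bp = 1000) {
  dna <- if (methods::is(assembly, "DNAStringSet")) assembly
  else Biostrings::readDNAStringSet(assembly)
  if (length(dna) == 0L) stop("empty assembly")
  keep <- Biostrings::width(dna) > min_scaffold_bp
  dna <- dna[keep]
  total <- sum(Biostrings::width(dna))
  if (length(dna) > 0L) {
    freq <- colSums(Biostrings::letterFrequency(dna, c("A", "C", "G", "T")))
    gc <- 100 * sum(freq[c("C", "G")]) / sum(freq)
  } else gc <- NA_real_
  structure(list(n_scaffolds = sum(keep), total_bp = total,
                 total_mb = round(total / 1e6, 2L), gc_ratio = gc),
            class = "assembly_stats")
}

#' Nearest integer multiple of a genome-size base unit
#'
#' Classifies genome sizes against an integer-multiple pattern (the
#' whole-genome-duplication signature): each size is assigned
#' `round(size / base_unit)` (half-up, minimum 1) and the residual from
#' that multiple.
#'
#' @param genome_sizes numeric vector of genome sizes in Mb (> 0).
#' @param base_unit base genome size in Mb (default 25).
#' @return `data.frame` with columns `size_mb`, `multiple`,
#'   `residual_mb` (`size - multiple * base_unit`).
#' @export
size_multiplicity <- function(genome_sizes, base_unit = 25) {
  stopifnot(all(genome_sizes > 0), base_unit > 0)
  mult <- pmax(1L, as.integer(floor(genome_sizes / base_unit + 0.5)))
  data.frame(size_mb = genome_sizes, multiple = mult,
             residual_mb = genome_sizes - mult * base_unit)
}
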