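#' Scoring scheme for protein local alignment
#'
#' Bundles a substitution matrix, affine gap penalties and Karlin-Altschul
#' statistics parameters. The default matrix is BLOSUM62 (from
#' \pkg{Biostrings}) restricted to the 20 standard residues, with an extra
#' `X` row/column scored 0 against everything. A gap of length \eqn{k} costs
#' `gap_open + k * gap_extend`, so the first gapped residue costs
#' `gap_open + gap_extend` (the BLAST convention for 11/1 penalties).
#'
#' E-values follow the Karlin-Altschul form \eqn{E = K m n e^{-\lambda S}}
#' for a raw score \eqn{S} and sequence lengths \eqn{m}, \eqn{n}. The
#' defaults `K = 0.041`, `lambda = 0.267` are the usual gapped-BLOSUM62
#' values; only the ordering of hits and thresholding at the working cutoff
#' matter downstream, not BLAST-exact statistics.
#'
#' @param substitution_matrix a square integer matrix with residue
#'   dimnames, or the string `"BLOSUM62"`.
#' @param gap_open,gap_extend positive gap penalties.
#' @param K,lambda positive Karlin-Altschul parameters.
#' @return An object of class `scoring_scheme`.
#' @examples
#' sc <- scoring_scheme()
#' align_pair("ACDE", "ACDE", sc)$score # 24
#' @export
scoring_scheme <- function(substitution_matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1,
                           K = 0.041, lambda = 0.267) {
  if (is.character(substitution_matrix)) {
    if (!identical(substitution_matrix, "BLOSUM62"))
      stop("only BLOSUM62 is built in; pass a matrix for other schemes")
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    substitution_matrix <- e$BLOSUM62[AA_ALPHABET20, AA_ALPHABET20]
  }
  stopifnot(is.matrix(substitution_matrix),
            nrow(substitution_matrix) == ncol(substitution_matrix))
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be > 0")
  if (K <= 0 || lambda <= 0) stop("K and lambda must be > 0")
  # append the zero-scoring X column/row
  sm <- matrix(0L, 21L, 21L, dimnames = list(AA_ALPHABET_X, AA_ALPHABET_X))
  sm[AA_ALPHABET20, AA_ALPHABET20] <-
    as.integer(substitution_matrix[AA_ALPHABET20, AA_ALPHABET20])
  structure(list(substitution_matrix = sm,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 K = K, lambda = lambda),
            class = "scoring_scheme")
}

# Encode a residue string to 0-based integer codes; unknown residues other
# than X are an error.
encode_protein <- function(x) {
  if (!nzchar(x)) stop("empty sequence")
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  code <- match(ch, AA_ALPHABET_X)
  if (anyNA(code)) {
    bad <- unique(ch[is.na(code)])
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  }
  code - 1L
}

#' Optimal local alignment of two protein sequences
#'
#' Full (unseeded) Smith-Waterman dynamic programming with affine gaps.
#' Returns the maximum local alignment score and the statistics of one
#' optimal alignment.
#'
#' @param seq_a,seq_b residue strings over the 20-letter alphabet
#'   (`X` tolerated, scored 0).
#' @param scheme a [scoring_scheme()].
#' @return A list with elements `score`, `q_start`, `q_end`, `s_start`,
#'   `s_end` (1-based inclusive coordinates), `aln_length`, `matches`,
#'   `mismatches`, `gap_opens`, `gaps`, and `pct_identity`
#'   (`100 * matches / aln_length`). A score of 0 means no positive-scoring
#'   local alignment exists; the coordinates are then `NA`.
#' @export
align_pair <- function(seq_a, seq_b, scheme = scoring_scheme()) {
  a <- encode_protein(seq_a)
  b <- encode_protein(seq_b)
  res <- .sw_align_cpp(a, b, scheme$substitution_matrix,
                       scheme$gap_open, scheme$gap_extend)
  res$pct_identity <- if (res$aln_length > 0)
    100 * res$matches / res$aln_length else NA_real_
  res
}

#' Karlin-Altschul E-value and bit score
#'
#' `evalue_from_score()` computes \eqn{E = K m n e^{-\lambda S}};
#' `bit_score_from_score()` computes \eqn{(\lambda S - \ln K)/\ln 2}.
#'
#' @param raw_score non-negative integer alignment score.
#' @param m,n lengths (residues) of the two sequences.
#' @param scheme a [scoring_scheme()].
#' @return A numeric scalar (vectorised over `raw_score`).
#' @export
evalue_from_score <- function(raw_score, m, n, scheme = scoring_scheme()) {
  stopifnot(all(raw_score >= 0), all(m >= 1), all(n >= 1))
  scheme$K * m * n * exp(-scheme$lambda * raw_score)
}

#' @rdname evalue_from_score
#' @export
bit_score_from_score <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' All-vs-all protein similarity search
#'
#' Aligns every cross-taxon (optionally also within-taxon) sequence pair
#' with the full Smith-Waterman kernel and keeps pairs whose Karlin-Altschul
#' E-value is at or below the cutoff. Both directions of a pair are emitted
#' (the raw score is symmetric; alignment coordinates are swapped).
#' Self-hits (identical query and subject ID) are never reported.
#'
#' @param proteomes a named list (taxon -> sequences). Each element is a
#'   named character vector of residue strings or a
#'   [Biostrings::AAStringSet]; sequence names must be unique across taxa.
#' @param scheme a [scoring_scheme()].
#' @param evalue_cutoff keep hits with E-value at or below this (default
#'   `1e-5`, the working threshold of the whole pipeline).
#' @param within_taxon also align pairs within the same taxon (needed when
#'   counting in-paralogs, e.g. for enrichment matrices).
#' @return A hit table: `data.frame` with the 12 BLAST tabular columns
#'   (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore`), ordered by query, then subject, then descending bit
#'   score.
#' @export
all_vs_all <- function(proteomes, scheme = scoring_scheme(),
                       evalue_cutoff = 1e-5, within_taxon = FALSE) {
  stopifnot(is.list(proteomes), length(proteomes) >= 2 || within_taxon)
  seqs <- lapply(proteomes, as_residue_strings)
  ids <- unlist(lapply(seqs, names), use.names = FALSE)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    stop("all sequences must be named")
  if (anyDuplicated(ids))
    stop("duplicate sequence IDs across proteomes: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  taxon <- rep.int(seq_along(seqs), lengths(seqs))
  flat <- unlist(seqs, use.names = FALSE)
  enc <- lapply(flat, encode_protein)
  hits <- .all_vs_all_cpp(enc, taxon, ids, scheme$substitution_matrix,
                          scheme$gap_open, scheme$gap_extend,
                          scheme$K, scheme$lambda, evalue_cutoff,
                          within_taxon)
  hits <- hits[order(hits$qseqid, hits$sseqid, -hits$bitscore), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Coerce an AAStringSet or character vector to a named character vector.
as_residue_strings <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    out
  } else if (is.character(x)) {
    x
  } else stop("proteome must be a character vector or AAStringSet")
}

#' Read and write 12-column BLAST tabular hit tables
#'
#' The layout is the tab-separated `-outfmt 6` convention: `qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore`.
#' `read_hit_table()` rejects malformed rows (wrong column count,
#' non-numeric fields) with the offending line number;
#' `write_hit_table()` writes E-values in scientific notation at full
#' precision so that a write/read round trip reproduces the table exactly.
#'
#' @param path file path.
#' @param hits a hit table as returned by [all_vs_all()].
#' @return `read_hit_table()` returns the hit `data.frame`;
#'   `write_hit_table()` returns `path` invisibly.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hit_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12L))
    stop("line ", which(nc != 12L)[1L], ": expected 12 tab-separated ",
         "columns, found ", nc[nc != 12L][1L])
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  num_cols <- 3:12
  suppressWarnings(vals <- apply(m[, num_cols, drop = FALSE], 2, as.numeric))
  vals <- matrix(vals, ncol = length(num_cols))
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1L]
    stop("line ", bad, ": non-numeric value in a numeric column")
  }
  out <- data.frame(qseqid = m[, 1L], sseqid = m[, 2L],
                    pident = vals[, 1L], length = as.integer(vals[, 2L]),
                    mismatch = as.integer(vals[, 3L]),
                    gapopen = as.integer(vals[, 4L]),
                    qstart = as.integer(vals[, 5L]),
                    qend = as.integer(vals[, 6L]),
                    sstart = as.integer(vals[, 7L]),
                    send = as.integer(vals[, 8L]),
                    evalue = vals[, 9L], bitscore = vals[, 10L],
                    stringsAsFactors = FALSE)
  if (any(out$evalue < 0)) {
    stop("line ", which(out$evalue < 0)[1L], ": negative E-value")
  }
  if (any(out$length < 1)) {
    stop("line ", which(out$length < 1)[1L], ": alignment length < 1")
  }
  out
}

#' @rdname read_hit_table
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(is.data.frame(hits), identical(names(hits), HIT_COLUMNS))
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                   hits$qseqid, hits$sseqid, hits$pident, hits$length,
                   hits$mismatch, hits$gapopen, hits$qstart, hits$qend,
                   hits$sstart, hits$send,
                   sprintf("%.16e", hits$evalue), hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

empty_hit_table <- function() {
  data.frame(qseqid = character(), sseqid = character(),
             pident = numeric(), length = integer(), mismatch = integer(),
             gapopen = integer(), qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), evalue = numeric(),
             bitscore = numeric(), stringsAsFactors = FALSE)
}
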