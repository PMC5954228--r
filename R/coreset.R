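#' Gene-family presence/copy-count matrix
#'
#' Cell `(g, t)` is the number of group-`g` members contributed by taxon
#' `t` — 0/1 presence when families are single copy, higher counts for
#' paralog expansions.
#'
#' @param groups an ortholog group table (`group_id`, `taxon`, `seq_id`).
#' @param taxa character vector of taxon IDs (matrix columns, in order).
#' @return Integer matrix with group IDs as rownames and `taxa` as
#'   colnames.
#' @export
presence_matrix <- function(groups, taxa) {
  stopifnot(all(c("group_id", "taxon") %in% names(groups)),
            !anyDuplicated(taxa))
  bad <- setdiff(unique(groups$taxon), taxa)
  if (length(bad))
    stop("group member(s) from unlisted taxa: ", paste(bad, collapse = ", "))
  gids <- unique(groups$group_id)
  m <- matrix(0L, length(gids), length(taxa),
              dimnames = list(gids, taxa))
  if (nrow(groups) > 0L) {
    tab <- table(factor(groups$group_id, levels = gids),
                 factor(groups$taxon, levels = taxa))
    m[] <- as.integer(tab)
  }
  m
}

#' Core gene families with missing-taxon tolerance
#'
#' A family belongs to the core of `taxon_set` when it is present (copy
#' count >= 1) in at least `length(taxon_set) - max_missing` of those taxa
#' — e.g. `max_missing = 3` over 9 commensals requires presence in at
#' least 6 of the 9.
#'
#' @param matrix a [presence_matrix()].
#' @param taxon_set taxa over which the core is computed (subset of the
#'   matrix columns).
#' @param max_missing how many of `taxon_set` may lack the family
#'   (`0 <= max_missing < length(taxon_set)`).
#' @return Character vector of core group IDs (matrix row order).
#' @export
shared_genes <- function(matrix, taxon_set, max_missing = 0L) {
  stopifnot(all(taxon_set %in% colnames(matrix)),
            max_missing >= 0, max_missing < length(taxon_set))
  present <- rowSums(matrix[, taxon_set, drop = FALSE] >= 1L)
  rownames(matrix)[present >= length(taxon_set) - max_missing]
}

#' Venn partition of 2-4 named sets
#'
#' Counts every region of the inclusion/exclusion lattice exactly, from
#' membership bit-vectors. Region names join the defining set names with
#' `"&"`; a region counts elements in all named sets and none of the
#' others.
#'
#' @param sets a named list of 2 to 4 character vectors.
#' @return Named integer vector over all `2^k - 1` regions; the counts sum
#'   to the size of the union.
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 4L) stop("venn_partition supports 2 to 4 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, ncol = k,
                   dimnames = list(NULL, names(sets)))
  out <- integer(0)
  for (size in seq_len(k)) {
    for (idx in utils::combn(k, size, simplify = FALSE)) {
      inside <- rowSums(member[, idx, drop = FALSE]) == size
      outside <- rowSums(member[, -idx, drop = FALSE]) == 0
      region <- paste(names(sets)[idx], collapse = "&")
      out[region] <- sum(inside & if (size == k) TRUE else outside)
    }
  }
  out
}

#' Identify symbiosis-specific core families by intersection and
#' negative-control subtraction
#'
#' The candidate set contains every commensal core family whose
#' representative has a similarity hit (E-value at or below
#' `evalue_cutoff`) to at least one representative of the pathogen-A core
#' AND at least one of the pathogen-B core — the three-way intersection of
#' symbiont core gene sets. Candidates whose representative hits any
#' protein of any negative-control proteome (strictly below
#' `control_cutoff`) are then removed; the survivors are the
#' symbiosis-specific core families.
#'
#' @param commensal_core,pathogenA_core,pathogenB_core named character
#'   vectors (or `AAStringSet`s), family ID -> representative protein
#'   sequence.
#' @param control_proteomes named list, control taxon -> sequences
#'   (named character vector or `AAStringSet`).
#' @param scheme a [scoring_scheme()].
#' @param evalue_cutoff inclusive threshold for cross-guild sharing
#'   (default `1e-5`).
#' @param control_cutoff strict (`<`) threshold for the negative-control
#'   subtraction (default `1e-5`).
#' @return An object of class `fiscog_report`: list with `candidates`,
#'   `surviving` (character vectors of commensal family IDs) and
#'   `removed_by_control` (`data.frame`: `family_id`, `control_taxon`,
#'   `best_evalue`). `surviving` and removed IDs partition `candidates`.
#' @export
fiscog_identify <- function(commensal_core, pathogenA_core, pathogenB_core,
                            control_proteomes,
                            scheme = scoring_scheme(),
                            evalue_cutoff = 1e-5,
                            control_cutoff = 1e-5) {
  com <- rep_seqs(commensal_core, "commensal core")
  pa <- rep_seqs(pathogenA_core, "pathogen-A core")
  pb <- rep_seqs(pathogenB_core, "pathogen-B core")
  if (length(control_proteomes) == 0L) stop("control proteomes are empty")

  linked <- function(target) {
    pseudo <- list(q = stats::setNames(com, paste0("q|", names(com))),
                   s = stats::setNames(target,
                                       paste0("s|", names(target))))
    h <- all_vs_all(pseudo, scheme, evalue_cutoff)
    hq <- h[startsWith(h$qseqid, "q|"), , drop = FALSE]
    unique(sub("^q\\|", "", hq$qseqid))
  }
  in_pa <- linked(pa)
  in_pb <- linked(pb)
  candidates <- names(com)[names(com) %in% in_pa & names(com) %in% in_pb]

  removed <- data.frame(family_id = character(),
                        control_taxon = character(),
                        best_evalue = numeric(), stringsAsFactors = FALSE)
  if (length(candidates)) {
    cand_seqs <- stats::setNames(com[candidates],
                                 paste0("q|", candidates))
    ctl <- lapply(control_proteomes, as_residue_strings)
    hits_list <- lapply(names(ctl), function(ct) {
      h <- all_vs_all(list(q = cand_seqs, s = ctl[[ct]]),
                      scheme, evalue_cutoff = control_cutoff)
      h <- h[startsWith(h$qseqid, "q|") & h$evalue < control_cutoff, ,
             drop = FALSE]
      if (nrow(h) == 0L) return(NULL)
      data.frame(family_id = sub("^q\\|", "", h$qseqid),
                 control_taxon = ct, evalue = h$evalue,
                 stringsAsFactors = FALSE)
    })
    ctl_hits <- do.call(rbind, hits_list)
    if (!is.null(ctl_hits) && nrow(ctl_hits) > 0L) {
      ctl_hits <- ctl_hits[order(ctl_hits$family_id, ctl_hits$evalue,
                                 ctl_hits$control_taxon), , drop = FALSE]
      first <- ctl_hits[!duplicated(ctl_hits$family_id), , drop = FALSE]
      removed <- data.frame(family_id = first$family_id,
                            control_taxon = first$control_taxon,
                            best_evalue = first$evalue,
                            stringsAsFactors = FALSE)
      rownames(removed) <- NULL
    }
  }
  surviving <- setdiff(candidates, removed$family_id)
  structure(list(candidates = candidates, surviving = surviving,
                 removed_by_control = removed),
            class = "fiscog_report")
}

# Validate a family -> representative-sequence map.
rep_seqs <- function(x, what) {
  x <- as_residue_strings(x)
  if (length(x) == 0L) stop(what, " is empty")
  if (is.null(names(x)) || any(!nzchar(names(x))) || anyNA(names(x)))
    stop(what, ": every family needs a named representative sequence")
  if (any(is.na(x) | !nzchar(x)))
    stop(what, ": family without representative sequence: ",
         paste(names(x)[is.na(x) | !nzchar(x)], collapse = ", "))
  x
}

#' @export
print.fiscog_report <- function(x, ...) {
  cat("Symbiotic core gene report\n",
      "  candidates (3-way intersection): ", length(x$candidates), "\n",
      "  removed by negative controls:    ", nrow(x$removed_by_control),
      "\n",
      "  surviving symbiosis-specific:    ", length(x$surviving), "\n",
      sep = "")
  invisible(x)
}

#' Per-taxon enrichment of surviving core families
#'
#' Cell `(g, t)` counts the distinct proteins of taxon `t` hitting family
#' `g`'s representative at E-value at or below the cutoff — the counts
#' behind a family-by-taxon enrichment heat map.
#'
#' @param representatives named character vector (or `AAStringSet`),
#'   family ID -> representative sequence.
#' @param proteomes named list, taxon -> sequences.
#' @param scheme a [scoring_scheme()].
#' @param evalue_cutoff inclusive threshold.
#' @return Integer matrix, families x taxa.
#' @export
enrichment_matrix <- function(representatives, proteomes,
                              scheme = scoring_scheme(),
                              evalue_cutoff = 1e-5) {
  reps <- rep_seqs(representatives, "representative set")
  reps_pseudo <- stats::setNames(reps, paste0("rep|", names(reps)))
  taxa <- names(proteomes)
  m <- matrix(0L, length(reps), length(taxa),
              dimnames = list(names(reps), taxa))
  for (t in taxa) {
    target <- as_residue_strings(proteomes[[t]])
    if (length(target) == 0L) next
    h <- all_vs_all(list(rep = reps_pseudo, tx = target), scheme,
                    evalue_cutoff)
    h <- h[startsWith(h$qseqid, "rep|"), , drop = FALSE]
    if (nrow(h) == 0L) next
    fam <- sub("^rep\\|", "", h$qseqid)
    cnt <- tapply(h$sseqid, fam, function(s) length(unique(s)))
    m[names(cnt), t] <- as.integer(cnt)
  }
  m
}

#' Single-copy gene selection for duplication analysis
#'
#' `single_copy_set` contains the families with exactly one copy in every
#' small-genome taxon; `duplication_candidate_set` is its subset where at
#' least one large-genome taxon carries two or more copies — the pattern
#' expected of families retained in duplicate after a whole-genome
#' duplication.
#'
#' @param matrix a [presence_matrix()].
#' @param small_taxa,large_taxa disjoint sets of matrix columns.
#' @return List with character vectors `single_copy_set` and
#'   `duplication_candidate_set`.
#' @export
single_copy_selection <- function(matrix, small_taxa, large_taxa) {
  stopifnot(all(small_taxa %in% colnames(matrix)),
            all(large_taxa %in% colnames(matrix)))
  if (length(intersect(small_taxa, large_taxa)))
    stop("small_taxa and large_taxa must be disjoint")
  small <- matrix[, small_taxa, drop = FALSE]
  single <- rownames(matrix)[rowSums(small == 1L) == length(small_taxa)]
  large <- matrix[single, large_taxa, drop = FALSE]
  dup <- single[rowSums(large >= 2L) >= 1L]
  list(single_copy_set = single, duplication_candidate_set = dup)
}

#' Feature-by-taxon count matrix from a per-gene annotation table
#'
#' Consumes a precomputed per-gene feature annotation table (for example
#' protein-domain assignments) and tallies, per feature and taxon, the
#' number of distinct genes carrying the feature.
#'
#' @param annotations `data.frame` with columns `seq_id`, `taxon`,
#'   `feature_id`.
#' @param taxa optional taxon universe (matrix columns); defaults to the
#'   taxa observed in the table.
#' @return Integer matrix, features x taxa.
#' @export
feature_count_matrix <- function(annotations, taxa = NULL) {
  need <- c("seq_id", "taxon", "feature_id")
  if (!is.data.frame(annotations) || !all(need %in% names(annotations)))
    stop("annotations must have columns seq_id, taxon, feature_id")
  if (is.null(taxa)) taxa <- sort(unique(annotations$taxon))
  ann <- unique(annotations[, need])
  feats <- sort(unique(ann$feature_id))
  m <- matrix(0L, length(feats), length(taxa),
              dimnames = list(feats, taxa))
  if (nrow(ann) > 0L) {
    bad <- setdiff(unique(ann$taxon), taxa)
    if (length(bad)) stop("annotation rows for unlisted taxa: ",
                          paste(bad, collapse = ", "))
    tab <- table(factor(ann$feature_id, levels = feats),
                 factor(ann$taxon, levels = taxa))
    m[] <- as.integer(tab)
  }
  m
}

#' Write a symbiotic-core report directory
#'
#' Emits `candidates.tsv`, `surviving.tsv`, `removed.tsv`, optionally
#' `enrichment.tsv`, and a `summary.json` with all counts.
#'
#' @param report a [fiscog_identify()] result.
#' @param dir output directory (created if needed).
#' @param enrichment optional [enrichment_matrix()] for the surviving
#'   families.
#' @return `dir`, invisibly.
#' @export
write_fiscog_report <- function(report, dir, enrichment = NULL) {
  stopifnot(inherits(report, "fiscog_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(report$candidates, file.path(dir, "candidates.tsv"))
  writeLines(report$surviving, file.path(dir, "surviving.tsv"))
  utils::write.table(report$removed_by_control,
                     file.path(dir, "removed.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(enrichment)) {
    df <- data.frame(group_id = rownames(enrichment), enrichment,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  summary <- list(n_candidates = length(report$candidates),
                  n_surviving = length(report$surviving),
                  n_removed_by_control = nrow(report$removed_by_control))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
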