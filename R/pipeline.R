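#' Cluster one guild's proteomes into ortholog families
#'
#' Runs the similarity search within one set of proteomes, builds the
#' `-log10(E)`-weighted graph, Markov-clusters it, selects per-taxon and
#' family-level representatives and tabulates the presence matrix.
#'
#' @param proteomes named list, taxon -> sequences (named character vector
#'   or `AAStringSet`).
#' @param scheme a [scoring_scheme()].
#' @param evalue_cutoff working E-value threshold (default `1e-5`).
#' @param inflation MCL inflation (default 2).
#' @return List with `hits`, `graph`, `groups`, `representatives`
#'   (per taxon), `group_representatives` (one per family, with a
#'   `sequence` column) and `presence` (families x taxa matrix).
#' @export
cluster_proteomes <- function(proteomes, scheme = scoring_scheme(),
                              evalue_cutoff = 1e-5, inflation = 2) {
  seqs <- lapply(proteomes, as_residue_strings)
  taxon_map <- data.frame(
    seq_id = unlist(lapply(seqs, names), use.names = FALSE),
    taxon = rep(names(seqs), lengths(seqs)), stringsAsFactors = FALSE)
  hits <- all_vs_all(seqs, scheme, evalue_cutoff)
  graph <- build_similarity_graph(hits, taxon_map, evalue_cutoff)
  groups <- mcl_cluster(graph, inflation = inflation)
  reps <- select_representatives(groups, graph)
  greps <- select_group_representative(groups, graph)
  flat <- unlist(unname(seqs))
  greps$sequence <- unname(flat[greps$seq_id])
  list(hits = hits, graph = graph, groups = groups,
       representatives = reps, group_representatives = greps,
       presence = presence_matrix(groups, names(seqs)))
}

#' Full symbiotic-core discovery pipeline
#'
#' The complete analysis chain on four guilds of proteomes: each symbiont
#' guild (commensals, pathogen group A, pathogen group B) is clustered
#' into families, missing-taxon-tolerant core sets are taken per guild,
#' the three cores are intersected via representative cross-hits, and
#' candidates with homologs in the free-living control proteomes are
#' subtracted. Defaults follow the guild-specific tolerances of the study
#' design: up to 3 of 9 commensals, up to 2 of 6 group-A pathogens and no
#' group-B pathogens missing.
#'
#' @param commensal,pathogenA,pathogenB,controls named lists, taxon ->
#'   sequences, one list per guild.
#' @param max_missing named numeric vector with entries `commensal`,
#'   `pathogenA`, `pathogenB`.
#' @param scheme a [scoring_scheme()].
#' @param evalue_cutoff inclusive threshold for similarity edges and
#'   cross-guild sharing.
#' @param control_cutoff strict threshold for negative-control
#'   subtraction.
#' @param inflation MCL inflation.
#' @param enrichment also compute the enrichment matrix of the surviving
#'   families across all symbiont taxa (default `TRUE`).
#' @return List with per-guild clusterings (`clusterings`), core family
#'   IDs (`cores`), the [fiscog_identify()] `report`, the surviving
#'   families' commensal group IDs mapped to representative sequences
#'   (`surviving_representatives`), and optionally `enrichment`.
#' @export
fiscog_pipeline <- function(commensal, pathogenA, pathogenB, controls,
                            max_missing = c(commensal = 3, pathogenA = 2,
                                            pathogenB = 0),
                            scheme = scoring_scheme(),
                            evalue_cutoff = 1e-5, control_cutoff = 1e-5,
                            inflation = 2, enrichment = TRUE) {
  guilds <- list(commensal = commensal, pathogenA = pathogenA,
                 pathogenB = pathogenB)
  clusterings <- lapply(guilds, cluster_proteomes, scheme = scheme,
                        evalue_cutoff = evalue_cutoff,
                        inflation = inflation)
  cores <- lapply(names(guilds), function(g) {
    cl <- clusterings[[g]]
    shared_genes(cl$presence, colnames(cl$presence),
                 max_missing = max_missing[[g]])
  })
  names(cores) <- names(guilds)
  core_reps <- lapply(names(guilds), function(g) {
    gr <- clusterings[[g]]$group_representatives
    gr <- gr[gr$group_id %in% cores[[g]], , drop = FALSE]
    stats::setNames(gr$sequence, gr$group_id)
  })
  names(core_reps) <- names(guilds)
  report <- fiscog_identify(core_reps$commensal, core_reps$pathogenA,
                            core_reps$pathogenB, controls,
                            scheme = scheme,
                            evalue_cutoff = evalue_cutoff,
                            control_cutoff = control_cutoff)
  surviving_reps <- core_reps$commensal[report$surviving]
  out <- list(clusterings = clusterings, cores = cores, report = report,
              surviving_representatives = surviving_reps)
  if (enrichment && length(surviving_reps)) {
    out$enrichment <- enrichment_matrix(
      surviving_reps,
      c(commensal, pathogenA, pathogenB, controls),
      scheme = scheme, evalue_cutoff = evalue_cutoff)
  }
  out
}

#' Map simulated ground-truth families onto discovered groups
#'
#' Joins an ortholog group table with a [simulate_proteomes()] truth table
#' and reports, per group, the underlying true families of its members —
#' the basis of planted-family precision/recall checks.
#'
#' @param groups an ortholog group table (`group_id`, `taxon`, `seq_id`).
#' @param truth the `truth` table from [simulate_proteomes()].
#' @return `data.frame` with one row per group: `group_id`, `n_members`,
#'   `n_families` (distinct true families among members) and `family_id`
#'   (the single true family when `n_families == 1`, else `NA`).
#' @export
match_groups_to_truth <- function(groups, truth) {
  fam <- stats::setNames(truth$family_id, truth$seq_id)
  if (anyNA(fam[groups$seq_id]))
    stop("group member(s) missing from the truth table")
  spl <- split(unname(fam[groups$seq_id]), groups$group_id)
  data.frame(
    group_id = names(spl),
    n_members = lengths(spl),
    n_families = vapply(spl, function(x) length(unique(x)), integer(1)),
    family_id = vapply(spl, function(x)
      if (length(unique(x)) == 1L) x[[1L]] else NA_character_,
      character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
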