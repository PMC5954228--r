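#' Simulation design constructors
#'
#' `guild_config()` describes one guild of taxa (e.g. 9 insect-gut
#' commensals); `family_spec()` describes one gene family, including
#' per-guild presence probabilities, per-taxon copy numbers and the
#' planted-core flag; `sim_design()` bundles guilds and families with the
#' divergence parameters and a seed.
#'
#' A planted core family (`is_planted_core = TRUE`) models a
#' symbiosis-specific gene: it is present in every taxon of every
#' non-control guild and absent from every taxon of the guild named
#' `"control"`; its `presence` map is filled in automatically and must not
#' contradict that pattern.
#'
#' @param guild_name guild label, e.g. `"commensal"`, `"pathogenA"`,
#'   `"pathogenB"`, `"control"`. The name `"control"` marks the
#'   negative-control guild.
#' @param n_taxa number of taxa in the guild (>= 1).
#' @param taxon_prefix prefix for generated taxon names
#'   (`<prefix>1 ... <prefix>n`).
#' @return `guild_config()`, `family_spec()` and `sim_design()` return
#'   lists of class `guild_config`, `family_spec` and `sim_design`.
#' @export
guild_config <- function(guild_name, n_taxa, taxon_prefix = guild_name) {
  stopifnot(is.character(guild_name), length(guild_name) == 1L,
            n_taxa >= 1)
  structure(list(guild_name = guild_name, n_taxa = as.integer(n_taxa),
                 taxon_prefix = taxon_prefix),
            class = "guild_config")
}

#' @rdname guild_config
#' @param family_id unique family identifier.
#' @param ancestral_length length of the ancestral protein (>= 30 residues; default 50).
#' @param presence named numeric vector, guild name -> per-taxon presence
#'   probability in `[0, 1]`. Guilds absent from the map get probability 0.
#' @param is_planted_core if `TRUE` the family is a planted symbiosis-core
#'   family (see Details).
#' @param copy_number optional named integer vector, taxon name -> gene copy
#'   count for taxa carrying the family; taxa not listed get 1 copy.
#' @export
family_spec <- function(family_id, ancestral_length = 50,
                        presence = NULL, is_planted_core = FALSE,
                        copy_number = NULL) {
  stopifnot(is.character(family_id), length(family_id) == 1L)
  if (ancestral_length < 30) stop("ancestral_length must be >= 30")
  if (!is.null(presence)) {
    stopifnot(is.numeric(presence), !is.null(names(presence)),
              all(presence >= 0 & presence <= 1))
  }
  if (!is.null(copy_number)) {
    stopifnot(is.numeric(copy_number), !is.null(names(copy_number)),
              all(copy_number >= 0))
    copy_number <- stats::setNames(as.integer(copy_number),
                                   names(copy_number))
  }
  structure(list(family_id = family_id,
                 ancestral_length = as.integer(ancestral_length),
                 presence = presence,
                 is_planted_core = isTRUE(is_planted_core),
                 copy_number = copy_number),
            class = "family_spec")
}

#' @rdname guild_config
#' @param guilds list of [guild_config()] objects with unique guild names.
#' @param families list of [family_spec()] objects with unique family IDs.
#' @param substitution_rate expected substitutions per site applied
#'   independently on each taxon's branch from the family ancestor (star
#'   phylogeny), in `[0, 1]`.
#' @param duplication_divergence expected substitutions per site between
#'   paralog copies within a taxon, in `[0, 1]`.
#' @param seed integer seed; fixes every emitted artifact byte-for-byte.
#' @export
sim_design <- function(guilds, families, substitution_rate = 0.1,
                       duplication_divergence = 0.05, seed = 1L) {
  if (length(guilds) == 0L) stop("empty guild list")
  stopifnot(all(vapply(guilds, inherits, logical(1), "guild_config")),
            all(vapply(families, inherits, logical(1), "family_spec")),
            substitution_rate >= 0, substitution_rate <= 1,
            duplication_divergence >= 0, duplication_divergence <= 1)
  gnames <- vapply(guilds, `[[`, character(1), "guild_name")
  if (anyDuplicated(gnames)) stop("guild names must be unique")
  fids <- vapply(families, `[[`, character(1), "family_id")
  if (anyDuplicated(fids)) stop("family IDs must be unique")
  for (f in families) {
    if (!is.null(f$presence) && !all(names(f$presence) %in% gnames))
      stop("family ", f$family_id, " references unknown guild(s): ",
           paste(setdiff(names(f$presence), gnames), collapse = ", "))
    if (f$is_planted_core && !is.null(f$presence)) {
      ctrl <- intersect(names(f$presence), "control")
      if (length(ctrl) && any(f$presence[ctrl] != 0))
        stop("planted core family ", f$family_id,
             " must be absent from the control guild")
      noncontrol <- setdiff(names(f$presence), "control")
      if (any(f$presence[noncontrol] != 1))
        stop("planted core family ", f$family_id,
             " must have presence 1 in non-control guilds")
    }
  }
  structure(list(guilds = guilds, families = families,
                 substitution_rate = substitution_rate,
                 duplication_divergence = duplication_divergence,
                 seed = as.integer(seed)),
            class = "sim_design")
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Introduce a fixed number of substitutions into a protein sequence
#'
#' Exactly `n_substitutions` distinct positions are changed; the
#' replacement residue at a position is drawn uniformly from the 19
#' residues differing from the original, so the Hamming distance to the
#' input is exactly `n_substitutions`. Draws from R's current random number
#' stream.
#'
#' @param sequence residue string.
#' @param n_substitutions number of positions to change
#'   (0 <= n <= `nchar(sequence)`).
#' @return The mutated residue string (same length).
#' @export
mutate_protein <- function(sequence, n_substitutions) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  len <- length(ch)
  if (n_substitutions > len)
    stop("n_substitutions (", n_substitutions, ") exceeds sequence length (",
         len, ")")
  if (n_substitutions == 0L) return(sequence)
  pos <- sample.int(len, n_substitutions)
  for (p in pos) {
    alt <- AA_ALPHABET20[AA_ALPHABET20 != ch[p]]
    ch[p] <- alt[sample.int(19L, 1L)]
  }
  paste(ch, collapse = "")
}

random_protein <- function(len) {
  paste(AA_ALPHABET20[sample.int(20L, len, replace = TRUE)], collapse = "")
}

#' Simulate multi-taxon proteomes with known family structure
#'
#' For each family an ancestral protein is drawn uniformly over the 20
#' standard residues; each carrying taxon receives an independently
#' diverged copy (binomially many substitutions at rate
#' `substitution_rate`), and additional paralog copies diverge further at
#' rate `duplication_divergence`. Presence of a family in a taxon is
#' Bernoulli with the guild's presence probability; planted core families
#' are deterministic (all symbiont taxa, no control taxa).
#'
#' @param design a [sim_design()].
#' @param out_dir optional directory; if given, one 60-column-wrapped
#'   multi-FASTA per taxon (`<taxon>.faa`) and a `truth.tsv` table are
#'   written there.
#' @return A list with components
#'   \describe{
#'   \item{proteomes}{named list, taxon -> named character vector of
#'     protein sequences; IDs are `<taxon>|<family>|c<copy>`.}
#'   \item{truth}{`data.frame` with columns `family_id`, `taxon`, `seq_id`,
#'     `copy`, `is_planted_core` — the ground-truth family table.}
#'   \item{taxa}{`data.frame` with columns `taxon`, `guild`.}
#'   }
#' @export
simulate_proteomes <- function(design, out_dir = NULL) {
  stopifnot(inherits(design, "sim_design"))
  gnames <- vapply(design$guilds, `[[`, character(1), "guild_name")
  taxa <- do.call(rbind, lapply(design$guilds, function(g) {
    data.frame(taxon = paste0(g$taxon_prefix, seq_len(g$n_taxa)),
               guild = g$guild_name, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(taxa$taxon)) stop("taxon prefixes generate duplicate taxon names")
  with_seed(design$seed, {
    seqs <- stats::setNames(
      lapply(taxa$taxon, function(t) character(0)), taxa$taxon)
    truth <- vector("list", length(design$families))
    for (k in seq_along(design$families)) {
      fam <- design$families[[k]]
      anc <- random_protein(fam$ancestral_length)
      pres_prob <- vapply(taxa$guild, function(g) {
        if (fam$is_planted_core) return(if (g == "control") 0 else 1)
        if (is.null(fam$presence) || !g %in% names(fam$presence)) 0
        else unname(fam$presence[[g]])
      }, numeric(1))
      rows <- list()
      for (i in seq_len(nrow(taxa))) {
        p <- pres_prob[i]
        present <- p >= 1 || (p > 0 && stats::runif(1) < p)
        if (!present) next
        taxon <- taxa$taxon[i]
        ncopy <- if (!is.null(fam$copy_number) &&
                     taxon %in% names(fam$copy_number))
          fam$copy_number[[taxon]] else 1L
        if (ncopy < 1L) next
        nsub <- stats::rbinom(1L, fam$ancestral_length,
                              design$substitution_rate)
        base <- mutate_protein(anc, nsub)
        for (cp in seq_len(ncopy)) {
          s <- if (cp == 1L) base else
            mutate_protein(base, stats::rbinom(1L, fam$ancestral_length,
                                               design$duplication_divergence))
          id <- paste0(taxon, "|", fam$family_id, "|c", cp)
          seqs[[taxon]][id] <- s
          rows[[length(rows) + 1L]] <-
            data.frame(family_id = fam$family_id, taxon = taxon,
                       seq_id = id, copy = cp,
                       is_planted_core = fam$is_planted_core,
                       stringsAsFactors = FALSE)
        }
      }
      truth[[k]] <- if (length(rows)) do.call(rbind, rows) else NULL
    }
    truth <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
    if (is.null(truth))
      truth <- data.frame(family_id = character(), taxon = character(),
                          seq_id = character(), copy = integer(),
                          is_planted_core = logical(),
                          stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    out <- list(proteomes = seqs, truth = truth, taxa = taxa)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (t in names(seqs)) {
        aa <- Biostrings::AAStringSet(seqs[[t]])
        Biostrings::writeXStringSet(aa, file.path(out_dir,
                                                  paste0(t, ".faa")),
                                    width = 60L)
      }
      utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
  })
}

#' The four-guild study design behind the symbiotic-core analysis
#'
#' Convenience constructor for the canonical simulation shape: 9 commensal,
#' 6 pathogen-A, 3 pathogen-B and 4 free-living control taxa; a set of
#' background families present in every guild (controls included) and a
#' set of planted symbiosis-core families present in all symbiont taxa and
#' absent from controls.
#'
#' @param n_background number of background families (default 300).
#' @param n_planted number of planted symbiosis-core families (default 8).
#' @param n_commensal,n_pathogenA,n_pathogenB,n_control guild sizes
#'   (defaults 9, 6, 3, 4).
#' @param ancestral_length protein length in residues (default 60).
#' @param substitution_rate,duplication_divergence see [sim_design()].
#' @param seed integer seed.
#' @return A [sim_design()].
#' @export
fiscog_design <- function(n_background = 300, n_planted = 8,
                          n_commensal = 9, n_pathogenA = 6,
                          n_pathogenB = 3, n_control = 4,
                          ancestral_length = 50,
                          substitution_rate = 0.1,
                          duplication_divergence = 0.05, seed = 1L) {
  guilds <- list(guild_config("commensal", n_commensal, "com"),
                 guild_config("pathogenA", n_pathogenA, "pga"),
                 guild_config("pathogenB", n_pathogenB, "pgb"),
                 guild_config("control", n_control, "ctl"))
  all_guilds <- c(commensal = 1, pathogenA = 1, pathogenB = 1, control = 1)
  fams <- c(
    lapply(seq_len(n_background), function(i)
      family_spec(sprintf("bg%03d", i), ancestral_length,
                  presence = all_guilds)),
    lapply(seq_len(n_planted), function(i)
      family_spec(sprintf("core%02d", i), ancestral_length,
                  is_planted_core = TRUE)))
  sim_design(guilds, fams, substitution_rate = substitution_rate,
             duplication_divergence = duplication_divergence, seed = seed)
}

#' Pileup design and simulation
#'
#' `pileup_design()` describes a per-site read-count simulation for a
#' haploid or diploid genome; `simulate_pileup()` draws the table. Coverage
#' at each site is Poisson with mean `coverage_mean`, floored at 1. In a
#' diploid genome a site is heterozygous with probability `heterozygosity`,
#' and its alternate read count is Binomial(coverage, 1/2) — a fair split
#' of the two alleles (symmetric sequencing error leaves the expected split
#' at 1/2). At homozygous and haploid sites alternate reads arise only from
#' sequencing error, Binomial(coverage, `error_rate`).
#'
#' @param ploidy 1 or 2.
#' @param n_sites number of genome sites to simulate.
#' @param coverage_mean mean read depth (>= 1).
#' @param heterozygosity fraction of heterozygous sites (diploid only).
#' @param error_rate per-read error probability.
#' @param seed integer seed.
#' @return `pileup_design()` returns a `pileup_design` object.
#'   `simulate_pileup()` returns a `data.frame` with columns `contig`,
#'   `pos` (1-based), `ref_count`, `alt_count`; the logical attribute
#'   `"truth_het"` marks the truly heterozygous sites.
#' @export
pileup_design <- function(ploidy, n_sites, coverage_mean,
                          heterozygosity = 0, error_rate = 0.01,
                          seed = 1L) {
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  stopifnot(n_sites >= 1, coverage_mean >= 1,
            heterozygosity >= 0, heterozygosity <= 1,
            error_rate >= 0, error_rate < 1)
  structure(list(ploidy = as.integer(ploidy), n_sites = as.integer(n_sites),
                 coverage_mean = coverage_mean,
                 heterozygosity = heterozygosity, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "pileup_design")
}

#' @rdname pileup_design
#' @param design a [pileup_design()].
#' @param out_path optional path for a 4-column TSV
#'   (`contig pos ref_count alt_count`).
#' @export
simulate_pileup <- function(design, out_path = NULL) {
  stopifnot(inherits(design, "pileup_design"))
  with_seed(design$seed, {
    n <- design$n_sites
    cov <- pmax(1L, stats::rpois(n, design$coverage_mean))
    het <- if (design$ploidy == 2L)
      stats::runif(n) < design$heterozygosity else rep(FALSE, n)
    p_alt <- ifelse(het, 0.5, design$error_rate)
    alt <- stats::rbinom(n, cov, p_alt)
    sites <- data.frame(contig = "sim_contig", pos = seq_len(n),
                        ref_count = cov - alt, alt_count = alt,
                        stringsAsFactors = FALSE)
    attr(sites, "truth_het") <- het
    if (!is.null(out_path))
      utils::write.table(sites, out_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    sites
  })
}
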