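#' Variant-calling configuration
#'
#' Site-level acceptance thresholds in the style of a pileup SNP caller:
#' minimum read depth, minimum alternate reads, minimum alternate-allele
#' fraction, and an exact one-sided binomial test of the alternate read
#' count against the sequencing error rate.
#'
#' @param min_coverage minimum total depth `ref + alt` (default 10).
#' @param min_alt_reads minimum alternate reads (default 2).
#' @param min_var_freq minimum `alt / (ref + alt)` (default 0.20).
#' @param p_threshold significance level of the binomial test (default
#'   0.05, strict `<`).
#' @param error_rate assumed per-read error probability under the null
#'   (default 0.01).
#' @return An object of class `calling_config`.
#' @export
calling_config <- function(min_coverage = 10L, min_alt_reads = 2L,
                           min_var_freq = 0.20, p_threshold = 0.05,
                           error_rate = 0.01) {
  stopifnot(min_coverage > 0, min_alt_reads > 0,
            min_var_freq > 0, min_var_freq < 1,
            p_threshold > 0, error_rate > 0)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_alt_reads = as.integer(min_alt_reads),
                 min_var_freq = min_var_freq,
                 p_threshold = p_threshold, error_rate = error_rate),
            class = "calling_config")
}

#' Call variant sites from per-site read counts
#'
#' A site is accepted iff, in this order: total coverage `ref + alt >=
#' min_coverage`; `alt >= min_alt_reads`; `alt / (ref + alt) >=
#' min_var_freq`; and the exact one-sided binomial tail probability
#' `P(X >= alt | n = ref + alt, p = error_rate)` is below `p_threshold`.
#' The rejection reason names the first failed criterion.
#'
#' `call_variants()` is the vectorised form over a site table.
#'
#' @param ref_count,alt_count reference/alternate read counts at one site.
#' @param cfg a [calling_config()].
#' @return `call_variant_site()` returns a list with `accepted` (logical),
#'   `reason` (`NA` when accepted) and `p_value`. `call_variants()` returns
#'   the site table with `accepted`, `reason` and `p_value` columns added.
#' @export
call_variant_site <- function(ref_count, alt_count,
                              cfg = calling_config()) {
  res <- call_variants(data.frame(ref_count = ref_count,
                                  alt_count = alt_count), cfg)
  list(accepted = res$accepted[1L], reason = res$reason[1L],
       p_value = res$p_value[1L])
}

#' @rdname call_variant_site
#' @param sites `data.frame` with columns `ref_count`, `alt_count` (extra
#'   columns such as `contig`, `pos` are carried through).
#' @export
call_variants <- function(sites, cfg = calling_config()) {
  stopifnot(all(c("ref_count", "alt_count") %in% names(sites)),
            all(sites$ref_count >= 0), all(sites$alt_count >= 0))
  cov <- sites$ref_count + sites$alt_count
  freq <- ifelse(cov > 0, sites$alt_count / cov, 0)
  # exact one-sided binomial: P(X >= alt | n = cov, p = error_rate)
  p <- stats::pbinom(sites$alt_count - 1L, cov, cfg$error_rate,
                     lower.tail = FALSE)
  reason <- rep(NA_character_, nrow(sites))
  reason[p >= cfg$p_threshold] <- "binomial_p"
  reason[freq < cfg$min_var_freq] <- "min_var_freq"
  reason[sites$alt_count < cfg$min_alt_reads] <- "min_alt_reads"
  reason[cov < cfg$min_coverage] <- "min_coverage"
  sites$accepted <- is.na(reason)
  sites$reason <- reason
  sites$p_value <- p
  sites
}

#' Genome-wide SNP percentage
#'
#' @param n_accepted number of accepted variant sites.
#' @param genome_length genome size in bp (> 0).
#' @return `100 * n_accepted / genome_length` (percent).
#' @export
snp_ratio <- function(n_accepted, genome_length) {
  if (genome_length <= 0) stop("genome_length must be > 0")
  stopifnot(n_accepted >= 0)
  100 * n_accepted / genome_length
}

#' Integer-binned allele-frequency spectrum
#'
#' Per-site alternate-allele frequency `100 * alt / (ref + alt)` is
#' rounded half-up to an integer percent; sites outside `interval`
#' (default 10-90%) are excluded and the remaining sites tallied per
#' integer bin. Half-up rounding (46.5 becomes 47) keeps bin boundaries
#' deterministic across platforms.
#'
#' @param sites accepted variant sites (`data.frame` with `ref_count`,
#'   `alt_count`).
#' @param interval inclusive integer percent range, default `c(10, 90)`.
#' @return An object of class `frequency_spectrum`: list with `bins`
#'   (integer percents over the interval), `counts` and `n_variant_sites`
#'   (= `sum(counts)`).
#' @export
allele_frequency_spectrum <- function(sites, interval = c(10L, 90L)) {
  stopifnot(all(c("ref_count", "alt_count") %in% names(sites)),
            length(interval) == 2L, interval[1L] <= interval[2L])
  cov <- sites$ref_count + sites$alt_count
  stopifnot(all(cov > 0))
  freq <- 100 * sites$alt_count / cov
  bin <- floor(freq + 0.5)  # half-up
  bins <- seq.int(interval[1L], interval[2L])
  inside <- bin >= interval[1L] & bin <= interval[2L]
  counts <- as.integer(table(factor(bin[inside], levels = bins)))
  structure(list(bins = as.integer(bins), counts = counts,
                 n_variant_sites = sum(counts)),
            class = "frequency_spectrum")
}

#' Haploid/diploid call from the allele-frequency spectrum
#'
#' A diploid (disomic) genome concentrates heterozygous-site frequencies
#' around 50%; the call is `"diploid"` when at least `mass_threshold` of
#' the spectrum mass lies inside `peak_window` and the spectrum holds at
#' least `min_sites` sites. With enough sites but less peak mass the call
#' is `"haploid"`; with fewer than `min_sites` sites the spectrum carries
#' too little signal and the call is `"indeterminate"` (a haploid genome
#' at realistic error rates yields a near-empty spectrum).
#'
#' @param spectrum an [allele_frequency_spectrum()].
#' @param peak_window inclusive percent window around the heterozygous
#'   peak, default `c(40, 60)`.
#' @param mass_threshold minimum fraction of spectrum mass in the window
#'   for a diploid call (default 0.5).
#' @param min_sites minimum spectrum size for a confident call (default
#'   100).
#' @return List with `call` (`"haploid"`, `"diploid"` or
#'   `"indeterminate"`), `mass_fraction` and `n_sites`.
#' @export
classify_ploidy <- function(spectrum, peak_window = c(40L, 60L),
                            mass_threshold = 0.5, min_sites = 100L) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  n <- spectrum$n_variant_sites
  inside <- spectrum$bins >= peak_window[1L] &
    spectrum$bins <= peak_window[2L]
  mass <- if (n > 0) sum(spectrum$counts[inside]) / n else NA_real_
  call <- if (n < min_sites) "indeterminate"
  else if (mass >= mass_threshold) "diploid"
  else "haploid"
  list(call = call, mass_fraction = mass, n_sites = n)
}

#' Read a per-site read-count table
#'
#' @param path TSV with header columns `contig`, `pos`, `ref_count`,
#'   `alt_count`.
#' @return The site `data.frame`.
#' @export
read_site_counts <- function(path) {
  sites <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref_count", "alt_count")
  if (!all(need %in% names(sites)))
    stop("site table must have columns ", paste(need, collapse = ", "))
  if (any(sites$pos < 1)) stop("positions must be 1-based (>= 1)")
  if (any(sites$ref_count < 0 | sites$alt_count < 0))
    stop("read counts must be non-negative")
  sites
}
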