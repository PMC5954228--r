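# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the implementations under test.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_protein_str <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Exhaustive affine-gap local-alignment score by the textbook three-matrix
# recurrence (score only).
sw_score_oracle <- function(a, b, sm, gap_open, gap_extend) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  FF <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(E[i - 1, j] - gap_extend,
                     H[i - 1, j] - gap_open - gap_extend)
      FF[i, j] <- max(FF[i, j - 1] - gap_extend,
                      H[i, j - 1] - gap_open - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + sm[A[i - 1], B[j - 1]],
                     E[i, j], FF[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Whole-graph dense MCL reference: same update rules, single matrix over
# all nodes, components found by breadth-first search (no graph library).
mcl_oracle <- function(nodes, edges, inflation = 2, max_iter = 100,
                       tol = 1e-6, prune = 1e-8) {
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    W[cbind(edges$from, edges$to)] <- edges$weight
    W[cbind(edges$to, edges$from)] <- edges$weight
  }
  mx <- apply(W, 2, max)
  mx[mx <= 0] <- 1
  diag(W) <- mx
  M <- sweep(W, 2, colSums(W), "/")
  for (it in seq_len(max_iter)) {
    M2 <- (M %*% M)^inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    dead <- cs == 0
    if (any(dead)) {
      M2[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  A <- (M > prune) | t(M > prune)
  diag(A) <- TRUE
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      queue <- c(queue, which(A[v, ] & !seen))
    }
    comps[[length(comps) + 1]] <- sort(nodes[comp])
  }
  comps
}

# Canonical form of a partition (list of member vectors) for comparison.
canonical_partition <- function(members) {
  members <- lapply(unname(members), function(x) sort(unname(x)))
  members[order(vapply(members, `[`, character(1), 1L))]
}

# Group table -> partition.
groups_to_partition <- function(groups) {
  canonical_partition(unname(split(groups$seq_id, groups$group_id)))
}

# Brute-force reciprocal-best-hit enumeration by explicit loops.
rbh_oracle <- function(hits, taxon_map, taxon_a, taxon_b, cutoff = 1e-5) {
  tax <- setNames(taxon_map$taxon, taxon_map$seq_id)
  h <- hits[hits$evalue <= cutoff, , drop = FALSE]
  best <- function(qid, to) {
    rows <- h[h$qseqid == qid & tax[h$sseqid] == to, , drop = FALSE]
    if (nrow(rows) == 0) return(NA_character_)
    rows <- rows[order(rows$evalue, -rows$bitscore, rows$sseqid), ,
                 drop = FALSE]
    rows$sseqid[1]
  }
  a_ids <- taxon_map$seq_id[taxon_map$taxon == taxon_a]
  out <- list()
  for (qa in a_ids) {
    ba <- best(qa, taxon_b)
    if (is.na(ba)) next
    if (identical(best(ba, taxon_a), qa))
      out[[length(out) + 1]] <- c(qa, ba)
  }
  if (!length(out))
    return(data.frame(id_a = character(), id_b = character(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  data.frame(id_a = m[, 1], id_b = m[, 2], stringsAsFactors = FALSE)
}

# Random hit table between two taxa; E-values/bit scores drawn at the
# precision the tabular writer preserves.
random_hit_table <- function(n_q, n_s, n_hits, seed) {
  set.seed(seed)
  q <- sprintf("a%02d", sample.int(n_q, n_hits, replace = TRUE))
  s <- sprintf("b%02d", sample.int(n_s, n_hits, replace = TRUE))
  keep <- !duplicated(paste(q, s))
  q <- q[keep]; s <- s[keep]
  n <- length(q)
  data.frame(qseqid = q, sseqid = s,
             pident = round(runif(n, 20, 100), 2),
             length = sample(10:500, n, replace = TRUE),
             mismatch = sample(0:50, n, replace = TRUE),
             gapopen = sample(0:5, n, replace = TRUE),
             qstart = sample(1:50, n, replace = TRUE),
             qend = sample(51:500, n, replace = TRUE),
             sstart = sample(1:50, n, replace = TRUE),
             send = sample(51:500, n, replace = TRUE),
             evalue = 10^runif(n, -180, -2),
             bitscore = round(runif(n, 30, 500), 1),
             stringsAsFactors = FALSE)
}

# Random genome-match tables (flattened show-coords layout).
mk_matches <- function(n, seed = 1) {
  set.seed(seed)
  len <- sample(100:5000, n, replace = TRUE)
  start <- cumsum(c(1, len[-n] + 10))
  data.frame(ref_start = start, ref_end = start + len - 1,
             qry_start = start, qry_end = start + len - 1,
             ref_len = len, qry_len = len,
             pct_identity = round(runif(n, 70, 100), 2))
}

# Small three-guild-plus-control simulation used across module tests.
small_design <- function(seed = 11, n_background = 6, n_planted = 2) {
  fiscog_design(n_background = n_background, n_planted = n_planted,
                n_commensal = 3, n_pathogenA = 2, n_pathogenB = 2,
                n_control = 2, seed = seed)
}

guild_proteomes <- function(sim, guild) {
  sim$proteomes[sim$taxa$taxon[sim$taxa$guild == guild]]
}
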