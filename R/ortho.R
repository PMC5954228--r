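#' Reciprocal best hits between two taxa
#'
#' A pair `(a, b)` is reported iff `b` is `a`'s best subject in
#' `taxon_b` and `a` is `b`'s best subject in `taxon_a`, both with E-value
#' at or below the cutoff. "Best" ranks by lowest E-value, then highest bit
#' score, then lexicographically smallest subject ID, so the best hit is
#' always unique.
#'
#' @param hits a 12-column hit table ([all_vs_all()] / [read_hit_table()]).
#' @param taxon_map `data.frame` with columns `seq_id`, `taxon`.
#' @param taxon_a,taxon_b taxon labels present in `taxon_map`.
#' @param evalue_cutoff maximum E-value for an eligible hit.
#' @return `data.frame` with columns `id_a`, `id_b`; each ID appears in at
#'   most one pair.
#' @export
reciprocal_best_hits <- function(hits, taxon_map, taxon_a, taxon_b,
                                 evalue_cutoff = 1e-5) {
  stopifnot(is.data.frame(taxon_map),
            all(c("seq_id", "taxon") %in% names(taxon_map)))
  if (!taxon_a %in% taxon_map$taxon) stop("unknown taxon: ", taxon_a)
  if (!taxon_b %in% taxon_map$taxon) stop("unknown taxon: ", taxon_b)
  tax <- stats::setNames(taxon_map$taxon, taxon_map$seq_id)
  h <- hits[hits$evalue <= evalue_cutoff &
              !is.na(tax[hits$qseqid]) & !is.na(tax[hits$sseqid]), ,
            drop = FALSE]
  best_of <- function(from, to) {
    sub <- h[tax[h$qseqid] == from & tax[h$sseqid] == to, , drop = FALSE]
    if (nrow(sub) == 0L) return(character(0))
    sub <- sub[order(sub$qseqid, sub$evalue, -sub$bitscore, sub$sseqid), ,
               drop = FALSE]
    keep <- !duplicated(sub$qseqid)
    stats::setNames(sub$sseqid[keep], sub$qseqid[keep])
  }
  ab <- best_of(taxon_a, taxon_b)
  ba <- best_of(taxon_b, taxon_a)
  a_ids <- names(ab)
  mutual <- a_ids[!is.na(ba[ab[a_ids]]) & ba[ab[a_ids]] == a_ids]
  data.frame(id_a = mutual, id_b = unname(ab[mutual]),
             stringsAsFactors = FALSE)
}

#' Assemble multi-taxon families from pairwise RBH pairs
#'
#' Families are the connected components (single linkage) of the union of
#' all pairwise reciprocal-best-hit pairs. Group IDs are deterministic:
#' groups are ordered by their lexicographically smallest member.
#'
#' @param pairs a `data.frame` with columns `id_a`, `id_b` (the union of
#'   pairwise RBH sets), or a list of such data frames.
#' @param taxon_map `data.frame` with columns `seq_id`, `taxon`.
#' @return An ortholog group table: `data.frame` with columns `group_id`,
#'   `taxon`, `seq_id`.
#' @export
rbh_families <- function(pairs, taxon_map) {
  if (is.data.frame(pairs)) pairs <- list(pairs)
  edges <- do.call(rbind, lapply(pairs, function(p)
    data.frame(id_a = p$id_a, id_b = p$id_b, stringsAsFactors = FALSE)))
  if (is.null(edges) || nrow(edges) == 0L)
    return(data.frame(group_id = character(), taxon = character(),
                      seq_id = character(), stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  make_group_table(members, taxon_map)
}

# Order groups by smallest member, assign zero-padded IDs, emit long table.
make_group_table <- function(members, taxon_map) {
  members <- lapply(members, sort)
  members <- members[order(vapply(members, `[`, character(1), 1L))]
  tax <- stats::setNames(taxon_map$taxon, taxon_map$seq_id)
  n <- length(members)
  width <- max(4L, nchar(n))
  ids <- sprintf("OG%0*d", width, seq_len(n))
  out <- data.frame(
    group_id = rep(ids, lengths(members)),
    seq_id = unlist(members, use.names = FALSE),
    stringsAsFactors = FALSE)
  out$taxon <- unname(tax[out$seq_id])
  if (anyNA(out$taxon))
    stop("sequence(s) missing from taxon map: ",
         paste(utils::head(out$seq_id[is.na(out$taxon)], 5), collapse = ", "))
  out[, c("group_id", "taxon", "seq_id")]
}

#' Build the undirected similarity graph used for Markov clustering
#'
#' One undirected edge per unordered sequence pair with an eligible hit;
#' the edge weight is `-log10` of the smallest E-value over both hit
#' directions, with E-values floored at `1e-200` so the weight never
#' exceeds 200. Pairs whose best E-value exceeds the cutoff get no edge, so
#' all weights are at least `-log10(cutoff)`.
#'
#' @param hits a 12-column hit table.
#' @param taxon_map `data.frame` with columns `seq_id`, `taxon`; every
#'   sequence in the map becomes a node (isolated nodes allowed).
#' @param evalue_cutoff maximum E-value for an edge.
#' @return An object of class `similarity_graph`: list with `nodes`
#'   (`data.frame`: `seq_id`, `taxon`) and `edges` (`data.frame`: `from`,
#'   `to`, `weight`, with `from < to`).
#' @export
build_similarity_graph <- function(hits, taxon_map, evalue_cutoff = 1e-5) {
  stopifnot(all(c("seq_id", "taxon") %in% names(taxon_map)))
  h <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  if (nrow(h) > 0L) {
    a <- pmin(h$qseqid, h$sseqid)
    b <- pmax(h$qseqid, h$sseqid)
    key <- paste(a, b, sep = "\r")
    emin <- tapply(h$evalue, key, min)
    keep <- emin <= evalue_cutoff
    emin <- emin[keep]
    ab <- strsplit(names(emin), "\r", fixed = TRUE)
    edges <- data.frame(
      from = vapply(ab, `[`, character(1), 1L),
      to = vapply(ab, `[`, character(1), 2L),
      weight = -log10(pmax(emin, 1e-200)),
      stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  unknown <- setdiff(c(edges$from, edges$to), taxon_map$seq_id)
  if (length(unknown))
    stop("hit sequence(s) missing from taxon map: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  nodes <- data.frame(seq_id = taxon_map$seq_id, taxon = taxon_map$taxon,
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$seq_id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' Markov clustering (MCL) of the similarity graph
#'
#' Implements the Markov Cluster algorithm: self-loops are added with
#' weight equal to each node's maximum incident edge weight (1 for isolated
#' nodes), columns are normalised to a stochastic matrix, and expansion
#' (matrix self-multiplication) alternates with inflation (entrywise power
#' `inflation`, then column renormalisation) until the largest entry change
#' falls below `tol` or `max_iter` is reached. Clusters are the connected
#' components of the converged matrix's nonzero pattern (entries below
#' `prune` count as zero). Because random-walk flow never crosses graph
#' components, the iteration runs independently per connected component;
#' the result does not depend on node input order.
#'
#' @param graph a [build_similarity_graph()] result.
#' @param inflation entrywise-power parameter (> 1 for contraction;
#'   default 2, the `mcl` program's convention).
#' @param max_iter,tol iteration controls.
#' @param prune entries below this are treated as zero (numerical support
#'   of the limit matrix).
#' @return An ortholog group table (`group_id`, `taxon`, `seq_id`) covering
#'   every node exactly once.
#' @export
mcl_cluster <- function(graph, inflation = 2, max_iter = 100L, tol = 1e-6,
                        prune = 1e-8) {
  stopifnot(inherits(graph, "similarity_graph"))
  if (inflation <= 0) stop("inflation must be positive")
  if (nrow(graph$nodes) == 0L) stop("empty graph")
  ids <- sort(graph$nodes$seq_id)
  # connected components of the input graph
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  wmap <- graph$edges
  clusters <- list()
  for (mem in members) {
    mem <- sort(mem)
    if (length(mem) == 1L) {
      clusters[[length(clusters) + 1L]] <- mem
      next
    }
    sub <- wmap[wmap$from %in% mem & wmap$to %in% mem, , drop = FALSE]
    W <- matrix(0, length(mem), length(mem), dimnames = list(mem, mem))
    W[cbind(sub$from, sub$to)] <- sub$weight
    W[cbind(sub$to, sub$from)] <- sub$weight
    part <- mcl_dense(W, inflation, max_iter, tol, prune)
    clusters <- c(clusters, part)
  }
  make_group_table(clusters, graph$nodes)
}

# Dense MCL iteration on one symmetric weight matrix (zero diagonal).
# Returns a list of character vectors (the clusters).
mcl_dense <- function(W, inflation, max_iter, tol, prune) {
  n <- nrow(W)
  loop <- apply(W, 2L, max)
  loop[loop <= 0] <- 1
  diag(W) <- loop
  M <- sweep(W, 2L, colSums(W), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M          # expansion
    M2 <- M2^inflation     # inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    dead <- cs == 0
    if (any(dead)) {       # fully pruned column: restore a self-loop
      M2[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    M2 <- sweep(M2, 2L, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  A <- (M > prune) | t(M > prune)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  unname(split(rownames(W), comp$membership))
}

#' Per-taxon cluster representatives by graph connectivity
#'
#' For each group and each taxon with at least one member, selects the
#' member with the greatest total edge weight (`-log10` E-value weights)
#' to all other group members, within- and cross-taxon alike. Ties break
#' to the lexicographically smallest sequence ID.
#'
#' @param groups an ortholog group table (`group_id`, `taxon`, `seq_id`).
#' @param graph the [build_similarity_graph()] the groups were derived from.
#' @return `data.frame` with columns `group_id`, `taxon`, `seq_id` — one
#'   row per (group, taxon).
#' @export
select_representatives <- function(groups, graph) {
  stopifnot(inherits(graph, "similarity_graph"))
  missing <- setdiff(groups$seq_id, graph$nodes$seq_id)
  if (length(missing))
    stop("group member(s) not in graph: ",
         paste(utils::head(missing, 5), collapse = ", "))
  conn <- group_connectivity(groups, graph)
  conn <- conn[order(conn$group_id, conn$taxon, -conn$connectivity,
                     conn$seq_id), , drop = FALSE]
  keep <- !duplicated(conn[, c("group_id", "taxon")])
  out <- conn[keep, c("group_id", "taxon", "seq_id"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# Sum of edge weights from each member to the other members of its group.
group_connectivity <- function(groups, graph) {
  grp <- stats::setNames(groups$group_id, groups$seq_id)
  e <- graph$edges
  same <- !is.na(grp[e$from]) & !is.na(grp[e$to]) &
    grp[e$from] == grp[e$to]
  e <- e[same, , drop = FALSE]
  w <- tapply(c(e$weight, e$weight), c(e$from, e$to), sum)
  conn <- groups
  conn$connectivity <- ifelse(is.na(w[conn$seq_id]), 0,
                              as.numeric(w[conn$seq_id]))
  conn
}

#' One representative sequence per group
#'
#' Like [select_representatives()] but taxon-blind: the single member of
#' each group with the greatest total connectivity to the rest of the
#' group (ties to the smallest ID). This is the family-level unit used for
#' cross-guild comparison and enrichment counting.
#'
#' @inheritParams select_representatives
#' @return `data.frame` with columns `group_id`, `seq_id`.
#' @export
select_group_representative <- function(groups, graph) {
  conn <- group_connectivity(groups, graph)
  conn <- conn[order(conn$group_id, -conn$connectivity, conn$seq_id), ,
               drop = FALSE]
  keep <- !duplicated(conn$group_id)
  out <- conn[keep, c("group_id", "seq_id"), drop = FALSE]
  rownames(out) <- NULL
  out
}
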