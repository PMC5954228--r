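# Helpers to build tiny hit tables by hand: only the columns the orthology
# stage reads (IDs, evalue, bitscore) need meaningful values.
mk_hits <- function(q, s, e, b = -log10(e)) {
  data.frame(qseqid = q, sseqid = s, pident = 90, length = 100,
             mismatch = 10, gapopen = 0, qstart = 1, qend = 100,
             sstart = 1, send = 100, evalue = e, bitscore = b,
             stringsAsFactors = FALSE)
}

test_that("reciprocal best hits require mutual top ranking", {
  tm <- data.frame(seq_id = c("a1", "a2", "b1", "b2"),
                   taxon = rep(c("A", "B"), each = 2))
  # mutual best: a1 <-> b1
  h <- mk_hits(c("a1", "b1"), c("b1", "a1"), c(1e-50, 1e-48))
  expect_identical(reciprocal_best_hits(h, tm, "A", "B"),
                   data.frame(id_a = "a1", id_b = "b1",
                              stringsAsFactors = FALSE))
  # reciprocity violated: a1's best is b1 but b1's best is a2
  h <- mk_hits(c("a1", "b1", "b1", "a2"), c("b1", "a2", "a1", "b1"),
               c(1e-50, 1e-60, 1e-40, 1e-55))
  rb <- reciprocal_best_hits(h, tm, "A", "B")
  expect_false(any(rb$id_a == "a1" & rb$id_b == "b1"))
  expect_error(reciprocal_best_hits(h, tm, "A", "Z"), "unknown taxon")
})

test_that("reciprocal best hits equal brute-force mutual-argmax enumeration", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 20
    tm <- data.frame(seq_id = c(sprintf("a%02d", 1:n), sprintf("b%02d", 1:n)),
                     taxon = rep(c("A", "B"), each = n))
    nh <- 120
    q <- sprintf("a%02d", sample.int(n, nh, replace = TRUE))
    s <- sprintf("b%02d", sample.int(n, nh, replace = TRUE))
    h <- mk_hits(c(q, s), c(s, q), 10^-sample(3:80, 2 * nh, replace = TRUE))
    got <- reciprocal_best_hits(h, tm, "A", "B")
    want <- rbh_oracle(h, tm, "A", "B")
    expect_identical(got[order(got$id_a), ], want[order(want$id_a), ],
                     ignore_attr = TRUE)
    # one-to-one: no ID participates in two pairs
    expect_false(anyDuplicated(got$id_a) > 0)
    expect_false(anyDuplicated(got$id_b) > 0)
  }
})

test_that("multi-taxon families are connected components of RBH pairs", {
  tm <- data.frame(seq_id = c("a1", "a2", "b1", "c1"),
                   taxon = c("A", "A", "B", "C"))
  pairs <- data.frame(id_a = c("a1", "b1"), id_b = c("b1", "c1"),
                      stringsAsFactors = FALSE)
  fam <- rbh_families(pairs, tm)
  expect_identical(length(unique(fam$group_id)), 1L)
  expect_setequal(fam$seq_id, c("a1", "b1", "c1"))

  pairs2 <- data.frame(id_a = c("a1", "a2"), id_b = c("b1", "c1"),
                       stringsAsFactors = FALSE)
  fam2 <- rbh_families(pairs2, tm)
  expect_identical(length(unique(fam2$group_id)), 2L)

  # random pair sets against an independent union-find
  for (seed in 1:5) {
    set.seed(seed)
    ids <- sprintf("s%02d", 1:30)
    tmr <- data.frame(seq_id = ids, taxon = "T")
    pr <- data.frame(id_a = sample(ids, 25, replace = TRUE),
                     id_b = sample(ids, 25, replace = TRUE),
                     stringsAsFactors = FALSE)
    pr <- pr[pr$id_a != pr$id_b, ]
    got <- groups_to_partition(rbh_families(pr, tmr))
    # union-find oracle
    parent <- setNames(ids, ids)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    for (k in seq_len(nrow(pr)))
      parent[[find(pr$id_a[k])]] <- find(pr$id_b[k])
    root <- vapply(ids, find, character(1))
    touched <- unique(c(pr$id_a, pr$id_b))
    want <- canonical_partition(
      Filter(function(g) length(g) > 0,
             split(touched, root[touched])))
    expect_identical(got, want)
  }
})

test_that("similarity graph applies the min-E, floor and cutoff rules", {
  tm <- data.frame(seq_id = c("A1", "B1", "C1", "D1"),
                   taxon = c("A", "B", "C", "D"))
  h <- mk_hits(c("A1", "B1", "A1", "A1"),
               c("B1", "A1", "C1", "D1"),
               c(1e-10, 1e-12, 1e-4, 0))
  g <- build_similarity_graph(h, tm, evalue_cutoff = 1e-5)
  # min-E rule over directions: -log10(1e-12) = 12
  e_ab <- g$edges[g$edges$from == "A1" & g$edges$to == "B1", ]
  expect_equal(e_ab$weight, 12)
  # E above cutoff: no edge
  expect_false(any(g$edges$from == "A1" & g$edges$to == "C1"))
  # floor at 1e-200: weight 200
  e_ad <- g$edges[g$edges$from == "A1" & g$edges$to == "D1", ]
  expect_equal(e_ad$weight, 200)
  # cutoff guarantee: all weights >= 5
  expect_true(all(g$edges$weight >= 5))
})

test_that("edge set grows monotonically with the E-value cutoff", {
  tab <- mk_hits(sprintf("q%d", 1:40),
                 sprintf("s%d", sample(1:40)),
                 10^-runif(40, 2, 60))
  tm <- data.frame(seq_id = unique(c(tab$qseqid, tab$sseqid)), taxon = "T")
  cuts <- c(1e-20, 1e-10, 1e-5, 1e-2)
  edge_keys <- lapply(cuts, function(ct) {
    g <- build_similarity_graph(tab, tm, evalue_cutoff = ct)
    paste(g$edges$from, g$edges$to)
  })
  for (i in seq_len(length(cuts) - 1))
    expect_true(all(edge_keys[[i]] %in% edge_keys[[i + 1]]))
})

test_that("MCL separates obvious components and matches the dense oracle", {
  # two disconnected triangles
  tm <- data.frame(seq_id = c("a", "b", "c", "x", "y", "z"), taxon = "T")
  h <- mk_hits(c("a", "b", "a", "x", "y", "x"),
               c("b", "c", "c", "y", "z", "z"), rep(1e-20, 6))
  g <- build_similarity_graph(h, tm)
  cl <- mcl_cluster(g)
  expect_identical(groups_to_partition(cl),
                   list(c("a", "b", "c"), c("x", "y", "z")))
  # single edge
  tm2 <- data.frame(seq_id = c("a", "b"), taxon = "T")
  g2 <- build_similarity_graph(mk_hits("a", "b", 1e-30), tm2)
  expect_identical(groups_to_partition(mcl_cluster(g2)), list(c("a", "b")))

  # 30-node random graphs vs whole-graph dense reference
  for (seed in 1:5) {
    set.seed(seed)
    ids <- sprintf("n%02d", 1:30)
    ne <- 45
    e <- data.frame(from = sample(ids, ne, replace = TRUE),
                    to = sample(ids, ne, replace = TRUE),
                    stringsAsFactors = FALSE)
    e <- e[e$from != e$to, ]
    e$evalue <- 10^-sample(6:60, nrow(e), replace = TRUE)
    h <- mk_hits(e$from, e$to, e$evalue)
    tmr <- data.frame(seq_id = ids, taxon = "T")
    g <- build_similarity_graph(h, tmr)
    got <- groups_to_partition(mcl_cluster(g))
    want <- canonical_partition(mcl_oracle(sort(ids), g$edges))
    expect_identical(got, want, label = paste("seed", seed))
  }
})

test_that("MCL output is a partition and never merges graph components", {
  set.seed(77)
  ids <- sprintf("n%02d", 1:24)
  e <- data.frame(from = sample(ids, 30, replace = TRUE),
                  to = sample(ids, 30, replace = TRUE))
  e <- e[e$from != e$to, ]
  h <- mk_hits(e$from, e$to, 10^-sample(6:40, nrow(e), replace = TRUE))
  tm <- data.frame(seq_id = ids, taxon = "T")
  g <- build_similarity_graph(h, tm)
  cl <- mcl_cluster(g)
  expect_setequal(cl$seq_id, ids)                 # coverage
  expect_identical(anyDuplicated(cl$seq_id), 0L)  # disjointness
  # each cluster lies within one input-graph component
  ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = FALSE,
                                      vertices = ids)
  comp <- igraph::components(ig)$membership
  for (grp in split(cl$seq_id, cl$group_id))
    expect_identical(length(unique(comp[grp])), 1L)
})

test_that("representative selection maximises connectivity with lexicographic
           ties", {
  tm <- data.frame(seq_id = c("a1", "a2", "b1", "b2"),
                   taxon = c("A", "A", "B", "B"))
  # a1 strongly connected, a2 weakly
  h <- mk_hits(c("a1", "a1", "a2"), c("b1", "b2", "b1"),
               c(1e-30, 1e-30, 1e-10))
  g <- build_similarity_graph(h, tm)
  groups <- data.frame(group_id = "OG0001",
                       taxon = c("A", "A", "B", "B"),
                       seq_id = c("a1", "a2", "b1", "b2"),
                       stringsAsFactors = FALSE)
  reps <- select_representatives(groups, g)
  expect_identical(reps$seq_id[reps$taxon == "A"], "a1")
  # exact tie -> lexicographically smallest
  h2 <- mk_hits(c("a1", "a2"), c("b1", "b1"), c(1e-30, 1e-30))
  g2 <- build_similarity_graph(h2, tm)
  reps2 <- select_representatives(groups, g2)
  expect_identical(reps2$seq_id[reps2$taxon == "A"], "a1")

  # random clusters: equals brute-force weight-sum maximisation
  set.seed(12)
  for (r in 1:5) {
    ids <- sprintf("%s%d", rep(c("a", "b", "c"), each = 4), 1:4)
    tmr <- data.frame(seq_id = ids, taxon = rep(c("A", "B", "C"), each = 4))
    e <- t(combn(ids, 2))
    keep <- runif(nrow(e)) < 0.5
    h <- mk_hits(e[keep, 1], e[keep, 2],
                 10^-sample(6:50, sum(keep), replace = TRUE))
    g <- build_similarity_graph(h, tmr)
    grp <- data.frame(group_id = "OG0001", taxon = tmr$taxon, seq_id = ids,
                      stringsAsFactors = FALSE)
    reps <- select_representatives(grp, g)
    wsum <- sapply(ids, function(i) {
      e2 <- g$edges
      sum(e2$weight[e2$from == i | e2$to == i])
    })
    for (t in c("A", "B", "C")) {
      members <- ids[tmr$taxon == t]
      best <- members[order(-wsum[members], members)][1]
      expect_identical(reps$seq_id[reps$taxon == t], best)
    }
  }
})
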