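test_that("presence matrix counts copies per taxon", {
  groups <- data.frame(group_id = c("g1", "g1", "g1"),
                       taxon = c("A", "A", "B"),
                       seq_id = c("a1", "a2", "b1"),
                       stringsAsFactors = FALSE)
  m <- presence_matrix(groups, c("A", "B", "C"))
  expect_identical(unname(m["g1", ]), c(2L, 1L, 0L))
  expect_identical(nrow(presence_matrix(groups[0, ], c("A", "B"))), 0L)
  expect_error(presence_matrix(groups, c("A")), "unlisted taxa")
})

test_that("presence matrix reproduces the simulator's ground truth", {
  d <- small_design(seed = 31)
  sim <- simulate_proteomes(d)
  groups <- data.frame(group_id = sim$truth$family_id,
                       taxon = sim$truth$taxon,
                       seq_id = sim$truth$seq_id, stringsAsFactors = FALSE)
  m <- presence_matrix(groups, sim$taxa$taxon)
  truth_counts <- table(sim$truth$family_id, sim$truth$taxon)
  expect_identical(unname(m[rownames(truth_counts), colnames(truth_counts)]),
                   unname(matrix(as.integer(truth_counts),
                                 nrow(truth_counts))))
})

test_that("missing-taxon-tolerant cores follow the at-least-(N-k) rule", {
  m <- matrix(0L, 3, 9, dimnames = list(c("g6", "g5", "g9"),
                                        paste0("t", 1:9)))
  m["g6", 1:6] <- 1L   # present in 6 of 9
  m["g5", 1:5] <- 1L   # present in 5 of 9
  m["g9", ] <- 1L
  core <- shared_genes(m, paste0("t", 1:9), max_missing = 3)
  expect_true("g6" %in% core)    # 6-of-9 boundary: included
  expect_false("g5" %in% core)   # 5-of-9: excluded
  expect_true("g9" %in% core)

  # brute-force oracle over random matrices and all tolerances
  set.seed(41)
  for (r in 1:5) {
    mm <- matrix(rbinom(50 * 9, 2, 0.4), 50, 9,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("t", 1:9)))
    for (k in 0:8) {
      got <- shared_genes(mm, paste0("t", 1:9), max_missing = k)
      want <- rownames(mm)[vapply(seq_len(50), function(i)
        sum(mm[i, ] >= 1) >= 9 - k, logical(1))]
      expect_identical(got, want)
    }
  }
})

test_that("core size is nondecreasing in the missing-taxon tolerance", {
  set.seed(43)
  m <- matrix(rbinom(40 * 9, 1, 0.6), 40, 9,
              dimnames = list(sprintf("g%02d", 1:40), paste0("t", 1:9)))
  sizes <- vapply(0:8, function(k)
    length(shared_genes(m, paste0("t", 1:9), max_missing = k)), integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("Venn partitions tally every lattice region exactly", {
  v <- venn_partition(list(X = c("a", "b"), Y = c("b", "c"), Z = "b"))
  expect_identical(unname(v["X&Y&Z"]), 1L)  # b
  expect_identical(unname(v["X"]), 1L)      # a
  expect_identical(sum(v), 3L)              # |union|

  d <- venn_partition(list(X = c("a", "b"), Y = c("c", "d")))
  expect_identical(unname(d["X&Y"]), 0L)
  expect_error(venn_partition(list(a = "x")), "2 to 4")

  # bit-vector oracle on random sets
  set.seed(47)
  for (r in 1:5) {
    k <- sample(2:4, 1)
    sets <- setNames(lapply(seq_len(k), function(i)
      sample(letters, sample(5:15, 1))), LETTERS[seq_len(k)])
    v <- venn_partition(sets)
    expect_identical(sum(v), length(unique(unlist(sets))))
    univ <- unique(unlist(sets))
    for (region in names(v)) {
      inset <- strsplit(region, "&", fixed = TRUE)[[1]]
      outset <- setdiff(names(sets), inset)
      want <- sum(vapply(univ, function(el)
        all(vapply(sets[inset], function(s) el %in% s, logical(1))) &&
          !any(vapply(sets[outset], function(s) el %in% s, logical(1))),
        logical(1)))
      expect_identical(unname(v[region]), as.integer(want), label = region)
    }
  }
})

test_that("negative-control subtraction partitions the candidate set", {
  set.seed(53)
  fam_seq <- setNames(replicate(6, random_protein_str(50)),
                      paste0("f", 1:6))
  # pathogen cores hold diverged homologs of every family
  div <- function(s) mutate_protein(s, 5L)
  pa <- setNames(vapply(fam_seq, div, character(1)), paste0("pa_", 1:6))
  pb <- setNames(vapply(fam_seq, div, character(1)), paste0("pb_", 1:6))
  # controls hold homologs of families 1-4 only
  ctl <- list(ctl1 = setNames(vapply(fam_seq[1:4], div, character(1)),
                              paste0("c", 1:4)))
  rep <- fiscog_identify(fam_seq, pa, pb, ctl)
  expect_setequal(rep$candidates, paste0("f", 1:6))
  expect_setequal(rep$surviving, c("f5", "f6"))
  expect_setequal(rep$removed_by_control$family_id, paste0("f", 1:4))
  # conservation
  expect_identical(length(rep$candidates),
                   length(rep$surviving) + nrow(rep$removed_by_control))
  expect_identical(rep$removed_by_control$control_taxon,
                   rep("ctl1", 4))
  # empty subtraction: no control homologs at all
  ctl0 <- list(ctl1 = c(u1 = random_protein_str(80)))
  rep0 <- fiscog_identify(fam_seq, pa, pb, ctl0)
  expect_setequal(rep0$surviving, rep0$candidates)
  # total subtraction: controls contain every family
  ctl_all <- list(ctl1 = setNames(vapply(fam_seq, div, character(1)),
                                  paste0("c", 1:6)))
  rep_all <- fiscog_identify(fam_seq, pa, pb, ctl_all)
  expect_identical(rep_all$surviving, character(0))
  expect_error(fiscog_identify(setNames("", "f1"), pa, pb, ctl),
               "without representative")
})

test_that("adding control sequences never increases the surviving set", {
  set.seed(59)
  fam_seq <- setNames(replicate(5, random_protein_str(50)), paste0("f", 1:5))
  div <- function(s) mutate_protein(s, 5L)
  pa <- setNames(vapply(fam_seq, div, character(1)), paste0("pa", 1:5))
  pb <- setNames(vapply(fam_seq, div, character(1)), paste0("pb", 1:5))
  ctl1 <- list(c1 = setNames(div(fam_seq[[1]]), "x1"))
  ctl2 <- list(c1 = setNames(c(div(fam_seq[[1]]), div(fam_seq[[2]])),
                             c("x1", "x2")))
  s1 <- fiscog_identify(fam_seq, pa, pb, ctl1)$surviving
  s2 <- fiscog_identify(fam_seq, pa, pb, ctl2)$surviving
  expect_true(all(s2 %in% s1))
})

test_that("enrichment counts distinct in-family proteins per taxon", {
  set.seed(61)
  fam <- random_protein_str(50)
  reps <- setNames(fam, "g1")
  proteomes <- list(
    T1 = setNames(fam, "t1|g1|c1"),                     # the rep itself
    T2 = setNames(vapply(1:3, function(i) mutate_protein(fam, 4L),
                         character(1)),
                  paste0("t2|g1|c", 1:3)),              # 3 diverged copies
    T3 = setNames(random_protein_str(50), "t3|bg|c1"))  # unrelated
  m <- enrichment_matrix(reps, proteomes)
  expect_identical(unname(m["g1", ]), c(1L, 3L, 0L))
})

test_that("single-copy selection follows the small/large taxon rule", {
  m <- rbind(g1 = c(1, 1, 1, 1, 2, 0, 1, 1, 1),
             g2 = c(1, 1, 2, 1, 2, 2, 2, 2, 2),
             g3 = c(1, 1, 1, 1, 1, 1, 1, 1, 1))
  colnames(m) <- paste0("t", 1:9)
  small <- paste0("t", 1:4); large <- paste0("t", 5:9)
  sel <- single_copy_selection(m, small, large)
  expect_setequal(sel$single_copy_set, c("g1", "g3"))     # g2 small copy 2
  expect_identical(sel$duplication_candidate_set, "g1")   # g3 no dup
  expect_error(single_copy_selection(m, small, c("t4", "t5")), "disjoint")

  set.seed(67)
  for (r in 1:5) {
    mm <- matrix(rbinom(30 * 9, 3, 0.4), 30, 9,
                 dimnames = list(sprintf("g%02d", 1:30), paste0("t", 1:9)))
    sel <- single_copy_selection(mm, small, large)
    want_single <- rownames(mm)[apply(mm[, small] == 1, 1, all)]
    want_dup <- want_single[apply(mm[want_single, large, drop = FALSE] >= 2,
                                  1, any)]
    expect_identical(sel$single_copy_set, want_single)
    expect_identical(sel$duplication_candidate_set, want_dup)
  }
})

test_that("feature counts aggregate annotation tables", {
  ann <- data.frame(seq_id = c("s1", "s2", "s3", "s3"),
                    taxon = c("A", "A", "B", "B"),
                    feature_id = c("F", "F", "F", "G"),
                    stringsAsFactors = FALSE)
  m <- feature_count_matrix(ann)
  expect_identical(unname(m["F", ]), c(2L, 1L))
  expect_identical(unname(m["G", ]), c(0L, 1L))
  empty <- feature_count_matrix(ann[0, ])
  expect_identical(dim(empty), c(0L, 0L))
  expect_error(feature_count_matrix(data.frame(x = 1)), "columns")

  # tally oracle on random tables
  set.seed(71)
  ann <- data.frame(seq_id = sprintf("s%02d", sample(1:30, 100, TRUE)),
                    taxon = sample(c("A", "B", "C"), 100, TRUE),
                    feature_id = sample(c("F1", "F2", "F3", "F4"), 100, TRUE),
                    stringsAsFactors = FALSE)
  ann$seq_id <- paste(ann$taxon, ann$seq_id)  # gene IDs unique to a taxon
  m <- feature_count_matrix(ann)
  for (f in rownames(m)) for (t in colnames(m)) {
    want <- length(unique(ann$seq_id[ann$feature_id == f & ann$taxon == t]))
    expect_identical(m[f, t], as.integer(want))
  }
})

test_that("report writer emits the TSV/JSON bundle", {
  rep <- structure(list(candidates = c("f1", "f2"), surviving = "f2",
                        removed_by_control = data.frame(
                          family_id = "f1", control_taxon = "c1",
                          best_evalue = 1e-40, stringsAsFactors = FALSE)),
                   class = "fiscog_report")
  d <- file.path(tempdir(), "fiscog_report")
  write_fiscog_report(rep, d)
  expect_identical(readLines(file.path(d, "surviving.tsv")), "f2")
  js <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_identical(js$n_candidates, 2L)
  expect_identical(js$n_surviving, 1L)
  unlink(d, recursive = TRUE)
})
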