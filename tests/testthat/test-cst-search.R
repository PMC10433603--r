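# hand-built 4-leaf caterpillar-ish tree with small k-mer sets, used to
# exercise counting, BFS and path resolution without a full index
.toy_cst <- function() {
  tree <- data.frame(
    node_id = c("N1", "N2", "N3", "N4", "N5", "N6", "N7"),
    parent = c("N5", "N5", "N6", "N6", "N7", "N7", NA),
    left = c(NA, NA, NA, NA, "N1", "N3", "N5"),
    right = c(NA, NA, NA, NA, "N2", "N4", "N6"),
    depth = c(2L, 2L, 2L, 2L, 1L, 1L, 0L),
    is_leaf = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    cluster_id = c("C1", "C2", "C3", "C4", NA, NA, NA),
    stringsAsFactors = FALSE)
  rownames(tree) <- tree$node_id
  kms <- list(N1 = c("AAA", "AAC"), N2 = c("AAG", "AAT"),
              N3 = c("ACC", "ACG"), N4 = c("ACT", "AGA"),
              N5 = c("AGC", "AGG"), N6 = c("AGT", "ATA"),
              N7 = c("ATC", "ATG"))
  structure(list(tree = tree, node_kmers = kms,
                 augmented = setNames(vector("list", 7), tree$node_id),
                 k = 3L), class = "cst")
}

test_that("count assignment fills node vectors in stored k-mer order", {
  cst <- .toy_cst()
  counts <- structure(list(k = 3L, counts = setNames(
    c(5L, 7L), c("AAC", "AAA"))), class = "kmer_count_table")
  nc <- assign_counts(counts, cst)
  expect_identical(nc$N1, c(7L, 5L))      # node order AAA, AAC
  expect_true(all(unlist(nc[c("N2", "N3", "N4", "N5", "N6", "N7")]) == 0L))
  counts$k <- 5L
  expect_error(assign_counts(counts, cst), "k mismatch")
})

test_that("node scoring implements the matched fraction and its floor", {
  s <- score_node(c(0L, 0L, 5L, 7L))
  expect_equal(s$frac, 0.5)
  expect_equal(s$abund, 6.0)
  # 1/11 < 0.1 -> zero branch
  s <- score_node(c(1L, rep(0L, 10L)))
  expect_lt(s$frac, 0.1)
  expect_equal(s$abund, 0)
  # exactly at the floor the abundance is computed
  s <- score_node(c(3L, rep(0L, 9L)))
  expect_equal(s$frac, 0.1)
  expect_equal(s$abund, 3)
  expect_equal(score_node(c(0L, 0L))$abund, 0)
  expect_warning(s0 <- score_node(integer(0)), "empty")
  expect_equal(s0$frac, 0)
})

test_that("binomial stop test matches the exact CDF and its decision rule", {
  r <- binomial_stop_test(20, 20)
  expect_identical(r$decision, "traverse")
  expect_equal(r$p_value, 0.01^20, tolerance = 1e-10)
  r <- binomial_stop_test(20, 1)
  expect_identical(r$decision, "stop")
  expect_equal(r$p_value, 1 - 0.99^20, tolerance = 1e-12)
  # negative difference -> p = 0 -> traverse
  r <- binomial_stop_test(10, 12)
  expect_identical(r$decision, "traverse")
  expect_equal(r$p_value, 0)
  # half-up rounding of abundances
  r <- binomial_stop_test(2.5, 2.4)  # -> 3 vs 2, diff 1
  expect_equal(r$p_value, oracle_pbinom(1, 3, 0.99), tolerance = 1e-14)
  expect_error(binomial_stop_test(5, 5, e = 0), "\\(0, 1\\)")
  expect_error(binomial_stop_test(5, 5, beta = 1), "\\(0, 1\\)")
})

test_that("p-values match an independent exact-CDF oracle up to 200 trials", {
  for (ap in c(0:30, 50, 100, 150, 200)) {
    for (av in unique(pmin(ap, c(0L, 1L, 2L, ap %/% 2L, ap)))) {
      got <- binomial_stop_test(ap, av)$p_value
      expect_equal(got, oracle_pbinom(ap - av, ap, 0.99),
                   tolerance = 1e-12)
    }
  }
})

test_that("BFS visits exactly the supported subtrees", {
  cst <- .toy_cst()
  mk_counts <- function(vals) {
    ct <- setNames(rep(0L, 14L),
                   unlist(cst$node_kmers, use.names = FALSE))
    if (length(vals)) ct[names(vals)] <- vals
    lapply(cst$node_kmers, function(k) unname(ct[k]))
  }
  # strain in C1: its leaf, N5 and root carry signal
  nc <- mk_counts(c(AAA = 10L, AAC = 10L, AGC = 10L, AGG = 10L,
                    ATC = 10L, ATG = 10L))
  cands <- bfs_search(cst, nc)
  expect_identical(as.character(cands), "N1")
  # zero counts everywhere -> nothing
  expect_length(bfs_search(cst, mk_counts(c())), 0L)
  # two clusters under different internal nodes: both leaves returned
  nc <- mk_counts(c(AAA = 10L, AAC = 10L, AGC = 10L, AGG = 10L,
                    ACC = 12L, ACG = 12L, AGT = 12L, ATA = 12L,
                    ATC = 20L, ATG = 20L))
  expect_setequal(as.character(bfs_search(cst, nc)), c("N1", "N3"))
})

test_that("path resolution finds the maximal private subtree", {
  cst <- .toy_cst()
  # single candidate: full root-to-leaf path
  expect_identical(resolve_path(cst, "N1", "N1"), c("N7", "N5", "N1"))
  # sibling leaves both identified: each path shrinks to the leaf
  expect_identical(resolve_path(cst, "N1", c("N1", "N2")), "N1")
  # candidates in different wings: each keeps its wing's internal node
  expect_identical(resolve_path(cst, "N1", c("N1", "N3")), c("N5", "N1"))
  expect_identical(resolve_path(cst, "N3", c("N1", "N3")), c("N6", "N3"))
  expect_error(resolve_path(cst, "N2", "N1"), "candidates")
})

test_that("path resolution matches brute-force subtree enumeration", {
  cst <- .toy_cst()
  tree <- cst$tree
  leaves <- tree$node_id[tree$is_leaf]
  nodes_below <- function(v) {
    acc <- v; stack <- v
    while (length(stack)) {
      u <- stack[[1]]; stack <- stack[-1]
      kids <- c(tree[u, "left"], tree[u, "right"])
      kids <- kids[!is.na(kids)]
      acc <- c(acc, kids); stack <- c(stack, kids)
    }
    unique(acc)
  }
  path_up <- function(from, to) {  # node ids from `to` down to `from`
    p <- from; v <- from
    while (v != to) { v <- tree[v, "parent"]; p <- c(v, p) }
    p
  }
  set.seed(2)
  for (rep in 1:10) {
    cands <- sample(leaves, sample(2:4, 1L))
    for (lf in cands) {
      # oracle: deepest-rooted subtree containing lf and no other candidate
      best <- lf
      for (v in tree$node_id) {
        nb <- nodes_below(v)
        if (lf %in% nb && !any(setdiff(cands, lf) %in% nb) &&
            length(nb) > length(nodes_below(best)))
          best <- v
      }
      expect_identical(resolve_path(cst, lf, cands), path_up(lf, best))
    }
  }
})

test_that("leaf statistics pool path nodes and apply the acceptance cutoff", {
  cst <- .toy_cst()
  # two path nodes with (|C+|, |C|, abund) = (8,10,10) and (2,10,5):
  # F = 10/20, A = (8*10 + 2*5)/10 = 9; build counts realising these
  cst$node_kmers$N1 <- sprintf("K%02d", 1:10)
  cst$node_kmers$N5 <- sprintf("L%02d", 1:10)
  nc <- list(N1 = c(rep(10L, 8L), 0L, 0L), N5 = c(5L, 5L, rep(0L, 8L)))
  hit <- leaf_statistics(cst, "N1", c("N5", "N1"), nc, F_cutoff = 0.4)
  expect_equal(hit$F, 0.5)
  expect_equal(hit$A, 9.0)
  expect_identical(hit$cluster_id, "C1")
  # F at 0.39 with the default cutoff 0.4 -> rejected
  nc2 <- list(N1 = c(rep(1L, 39L), rep(0L, 61L)))
  expect_null(leaf_statistics(cst, "N1", "N1", nc2, F_cutoff = 0.4))
  # adjustment is the identity when no k-mers are shared with other hits
  oh <- list(list(cluster_id = "C9", A = 50, kmers = c("ZZZ")))
  hit2 <- leaf_statistics(cst, "N1", c("N5", "N1"), nc, other_hits = oh,
                          F_cutoff = 0.4)
  expect_equal(hit2$F, hit$F)
  expect_equal(hit2$A, hit$A)
  # shared k-mers are corrected by the other cluster's abundance
  oh <- list(list(cluster_id = "C9", A = 10, kmers = c("L01", "L02")))
  hit3 <- leaf_statistics(cst, "N1", c("N5", "N1"), nc, other_hits = oh,
                          F_cutoff = 0.1)
  expect_equal(hit3$F, 8 / 20)  # N5's two positives drop to zero
})

test_that("end-to-end cluster search on the small synthetic database", {
  db <- small_db()
  memb <- db$idx$assignment$membership
  # reads from one strain at 10X -> exactly its cluster
  rd <- simulate_reads(db$sim$sequences[["S01"]],
                       read_sim_config(depth = 10, seed = 7L))
  hits <- search_clusters(db$idx, config = db$rc, reads = c(rd$r1, rd$r2))
  expect_identical(hits$cluster_id, unname(memb[["S01"]]))
  # two strains from different clusters -> both clusters, no others
  s2 <- names(memb)[memb != memb[["S01"]]][1]
  rd2 <- simulate_reads(db$sim$sequences[[s2]],
                        read_sim_config(depth = 10, seed = 8L))
  hits2 <- search_clusters(db$idx, config = db$rc,
                           reads = c(rd$r1, rd$r2, rd2$r1, rd2$r2))
  expect_setequal(hits2$cluster_id, unname(memb[c("S01", s2)]))
  # reads from an unrelated random genome -> no hits
  set.seed(99)
  unrelated <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                     collapse = "")
  rd3 <- simulate_reads(unrelated, read_sim_config(depth = 10, seed = 9L))
  hits3 <- search_clusters(db$idx, config = db$rc,
                           reads = c(rd3$r1, rd3$r2))
  expect_identical(nrow(hits3), 0L)
})

test_that("scaling all counts up never removes an accepted hit", {
  db <- small_db()
  rd <- simulate_reads(db$sim$sequences[["S04"]],
                       read_sim_config(depth = 5, seed = 17L))
  cst <- db$idx$cst
  query <- unique(unlist(cst$node_kmers, use.names = FALSE))
  counts <- count_kmers_in_reads(query = query, k = cst$k,
                                 reads = c(rd$r1, rd$r2))
  base <- search_clusters(db$idx, config = db$rc, counts = counts)
  for (mult in c(2L, 5L)) {
    scaled <- counts
    scaled$counts <- scaled$counts * mult
    up <- search_clusters(db$idx, config = db$rc, counts = scaled)
    expect_true(all(base$cluster_id %in% up$cluster_id))
  }
})
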