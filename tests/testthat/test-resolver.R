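# window-enumeration oracle reused from helper-fixtures (oracle_kmers)

test_that("strain matrix rows are the non-constant presence patterns", {
  # two strains differing by one substitution, k = 5: the five windows
  # overlapping the variant are private to each strain, everything else is
  # constant and excluded
  set.seed(3)
  base <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  alt <- base
  substr(alt, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                 substr(base, 30, 30))[1]
  ka <- oracle_kmers(base, 5)
  kb <- oracle_kmers(alt, 5)
  m <- build_strain_matrix(list(A = ka, B = kb), "C1")
  expect_setequal(m$kmers, union(setdiff(ka, kb), setdiff(kb, ka)))
  expect_lte(length(setdiff(ka, kb)), 5L)
  onlyA <- m$kmers %in% setdiff(ka, kb)
  expect_true(all(m$X[onlyA, "A"]) && !any(m$X[onlyA, "B"]))
  # for a 2-strain matrix every row is single-1, hence strain_specific
  expect_true(all(m$pattern_class == "strain_specific"))

  # a private insertion >= k yields insertion-spanning strain-specific rows
  ins <- paste0(substr(base, 1, 30), "CCCCCGG", substr(base, 31, 60))
  ki <- oracle_kmers(ins, 5)
  m2 <- build_strain_matrix(list(A = ka, B = ki), "C1")
  spanning <- setdiff(ki, ka)
  expect_true(all(spanning %in% m2$kmers))

  # identical strains violate the distinct-column invariant
  expect_error(build_strain_matrix(list(A = ka, B = ka), "C1"),
               "not distinct")
})

test_that("joint rows are flagged by complementary Hamming-1 patterns", {
  # three strains, a core SNV with allele 1 in A+B and allele 2 in C:
  # variant windows form complementary patterns at Hamming distance 1
  set.seed(8)
  base <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  alt <- base
  substr(alt, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                 substr(base, 30, 30))[1]
  # plus a strain-specific region in A so columns stay distinct
  a_extra <- paste0(base, "TTTTTAACCA")
  sets <- list(A = oracle_kmers(a_extra, 5), B = oracle_kmers(base, 5),
               C = oracle_kmers(alt, 5))
  m <- build_strain_matrix(sets, "C1")
  code <- m$X %*% c(1, 2, 4)
  # rows present in A+B but not C (allele-1 windows) should be joint
  ab_rows <- which(code == 3)
  expect_true(any(m$pattern_class[ab_rows] == "joint"))
})

test_that("cross-cluster masking zeroes shared k-mers and is idempotent", {
  m <- list(kmers = c("AAA", "AAC", "AAG"), strain_ids = "s1")
  y <- c(50, 3, 7)
  # no other hits -> identity
  y1 <- mask_cross_cluster(y, m, list())
  expect_equal(as.numeric(y1), y)
  y2 <- mask_cross_cluster(y, m, list(c("AAA", "TTT")))
  expect_equal(as.numeric(y2), c(0, 3, 7))
  expect_equal(attr(y2, "masked"), 1L)
  y3 <- mask_cross_cluster(as.numeric(y2), m, list(c("AAA", "TTT")))
  expect_equal(as.numeric(y3), as.numeric(y2))
})

test_that("iterative detection selects present strains and stops on masked residue", {
  X <- cbind(A = c(1, 1, 0, 0, 1, 0),
             B = c(0, 0, 1, 1, 1, 0),
             C = c(0, 0, 0, 0, 0, 1)) == 1
  m <- structure(list(cluster_id = "C1",
                      kmers = sprintf("K%d", 1:6),
                      strain_ids = c("A", "B", "C"), X = X,
                      pattern_class = rep("strain_specific", 6),
                      single_strain = FALSE), class = "strain_matrix")
  # y = exact counts of strain A at depth 10 (its k-mers only)
  y <- c(10, 10, 0, 0, 10, 0)
  det <- iterative_strain_detection(m, y, stop_kmers = 1240,
                                    stop_scale_rows = 12400, trim = FALSE)
  expect_identical(det$selected, "A")
  # hand-evaluated first-round scores: f = X^T y
  expect_equal(unname(det$scores[[1]]), c(30, 10, 0))
  # all-zero y -> empty selection
  det0 <- iterative_strain_detection(m, rep(0, 6), trim = FALSE)
  expect_identical(det0$selected, character(0))
  # two strains with disjoint specific k-mers, higher total count first
  y2 <- c(5, 5, 20, 20, 0, 0)
  X2 <- X; X2[5, ] <- FALSE
  m2 <- m; m2$X <- X2
  det2 <- iterative_strain_detection(m2, y2, stop_kmers = 1240,
                                     stop_scale_rows = 12400, trim = FALSE)
  expect_identical(det2$selected, c("B", "A"))
})

test_that("outlier trim zeroes counts outside the 5th-95th percentile band", {
  X <- matrix(TRUE, 101, 1, dimnames = list(NULL, "A"))
  m <- structure(list(cluster_id = "C1", kmers = sprintf("K%03d", 1:101),
                      strain_ids = "A", X = X,
                      pattern_class = rep("core", 101),
                      single_strain = TRUE), class = "strain_matrix")
  y <- c(1:100, 100000)  # one wild outlier
  det <- iterative_strain_detection(m, y, trim = TRUE)
  expect_true(101L %in% det$trimmed)     # the spike is removed
  expect_equal(det$y[101], 0)
})

test_that("elastic net recovers noiseless depths", {
  set.seed(21)
  # single strain, y = d * x exactly -> relative error < 1%
  x <- matrix(rbinom(400, 1, 0.9), ncol = 1, dimnames = list(NULL, "A"))
  d <- 37.5
  beta <- estimate_depths(x, as.numeric(d * x[, 1]), seed = 5)
  expect_lt(abs(beta[["A"]] - d) / d, 0.01)
  # y = 0 -> beta = 0
  beta0 <- estimate_depths(x, rep(0, 400), seed = 5)
  expect_equal(as.numeric(beta0), 0)
  # two strains with disjoint supports, depths 30 and 10
  X2 <- cbind(A = rep(c(1, 0), each = 200), B = rep(c(0, 1), each = 200))
  y2 <- X2 %*% c(30, 10)
  beta2 <- estimate_depths(X2, as.numeric(y2), seed = 5)
  expect_lt(abs(beta2[["A"]] - 30) / 30, 0.05)
  expect_lt(abs(beta2[["B"]] - 10) / 10, 0.05)
  # duplicate columns are reported by name
  X3 <- cbind(A = c(1, 0, 1, 1), B = c(1, 0, 1, 1))
  expect_error(estimate_depths(X3, c(1, 0, 1, 1)), "A, B")
})

test_that("depth estimates scale linearly with coverage", {
  set.seed(33)
  x <- matrix(rbinom(600, 1, 0.8), ncol = 2)
  x[, 2] <- 1 - x[, 1]
  colnames(x) <- c("A", "B")
  y1 <- as.numeric(x %*% c(12, 4))
  y2 <- 2 * y1
  b1 <- estimate_depths(x, y1, seed = 9)
  b2 <- estimate_depths(x, y2, seed = 9)
  expect_lt(max(abs(b2 / b1 - 2)), 0.1)
})

test_that("relative abundance merges clusters by their tree abundances", {
  # single cluster: reduces to the normalised coefficients
  res <- list(list(cluster_id = "C1", beta = c(S1 = 8, S2 = 2)))
  prof <- relative_abundance(res, c(C1 = 12))
  expect_equal(prof$relative_abundance, c(0.8, 0.2))
  # cluster P (A=10), one strain; cluster Q (A=30), two equal strains
  res2 <- list(list(cluster_id = "P", beta = c(S1 = 5)),
               list(cluster_id = "Q", beta = c(S2 = 7, S3 = 7)))
  prof2 <- relative_abundance(res2, c(P = 10, Q = 30))
  ra <- setNames(prof2$relative_abundance, prof2$strain_id)
  expect_equal(unname(ra[c("S1", "S2", "S3")]), c(0.25, 0.375, 0.375))
  # symmetry: equal everything -> equal shares
  res3 <- list(list(cluster_id = "P", beta = c(S1 = 3, S2 = 3)),
               list(cluster_id = "Q", beta = c(S3 = 9, S4 = 9)))
  prof3 <- relative_abundance(res3, c(P = 20, Q = 20))
  expect_equal(prof3$relative_abundance, rep(0.25, 4))
  expect_equal(sum(prof3$relative_abundance), 1)
  # all-zero coefficients: empty profile with a warning
  expect_warning(
    p0 <- relative_abundance(list(list(cluster_id = "C1",
                                       beta = c(S1 = 0))), c(C1 = 5)),
    "zero")
  expect_identical(nrow(p0), 0L)
})

test_that("same-cluster mixtures are recovered with small JSD", {
  db <- small_db()
  memb <- db$idx$assignment$membership
  cl_of <- split(names(memb), memb)
  big <- cl_of[[which(lengths(cl_of) >= 3)[1]]]
  for (case in list(list(strains = big[1:2], depths = c(100, 10), seed = 60L),
                    list(strains = big[1:3], depths = c(100, 50, 10),
                         seed = 61L))) {
    mix <- simulate_mixture(db$sim$sequences[case$strains], case$depths,
                            read_sim_config(seed = case$seed))
    prof <- search_sample(db$idx, reads = c(mix$r1, mix$r2))
    expect_setequal(prof$strain_id, case$strains)
    est <- setNames(prof$relative_abundance, prof$strain_id)
    expect_lt(jsd(mix$truth, est), 0.05)
  }
})
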