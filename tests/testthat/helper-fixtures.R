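# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# the full-size synthetic reference set used by the acceptance-style tests:
# 6 clusters x (5,4,4,3,2,2) strains of a 50 kb species
acceptance_db <- function() {
  if (is.null(.fixture_env$acc)) {
    sim <- simulate_strain_set(strain_sim_config(seed = 101L))
    rc <- run_config(seed = 101L)
    idx <- suppressWarnings(build_index(sim$sequences, rc))
    .fixture_env$acc <- list(sim = sim, idx = idx, rc = rc)
  }
  .fixture_env$acc
}

# a small 8-strain / 3-cluster set of 20 kb genomes for cheaper tests
small_db <- function() {
  if (is.null(.fixture_env$small)) {
    sim <- simulate_strain_set(
      strain_sim_config(genome_length = 20000L, n_clusters = 3L,
                        strains_per_cluster = c(3L, 3L, 2L), seed = 42L))
    rc <- run_config(seed = 42L)
    idx <- suppressWarnings(build_index(sim$sequences, rc))
    .fixture_env$small <- list(sim = sim, idx = idx, rc = rc)
  }
  .fixture_env$small
}

# brute-force window-enumeration oracle for canonical k-mer extraction,
# independent of the package implementation
oracle_kmers <- function(seqs, k) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc1 <- function(s) {
    ch <- rev(strsplit(s, "")[[1]])
    paste(unname(comp[ch]), collapse = "")
  }
  out <- character(0)
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      r <- rc1(w)
      out <- c(out, if (w <= r) w else r)
    }
  }
  sort(unique(out))
}

# random leaf-labelled binary tree in the package's node-table layout
random_cluster_tree <- function(n_leaves, seed) {
  set.seed(seed)
  ids <- paste0("C", seq_len(n_leaves))
  nodes <- data.frame(node_id = paste0("N", seq_len(n_leaves)),
                      parent = NA_character_, left = NA_character_,
                      right = NA_character_, depth = NA_integer_,
                      is_leaf = TRUE, cluster_id = ids,
                      stringsAsFactors = FALSE)
  active <- nodes$node_id
  nxt <- n_leaves
  while (length(active) > 1L) {
    pick <- sample(length(active), 2L)
    nxt <- nxt + 1L
    nid <- paste0("N", nxt)
    nodes <- rbind(nodes, data.frame(
      node_id = nid, parent = NA_character_,
      left = active[pick[1]], right = active[pick[2]],
      depth = NA_integer_, is_leaf = FALSE, cluster_id = NA_character_,
      stringsAsFactors = FALSE))
    active <- c(active[-pick], nid)
  }
  rownames(nodes) <- nodes$node_id
  for (id in nodes$node_id)
    for (ch in c(nodes[id, "left"], nodes[id, "right"]))
      if (!is.na(ch)) nodes[ch, "parent"] <- id
  root <- nodes$node_id[is.na(nodes$parent)]
  nodes[root, "depth"] <- 0L
  queue <- root
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (ch in c(nodes[v, "left"], nodes[v, "right"])) {
      if (!is.na(ch)) {
        nodes[ch, "depth"] <- nodes[v, "depth"] + 1L
        queue <- c(queue, ch)
      }
    }
  }
  nodes
}

# direct set-formula oracle for node k-mer assignment: intersection of the
# leaf sets below the node minus the union of every leaf set outside
oracle_node_kmers <- function(tree, leaf_sets, node) {
  below <- function(v) {
    if (tree[v, "is_leaf"]) return(tree[v, "cluster_id"])
    c(below(tree[v, "left"]), below(tree[v, "right"]))
  }
  sub <- below(node)
  ext <- setdiff(tree$cluster_id[tree$is_leaf], sub)
  inter <- Reduce(intersect, lapply(sub, function(cid) leaf_sets[[cid]]))
  sort(setdiff(inter, unique(unlist(leaf_sets[ext]))))
}

# exact binomial CDF oracle via log-binomial-coefficient summation
oracle_pbinom <- function(q, size, prob) {
  if (q < 0) return(0)
  q <- min(q, size)
  i <- 0:q
  sum(exp(lchoose(size, i) + i * log(prob) + (size - i) * log1p(-prob)))
}
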