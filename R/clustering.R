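#' All-against-all Jaccard similarity matrix
#'
#' @param genomes list of [kmer_set()] objects with distinct `genome_id`s and
#'   identical `k`.
#' @return Square symmetric matrix of exact pairwise Jaccard similarities
#'   with unit diagonal and `genome_id` dimnames.
#' @export
build_similarity_matrix <- function(genomes) {
  stopifnot(length(genomes) >= 1L)
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate genome_id: ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "), call. = FALSE)
  ks <- vapply(genomes, function(g) g$k, integer(1))
  if (length(unique(ks)) != 1L)
    stop("all genomes must use the same k", call. = FALSE)
  n <- length(genomes)
  S <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        S[i, j] <- S[j, i] <- jaccard(genomes[[i]], genomes[[j]])
      }
    }
  }
  dimnames(S) <- list(ids, ids)
  S
}

.check_similarity <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop("'S' must be a square matrix", call. = FALSE)
  if (is.null(rownames(S))) {
    rownames(S) <- colnames(S) <- paste0("G", seq_len(nrow(S)))
  }
  if (max(abs(S - t(S))) > 1e-12)
    stop("'S' must be symmetric", call. = FALSE)
  if (any(S < -1e-12) || any(S > 1 + 1e-12))
    stop("similarities must lie in [0, 1]", call. = FALSE)
  S
}

# Deterministic agglomerative clustering on a similarity matrix.
# linkage "single": similarity between groups = max pairwise S;
# linkage "complete": min pairwise S. When several merges share the maximal
# similarity, the pair whose (smallest-member-id, smallest-member-id) labels
# are lexicographically smallest is merged first, which makes the dendrogram
# deterministic.
# Returns merge (hclust convention), height_sim (merge similarities,
# non-increasing) and labels.
.agglomerate <- function(S, linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  S <- .check_similarity(S)
  labels <- rownames(S)
  n <- nrow(S)
  if (n == 1L)
    return(structure(list(merge = matrix(integer(0), 0, 2),
                          height_sim = numeric(0), labels = labels),
                     class = "strain_dendrogram"))
  # active cluster bookkeeping
  members <- as.list(seq_len(n))       # leaf indices per active cluster
  node_of <- as.list(-seq_len(n))      # hclust node id per active cluster
  rep_lab <- labels                    # smallest member label per cluster
  CS <- S                              # cluster-level similarity
  merge <- matrix(0L, n - 1L, 2L)
  hsim <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(members)
    best <- -Inf; bi <- bj <- NA_integer_
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        s <- CS[i, j]
        if (s > best + 1e-15) {
          best <- s; bi <- i; bj <- j
        } else if (abs(s - best) <= 1e-15) {
          key_new <- sort(c(rep_lab[i], rep_lab[j]))
          key_old <- sort(c(rep_lab[bi], rep_lab[bj]))
          if (key_new[1] < key_old[1] ||
              (key_new[1] == key_old[1] && key_new[2] < key_old[2])) {
            bi <- i; bj <- j
          }
        }
      }
    }
    merge[step, ] <- c(node_of[[bi]], node_of[[bj]])
    hsim[step] <- best
    # merge bj into bi
    members[[bi]] <- c(members[[bi]], members[[bj]])
    node_of[[bi]] <- step
    rep_lab[bi] <- min(rep_lab[bi], rep_lab[bj])
    comb <- if (linkage == "single") pmax(CS[bi, ], CS[bj, ]) else
      pmin(CS[bi, ], CS[bj, ])
    CS[bi, ] <- comb; CS[, bi] <- comb; CS[bi, bi] <- 1
    keep <- setdiff(seq_len(m), bj)
    CS <- CS[keep, keep, drop = FALSE]
    members <- members[keep]; node_of <- node_of[keep]
    rep_lab <- rep_lab[keep]
  }
  structure(list(merge = merge, height_sim = hsim, labels = labels),
            class = "strain_dendrogram")
}

#' @export
print.strain_dendrogram <- function(x, ...) {
  cat(sprintf("strain dendrogram over %d genomes (%d merges)\n",
              length(x$labels), nrow(x$merge)))
  invisible(x)
}

#' Convert a strain dendrogram to an hclust object
#'
#' Heights are `1 - similarity`, so the object can be plotted or exported
#' with standard tools.
#'
#' @param x a `strain_dendrogram`.
#' @param ... unused.
#' @return An [stats::hclust] object.
#' @export
as.hclust.strain_dendrogram <- function(x, ...) {
  if (nrow(x$merge) == 0L)
    stop("cannot convert a single-leaf dendrogram to hclust", call. = FALSE)
  # compute a valid leaf order by traversing the merge tree
  order_of <- function(node) {
    if (node < 0) return(-node)
    c(order_of(x$merge[node, 1]), order_of(x$merge[node, 2]))
  }
  structure(list(merge = x$merge, height = 1 - x$height_sim,
                 order = order_of(nrow(x$merge)), labels = x$labels,
                 method = "single", call = match.call(),
                 dist.method = "1 - jaccard"),
            class = "hclust")
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are on the `1 - similarity` scale.
#'
#' @param x a `strain_dendrogram`.
#' @param file optional path; when given the tree is written there.
#' @return The Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(x, file = NULL) {
  phy <- ape::as.phylo(as.hclust(x))
  if (is.null(file)) ape::write.tree(phy)
  else invisible(ape::write.tree(phy, file = file))
}

#' Single-linkage clustering of strains at a similarity cutoff
#'
#' Performs agglomerative single-linkage clustering on distance
#' `1 - similarity` and cuts the dendrogram at `1 - H`: the resulting
#' clusters are exactly the connected components of the graph joining
#' genomes with similarity `>= H`.
#'
#' @param S similarity matrix (see [build_similarity_matrix()]).
#' @param H similarity cutoff in `(0, 1]`; a pair with `S >= H` stays in one
#'   cluster.
#' @return An object of class `"cluster_assignment"`: list with the
#'   `dendrogram`, `clusters` (named list cluster_id -> genome ids),
#'   `membership` (named character vector genome -> cluster_id), the cutoff
#'   `H`, and `cluster_tree`, the dendrogram contracted so that each cluster
#'   is one leaf (the topology later used by the cluster search tree).
#' @export
single_linkage_clusters <- function(S, H = 0.95) {
  if (!is.numeric(H) || H <= 0 || H > 1)
    stop("'H' must lie in (0, 1]", call. = FALSE)
  S <- .check_similarity(S)
  dend <- .agglomerate(S, "single")
  labels <- dend$labels
  n <- length(labels)
  # union-find over merges with similarity >= H
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  leaves_of <- vector("list", max(nrow(dend$merge), 1L))
  for (m in seq_len(nrow(dend$merge))) {
    ch <- dend$merge[m, ]
    lv <- unlist(lapply(ch, function(c) if (c < 0) -c else leaves_of[[c]]))
    leaves_of[[m]] <- lv
    if (dend$height_sim[m] >= H) {
      r1 <- find(lv[1])
      for (l in lv[-1]) { r2 <- find(l); if (r1 != r2) parent[r2] <- r1 }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(labels, roots)
  # deterministic cluster ids ordered by smallest member
  comp <- comp[order(vapply(comp, min, character(1)))]
  names(comp) <- paste0("C", seq_along(comp))
  membership <- rep(names(comp), lengths(comp))
  names(membership) <- unlist(comp)
  membership <- membership[labels[labels %in% names(membership)]]
  cluster_tree <- .contract_dendrogram(dend, membership, H)
  structure(list(dendrogram = dend, clusters = comp,
                 membership = membership, H = H,
                 cluster_tree = cluster_tree),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster assignment at H = %g: %d genomes in %d clusters\n",
              x$H, length(x$membership), length(x$clusters)))
  sizes <- lengths(x$clusters)
  cat("  sizes:", paste(sprintf("%s=%d", names(sizes), sizes),
                        collapse = " "), "\n")
  invisible(x)
}

# Contract a strain dendrogram at cutoff H into a binary tree whose leaves
# are the clusters. Under single linkage all merges at similarity >= H occur
# before any merge below H, so the below-H merges form a binary tree over
# the cluster components. Returns a node table:
#   node_id parent left right depth is_leaf cluster_id
# Node ids are "N1", "N2", ... in a deterministic (merge-order) numbering;
# the root has parent NA.
.contract_dendrogram <- function(dend, membership, H) {
  clusters <- split(names(membership), membership)
  cids <- names(clusters)
  if (length(cids) == 1L) {
    return(data.frame(node_id = "N1", parent = NA_character_,
                      left = NA_character_, right = NA_character_,
                      depth = 0L, is_leaf = TRUE, cluster_id = cids,
                      stringsAsFactors = FALSE))
  }
  # map each genome leaf to its cluster id
  lab2c <- membership
  nodes <- list()
  next_id <- 0L
  new_node <- function(left, right, cluster_id) {
    next_id <<- next_id + 1L
    id <- paste0("N", next_id)
    nodes[[id]] <<- list(node_id = id, left = left, right = right,
                         cluster_id = cluster_id)
    id
  }
  # component id (a CST node id) for each dendrogram node
  comp_of_leaf <- character(length(dend$labels))
  cst_of_cluster <- character(0)
  # leaves of the cluster tree are created lazily in cluster id order first
  for (cid in cids) cst_of_cluster[cid] <- new_node(NA_character_,
                                                    NA_character_, cid)
  comp <- character(nrow(dend$merge) + length(dend$labels))
  get_comp <- function(node) {
    if (node < 0) cst_of_cluster[[lab2c[[dend$labels[-node]]]]]
    else comp[[node]]
  }
  for (m in seq_len(nrow(dend$merge))) {
    a <- get_comp(dend$merge[m, 1]); b <- get_comp(dend$merge[m, 2])
    if (dend$height_sim[m] >= H) {
      stopifnot(a == b)  # within-cluster merge
      comp[[m]] <- a
    } else {
      comp[[m]] <- new_node(a, b, NA_character_)
    }
  }
  df <- do.call(rbind, lapply(nodes, function(nd)
    data.frame(node_id = nd$node_id, parent = NA_character_,
               left = nd$left, right = nd$right, depth = NA_integer_,
               is_leaf = is.na(nd$left), cluster_id = nd$cluster_id,
               stringsAsFactors = FALSE)))
  rownames(df) <- df$node_id
  for (id in df$node_id) {
    for (ch in c(df[id, "left"], df[id, "right"]))
      if (!is.na(ch)) df[ch, "parent"] <- id
  }
  root <- df$node_id[is.na(df$parent)]
  stopifnot(length(root) == 1L)
  # depths by BFS
  df[root, "depth"] <- 0L
  queue <- root
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (ch in c(df[v, "left"], df[v, "right"])) {
      if (!is.na(ch)) {
        df[ch, "depth"] <- df[v, "depth"] + 1L
        queue <- c(queue, ch)
      }
    }
  }
  df
}

#' Dereplicate near-identical reference genomes
#'
#' Complete-linkage clustering at a high similarity threshold; from each
#' cluster the member with the highest average similarity to the other
#' members is kept (ties broken by smallest genome id; singletons represent
#' themselves).
#'
#' @param S similarity matrix.
#' @param threshold complete-linkage Jaccard similarity threshold.
#' @return Sorted character vector of representative genome ids.
#' @export
dereplicate <- function(S, threshold = 0.99) {
  S <- .check_similarity(S)
  labels <- rownames(S)
  n <- nrow(S)
  if (n == 1L) return(labels)
  dend <- .agglomerate(S, "complete")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  leaves_of <- vector("list", nrow(dend$merge))
  for (m in seq_len(nrow(dend$merge))) {
    ch <- dend$merge[m, ]
    lv <- unlist(lapply(ch, function(c) if (c < 0) -c else leaves_of[[c]]))
    leaves_of[[m]] <- lv
    if (dend$height_sim[m] >= threshold) {
      r1 <- find(lv[1])
      for (l in lv[-1]) { r2 <- find(l); if (r1 != r2) parent[r2] <- r1 }
    }
  }
  groups <- split(seq_len(n), vapply(seq_len(n), find, integer(1)))
  reps <- vapply(groups, function(g) {
    if (length(g) == 1L) return(labels[g])
    mean_sim <- vapply(g, function(i) mean(S[i, setdiff(g, i)]), numeric(1))
    cand <- labels[g][mean_sim == max(mean_sim)]
    min(cand)
  }, character(1))
  sort(unname(reps))
}
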