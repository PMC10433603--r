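#' Map read k-mer counts onto the nodes of a cluster search tree
#'
#' @param counts a `kmer_count_table` built over (at least) the union of all
#'   node k-mers.
#' @param cst a `"cst"` object.
#' @return Named list node_id -> integer count vector in the node's stored
#'   k-mer order (k-mers missing from the table count 0).
#' @export
assign_counts <- function(counts, cst) {
  if (counts$k != cst$k)
    stop("k mismatch between counts (", counts$k, ") and tree (", cst$k, ")",
         call. = FALSE)
  lapply(cst$node_kmers, function(kms) {
    v <- counts$counts[match(kms, names(counts$counts))]
    v[is.na(v)] <- 0L
    unname(as.integer(v))
  })
}

#' Score a node's count vector
#'
#' `frac` is the fraction of node k-mers with a positive count; `abund` is
#' the mean of the positive counts, forced to 0 whenever `frac` falls below
#' `frac_floor` (weakly matched nodes are treated as noise).
#'
#' @param C_v integer count vector of one node.
#' @param frac_floor matched-fraction floor below which `abund` is zeroed.
#' @return List with `frac` and `abund`.
#' @export
score_node <- function(C_v, frac_floor = 0.1) {
  if (length(C_v) == 0L) {
    warning("empty node count vector; scoring as (0, 0)", call. = FALSE)
    return(list(frac = 0, abund = 0))
  }
  pos <- C_v[C_v > 0]
  frac <- length(pos) / length(C_v)
  abund <- if (frac >= frac_floor && length(pos)) mean(pos) else 0
  list(frac = frac, abund = abund)
}

# round-half-up to the nearest integer (documented tie rule)
.round_half_up <- function(x) floor(x + 0.5)

#' Binomial traversal test
#'
#' Decides whether the drop from a parent's mean k-mer count to a child's is
#' explainable by sequencing errors alone. Both abundances are rounded
#' half-up to integers; the p-value is `P(X <= abund_p' - abund_v')` for
#' `X ~ Binomial(abund_p', 1 - e)` (exact CDF). The child is traversed when
#' the null is rejected (`p < beta`); a negative difference gives p = 0 and
#' always traverses.
#'
#' @param abund_parent,abund_child non-negative abundance scores.
#' @param e assumed sequencing error rate in `(0, 1)`.
#' @param beta significance level in `(0, 1)`.
#' @return List with `decision` (`"traverse"` or `"stop"`) and `p_value`.
#' @export
binomial_stop_test <- function(abund_parent, abund_child, e = 0.01,
                               beta = 0.05) {
  if (!is.numeric(e) || e <= 0 || e >= 1)
    stop("'e' must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(beta) || beta <= 0 || beta >= 1)
    stop("'beta' must lie in (0, 1)", call. = FALSE)
  if (abund_parent < 0 || abund_child < 0)
    stop("abundances must be non-negative", call. = FALSE)
  ap <- .round_half_up(abund_parent)
  av <- .round_half_up(abund_child)
  d <- ap - av
  p <- if (d < 0) 0 else stats::pbinom(d, size = ap, prob = 1 - e)
  list(decision = if (p < beta) "traverse" else "stop", p_value = p)
}

#' Breadth-first cluster search over a scored tree
#'
#' Starting from the root (whose children always enter the queue when the
#' root has positive abundance), every dequeued node is tested against its
#' parent with [binomial_stop_test()]: nodes that reject the error-only null
#' are expanded (internal nodes) or become candidate leaves.
#'
#' @param cst a `"cst"` object.
#' @param node_counts output of [assign_counts()].
#' @param e,beta,frac_floor see [run_config()].
#' @return Character vector of candidate leaf node ids (BFS order); the
#'   node scores are attached as attribute `"scores"`.
#' @export
bfs_search <- function(cst, node_counts, e = 0.01, beta = 0.05,
                       frac_floor = 0.1) {
  tree <- cst$tree
  scores <- lapply(node_counts, score_node, frac_floor = frac_floor)
  abund <- vapply(scores, `[[`, numeric(1), "abund")
  root <- tree$node_id[is.na(tree$parent)]
  candidates <- character(0)
  if (abund[[root]] > 0) {
    if (tree[root, "is_leaf"]) {
      candidates <- root
    } else {
      queue <- c(tree[root, "left"], tree[root, "right"])
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        parent <- tree[v, "parent"]
        dec <- binomial_stop_test(abund[[parent]], abund[[v]], e, beta)
        if (dec$decision == "traverse") {
          if (tree[v, "is_leaf"]) candidates <- c(candidates, v)
          else queue <- c(queue, tree[v, "left"], tree[v, "right"])
        }
      }
    }
  }
  attr(candidates, "scores") <- scores
  candidates
}

# leaf node ids below a node
.subtree_leaves <- function(tree, node) {
  acc <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (tree[v, "is_leaf"]) acc <- c(acc, v)
    else stack <- c(stack, tree[v, "left"], tree[v, "right"])
  }
  acc
}

#' Evidence path of a candidate leaf
#'
#' The nodes whose k-mer matches can be attributed to the candidate alone:
#' the path from the root of the maximal subtree containing `leaf` and no
#' other candidate, down to `leaf`. With a single candidate this is the full
#' root-to-leaf path.
#'
#' @param cst a `"cst"` object.
#' @param leaf candidate leaf node id.
#' @param candidates character vector of all candidate leaf ids (must
#'   contain `leaf`).
#' @return Character vector of node ids from the subtree root down to
#'   `leaf`.
#' @export
resolve_path <- function(cst, leaf, candidates) {
  tree <- cst$tree
  if (!leaf %in% candidates)
    stop("'leaf' must be one of the candidates", call. = FALSE)
  path <- leaf
  v <- leaf
  repeat {
    parent <- tree[v, "parent"]
    if (is.na(parent)) break
    others <- setdiff(intersect(.subtree_leaves(tree, parent), candidates),
                      leaf)
    if (length(others)) break
    path <- c(parent, path)
    v <- parent
  }
  path
}

#' Path statistics and acceptance of a cluster hit
#'
#' Pools the count vectors of the nodes on a candidate's evidence path into
#' the weighted matched fraction `F_v` and weighted mean match count `A_v`.
#' Before pooling, counts of k-mers that also occur in strains of an
#' already-accepted other cluster are corrected for that cluster's abundance
#' estimate (subtracted and floored at 0, or excluded, per `adjust_mode`).
#' The hit is accepted iff `F_v` exceeds `F_cutoff`.
#'
#' @param cst a `"cst"` object.
#' @param leaf candidate leaf node id.
#' @param path_nodes node ids from [resolve_path()].
#' @param node_counts output of [assign_counts()].
#' @param other_hits list of accepted hits, each a list with `cluster_id`,
#'   `A` and `kmers` (union of the cluster's strain k-mers).
#' @param F_cutoff acceptance cutoff on `F_v`.
#' @param frac_floor see [score_node()].
#' @param adjust_mode `"subtract"` or `"exclude"`.
#' @return A list (class `"cluster_hit"`) with `cluster_id`, `F`, `A`,
#'   `path_nodes`, or `NULL` when rejected.
#' @export
leaf_statistics <- function(cst, leaf, path_nodes, node_counts,
                            other_hits = list(), F_cutoff = 0.4,
                            frac_floor = 0.1,
                            adjust_mode = c("subtract", "exclude")) {
  adjust_mode <- match.arg(adjust_mode)
  tree <- cst$tree
  npos <- ntot <- numeric(length(path_nodes))
  ab <- numeric(length(path_nodes))
  for (i in seq_along(path_nodes)) {
    v <- path_nodes[[i]]
    cnt <- node_counts[[v]]
    keep <- rep(TRUE, length(cnt))
    if (length(other_hits) && length(cnt)) {
      kms <- cst$node_kmers[[v]]
      for (oh in other_hits) {
        shared <- kms %in% oh$kmers
        if (any(shared)) {
          if (adjust_mode == "subtract")
            cnt[shared] <- pmax(0, cnt[shared] - oh$A)
          else keep[shared] <- FALSE
        }
      }
    }
    cnt <- cnt[keep]
    sc <- if (length(cnt)) score_node(cnt, frac_floor) else
      list(frac = 0, abund = 0)
    npos[i] <- sum(cnt > 0)
    ntot[i] <- length(cnt)
    ab[i] <- sc$abund
  }
  if (sum(ntot) == 0 || sum(npos) == 0) {
    warning("no usable k-mers on path of ", leaf, "; hit rejected",
            call. = FALSE)
    return(NULL)
  }
  F_v <- sum(npos) / sum(ntot)
  A_v <- sum(npos * ab) / sum(npos)
  if (F_v <= F_cutoff) return(NULL)
  structure(list(cluster_id = tree[leaf, "cluster_id"], leaf = leaf,
                 F = F_v, A = A_v, path_nodes = path_nodes),
            class = "cluster_hit")
}

#' Cluster-level search of a read set
#'
#' End-to-end cluster identification: count the index k-mers in the reads,
#' map the counts onto the tree, run the breadth-first search, resolve each
#' candidate's evidence path and accept hits by their pooled statistics. Hit
#' statistics are computed in two passes so that counts of k-mers shared
#' with another accepted cluster are corrected for that cluster's
#' first-pass abundance estimate.
#'
#' @param index a `"strainsift_index"` (see [build_index()]).
#' @param fastq_paths FASTQ file(s) with the sample reads.
#' @param config a [run_config()].
#' @param reads optional in-memory reads (bypasses `fastq_paths`).
#' @param counts optional precomputed `kmer_count_table` covering the node
#'   k-mers.
#' @return A data.frame with one row per identified cluster (`cluster_id`,
#'   `F`, `A`, `n_path_nodes`), sorted by decreasing `A`; per-node
#'   diagnostics in attribute `"diagnostics"`.
#' @export
search_clusters <- function(index, fastq_paths = NULL,
                            config = run_config(), reads = NULL,
                            counts = NULL) {
  cst <- index$cst
  if (is.null(counts)) {
    query <- unique(unlist(cst$node_kmers, use.names = FALSE))
    counts <- count_kmers_in_reads(fastq_paths, query, k = cst$k,
                                   reads = reads)
  }
  node_counts <- assign_counts(counts, cst)
  cands <- bfs_search(cst, node_counts, e = config$e, beta = config$beta,
                      frac_floor = config$frac_floor)
  scores <- attr(cands, "scores")
  empty <- data.frame(cluster_id = character(0), F = numeric(0),
                      A = numeric(0), n_path_nodes = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(cands)) {
    attr(empty, "diagnostics") <- list(scores = scores,
                                       candidates = character(0))
    return(empty)
  }
  paths <- lapply(cands, function(v) resolve_path(cst, v, cands))
  names(paths) <- cands
  pass1 <- lapply(cands, function(v)
    leaf_statistics(cst, v, paths[[v]], node_counts,
                    other_hits = list(), F_cutoff = config$F_cutoff,
                    frac_floor = config$frac_floor,
                    adjust_mode = config$adjust_mode))
  names(pass1) <- cands
  accepted1 <- cands[!vapply(pass1, is.null, logical(1))]
  if (!length(accepted1)) {
    attr(empty, "diagnostics") <- list(scores = scores, candidates = cands)
    return(empty)
  }
  final <- list()
  for (v in accepted1) {
    others <- setdiff(accepted1, v)
    oh <- lapply(others, function(o) {
      cid <- cst$tree[o, "cluster_id"]
      list(cluster_id = cid, A = pass1[[o]]$A,
           kmers = index$cluster_union[[cid]])
    })
    final[[v]] <- leaf_statistics(cst, v, paths[[v]], node_counts,
                                  other_hits = oh,
                                  F_cutoff = config$F_cutoff,
                                  frac_floor = config$frac_floor,
                                  adjust_mode = config$adjust_mode)
  }
  final <- final[!vapply(final, is.null, logical(1))]
  if (!length(final)) {
    attr(empty, "diagnostics") <- list(scores = scores, candidates = cands)
    return(empty)
  }
  df <- data.frame(
    cluster_id = vapply(final, `[[`, character(1), "cluster_id"),
    F = vapply(final, `[[`, numeric(1), "F"),
    A = vapply(final, `[[`, numeric(1), "A"),
    n_path_nodes = vapply(final, function(h) length(h$path_nodes),
                          integer(1)),
    stringsAsFactors = FALSE)
  ord <- order(-df$A, df$cluster_id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "diagnostics") <- list(scores = scores, candidates = cands,
                                  paths = paths, hits = final[ord])
  df
}
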