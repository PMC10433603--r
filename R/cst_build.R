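#' Leaf k-mer sets with prevalence filtering
#'
#' For every cluster, collects the k-mers occurring in at least `alpha`% of
#' its member strains (single-strain clusters keep all their k-mers). These
#' sets seed the k-mer assignment of the cluster search tree.
#'
#' @param assignment a `cluster_assignment` (or a named list cluster_id ->
#'   genome ids).
#' @param genome_kmers named list genome_id -> `kmer_set` (or character
#'   vector of canonical k-mers).
#' @param alpha prevalence percentage in `(0, 100]`; the boundary is
#'   inclusive (a k-mer in exactly `alpha`% of the strains is kept).
#' @return Named list cluster_id -> object of class `"leaf_kmer_set"` with
#'   fields `cluster_id`, `kmers` (sorted) and `n_strains`.
#' @export
build_leaf_sets <- function(assignment, genome_kmers, alpha = 90) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 100)
    stop("'alpha' must lie in (0, 100]", call. = FALSE)
  clusters <- if (inherits(assignment, "cluster_assignment"))
    assignment$clusters else assignment
  if (any(lengths(clusters) == 0L))
    stop("clusters must be non-empty", call. = FALSE)
  missing <- setdiff(unlist(clusters), names(genome_kmers))
  if (length(missing))
    stop("k-mer sets missing for genomes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- lapply(names(clusters), function(cid) {
    members <- clusters[[cid]]
    sets <- lapply(genome_kmers[members], .kmers_of)
    if (length(sets) == 1L) {
      kms <- sets[[1]]
    } else {
      all <- unlist(sets, use.names = FALSE)
      u <- unique(all)
      cnt <- tabulate(match(all, u), nbins = length(u))
      kms <- sort(u[cnt / length(sets) >= alpha / 100])
    }
    structure(list(cluster_id = cid, kmers = kms,
                   n_strains = length(sets)),
              class = "leaf_kmer_set")
  })
  names(out) <- names(clusters)
  out
}

#' Build the cluster search tree
#'
#' Assigns to each node of the contracted cluster tree the k-mers unique to
#' its rooted subtree: starting from the leaf sets, shared k-mers between
#' every two sibling nodes are recursively promoted to their parent, and any
#' k-mer still present in more than one node afterwards is removed
#' everywhere. The result is equivalent to evaluating, per node, the
#' intersection of the leaf sets below it minus the union of all leaf sets
#' outside its subtree.
#'
#' @param cluster_tree node table as produced by
#'   [single_linkage_clusters()] (`$cluster_tree`), or a
#'   `cluster_assignment`.
#' @param leaf_sets named list cluster_id -> `leaf_kmer_set` (see
#'   [build_leaf_sets()]).
#' @param k k-mer length recorded with the tree.
#' @return An object of class `"cst"`: list with the node table `tree`,
#'   `node_kmers` (named list node_id -> sorted character vector),
#'   `augmented` (same shape, initially empty) and `k`.
#' @export
build_cst <- function(cluster_tree, leaf_sets, k = 31L) {
  if (inherits(cluster_tree, "cluster_assignment"))
    cluster_tree <- cluster_tree$cluster_tree
  tree <- cluster_tree
  leaf_ids <- tree$cluster_id[tree$is_leaf]
  if (!setequal(leaf_ids, names(leaf_sets)))
    stop("leaf sets and tree leaves do not match", call. = FALSE)
  rownames(tree) <- tree$node_id
  K <- list()
  assign_rec <- function(node) {
    if (tree[node, "is_leaf"]) {
      K[[node]] <<- .kmers_of(leaf_sets[[tree[node, "cluster_id"]]]$kmers)
      return(invisible(NULL))
    }
    l <- tree[node, "left"]; r <- tree[node, "right"]
    assign_rec(l); assign_rec(r)
    shared <- intersect(K[[l]], K[[r]])
    K[[node]] <<- shared
    K[[l]] <<- setdiff(K[[l]], shared)
    K[[r]] <<- setdiff(K[[r]], shared)
    invisible(NULL)
  }
  root <- tree$node_id[is.na(tree$parent)]
  assign_rec(root)
  # global de-duplication: k-mers appearing in more than one node vanish
  all <- unlist(K, use.names = FALSE)
  dup <- unique(all[duplicated(all)])
  if (length(dup))
    K <- lapply(K, function(x) setdiff(x, dup))
  K <- lapply(K, sort)
  structure(list(tree = tree, node_kmers = K[tree$node_id],
                 augmented = setNames(vector("list", nrow(tree)),
                                      tree$node_id),
                 k = as.integer(k)),
            class = "cst")
}

#' @export
print.cst <- function(x, ...) {
  nk <- lengths(x$node_kmers)
  na <- lengths(x$augmented)
  cat(sprintf("cluster search tree: %d nodes (%d leaves), k = %d\n",
              nrow(x$tree), sum(x$tree$is_leaf), x$k))
  cat(sprintf("  node k-mers: min %d, median %.0f, max %d (%d augmented)\n",
              min(nk), stats::median(nk), max(nk), sum(na)))
  invisible(x)
}

# genome ids of the strains under node v's subtree
.subtree_strains <- function(cst, node, clusters) {
  tree <- cst$tree
  acc <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (tree[v, "is_leaf"]) acc <- c(acc, clusters[[tree[v, "cluster_id"]]])
    else stack <- c(stack, tree[v, "left"], tree[v, "right"])
  }
  acc
}

#' Augment weak nodes of a cluster search tree
#'
#' Nodes whose k-mer set is smaller than `min_kmers` are prone to chance
#' matches. Such nodes receive additional k-mers that (i) occur in at least
#' one strain below the node, (ii) occur in no strain outside its subtree
#' and (iii) are not assigned to any other node; candidates present in the
#' largest fraction of the subtree's strains are added first (ties broken by
#' k-mer order) until `min_kmers` is reached. Nodes with no eligible k-mers
#' stay weak and trigger a warning.
#'
#' @param cst a `"cst"` object.
#' @param genome_kmers named list genome_id -> `kmer_set`/character vector
#'   (the raw per-strain k-mer sets).
#' @param clusters named list cluster_id -> genome ids.
#' @param min_kmers augmentation target per node.
#' @return The `cst` with enlarged `node_kmers` and the added k-mers
#'   recorded per node in `augmented`.
#' @export
augment_weak_nodes <- function(cst, genome_kmers, clusters,
                               min_kmers = 1000L) {
  tree <- cst$tree
  sets <- lapply(genome_kmers, .kmers_of)
  all_g <- names(sets)
  # occurrence count of every k-mer across all strains
  long <- unlist(sets, use.names = FALSE)
  uni <- unique(long)
  total_cnt <- tabulate(match(long, uni), nbins = length(uni))
  names(total_cnt) <- uni
  assigned <- unique(unlist(cst$node_kmers, use.names = FALSE))
  # deepest nodes first so a node can claim k-mers specific to its own
  # subtree before any ancestor (for which they are also eligible) takes
  # them; ties broken by node id for determinism
  ord <- tree$node_id[order(-tree$depth, tree$node_id)]
  for (v in ord) {
    have <- length(cst$node_kmers[[v]])
    if (have >= min_kmers) next
    inside <- .subtree_strains(cst, v, clusters)
    if (length(inside) == length(all_g) && nrow(tree) > 1L) {
      # root of a multi-node tree: everything is "inside", nothing outside;
      # eligibility reduces to unassigned k-mers
    }
    in_long <- unlist(sets[inside], use.names = FALSE)
    in_uni <- unique(in_long)
    in_cnt <- tabulate(match(in_long, in_uni), nbins = length(in_uni))
    # unique to subtree: no occurrence outside, i.e. total count equals
    # inside count
    eligible <- in_uni[in_cnt == total_cnt[in_uni]]
    eligible <- setdiff(eligible, assigned)
    if (!length(eligible)) {
      warning(sprintf("node %s stays weak (%d k-mers): no eligible k-mers",
                      v, have), call. = FALSE)
      next
    }
    prev <- in_cnt[match(eligible, in_uni)]
    take <- eligible[order(-prev, eligible)]
    take <- take[seq_len(min(length(take), min_kmers - have))]
    cst$augmented[[v]] <- sort(c(cst$augmented[[v]], take))
    cst$node_kmers[[v]] <- sort(c(cst$node_kmers[[v]], take))
    assigned <- c(assigned, take)
    if (length(cst$node_kmers[[v]]) < min_kmers)
      warning(sprintf("node %s stays weak (%d k-mers after augmentation)",
                      v, length(cst$node_kmers[[v]])), call. = FALSE)
  }
  cst
}

# Enforce strain-level subtree uniqueness: the leaf-set subtraction of the
# node assignment cannot see k-mers that fall below the alpha prevalence
# filter of an outside cluster, so a node set may still contain k-mers
# present in some strain outside its subtree. Such k-mers attract counts
# from foreign strains and are removed here; weak nodes are refilled by
# augmentation afterwards.
.prune_nonunique_node_kmers <- function(cst, genome_kmers, clusters) {
  sets <- lapply(genome_kmers, .kmers_of)
  tree <- cst$tree
  for (v in tree$node_id) {
    inside <- .subtree_strains(cst, v, clusters)
    outside <- setdiff(names(sets), inside)
    if (!length(outside)) next
    out_union <- unique(unlist(sets[outside], use.names = FALSE))
    kms <- cst$node_kmers[[v]]
    drop <- kms %in% out_union
    if (any(drop)) cst$node_kmers[[v]] <- kms[!drop]
  }
  cst
}

# Direct set-formula evaluation of a node's k-mer set: intersection of the
# leaf sets below the node minus the union of every leaf set outside its
# subtree. Used as the reference semantics in tests against the promotion
# algorithm.
.cst_node_kmers_direct <- function(cluster_tree, leaf_sets, node) {
  tree <- cluster_tree
  rownames(tree) <- tree$node_id
  leaves_below <- function(v) {
    if (tree[v, "is_leaf"]) return(tree[v, "cluster_id"])
    c(leaves_below(tree[v, "left"]), leaves_below(tree[v, "right"]))
  }
  sub <- leaves_below(node)
  ext <- setdiff(tree$cluster_id[tree$is_leaf], sub)
  inter <- Reduce(intersect, lapply(leaf_sets[sub],
                                    function(l) .kmers_of(l$kmers)))
  out <- unique(unlist(lapply(leaf_sets[ext],
                              function(l) .kmers_of(l$kmers))))
  sort(setdiff(inter, out))
}
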