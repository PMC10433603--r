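#' Full strain-level search of a sample
#'
#' Runs the complete identification pipeline against an index: count the
#' index k-mers in the reads, identify clusters on the search tree, then
#' resolve the strains of every identified cluster with the discriminative
#' k-mer matrix (cross-cluster masking, percentile outlier trim, iterative
#' matrix multiplication, non-negative elastic-net depth estimation) and
#' merge the per-cluster results into one relative abundance profile.
#'
#' @param index a `"strainsift_index"` from [build_index()] or
#'   [read_index()].
#' @param fastq_paths FASTQ file(s) with the sample reads (single or
#'   paired; gzip allowed).
#' @param config a [run_config()]; its `k` must match the index.
#' @param reads optional in-memory read sequences (bypasses `fastq_paths`).
#' @return A `"strain_profile"` data.frame (possibly empty when nothing is
#'   detected) with attributes `"cluster_hits"` (the cluster-level search
#'   result) and `"diagnostics"` (per-cluster score traces and elastic-net
#'   tuning; includes `depth_conversion`, the factor `L_read/(L_read-k+1)`
#'   turning per-k-mer coverage into nominal read coverage for 250 bp
#'   reads).
#' @export
search_sample <- function(index, fastq_paths = NULL,
                          config = NULL, reads = NULL) {
  if (is.null(config)) config <- index$config
  if (config$k != index$config$k)
    stop("k mismatch: config k = ", config$k, " but index was built with k = ",
         index$config$k, call. = FALSE)
  cst <- index$cst
  node_query <- unique(unlist(cst$node_kmers, use.names = FALSE))
  mat_query <- unique(unlist(lapply(index$matrices, `[[`, "kmers"),
                             use.names = FALSE))
  query <- unique(c(node_query, mat_query))
  if (is.null(reads) && is.null(fastq_paths))
    stop("either 'fastq_paths' or 'reads' required", call. = FALSE)
  if (is.null(reads)) reads <- read_fastq(fastq_paths)
  empty <- relative_abundance_empty()
  if (length(reads) == 0L) {
    warning("no reads in input; empty profile", call. = FALSE)
    attr(empty, "cluster_hits") <- NULL
    return(empty)
  }
  counts <- count_kmers_in_reads(query = query, k = cst$k, reads = reads)
  hits <- search_clusters(index, config = config, counts = counts)
  if (nrow(hits) == 0L) {
    attr(empty, "cluster_hits") <- hits
    return(empty)
  }
  cluster_A <- setNames(hits$A, hits$cluster_id)
  results <- list()
  diag <- list()
  for (cid in hits$cluster_id) {
    m <- index$matrices[[cid]]
    y <- counts$counts[match(m$kmers, names(counts$counts))]
    y[is.na(y)] <- 0
    y <- as.numeric(y)
    other <- index$cluster_union[setdiff(hits$cluster_id, cid)]
    y <- mask_cross_cluster(y, m, other)
    masked <- attr(y, "masked")
    det <- iterative_strain_detection(m, as.numeric(y),
                                      stop_kmers = config$stop_kmers,
                                      stop_scale_rows = config$stop_scale_rows)
    if (!length(det$selected)) next
    drop_rows <- sort(unique(c(masked, det$trimmed)))
    beta <- estimate_depths(m$X[, det$selected, drop = FALSE],
                            det$y, exclude = drop_rows,
                            en_alpha_grid = config$en_alpha_grid,
                            nfolds = config$nfolds, seed = config$seed)
    results[[cid]] <- list(cluster_id = cid, beta = beta)
    diag[[cid]] <- list(selected = det$selected, scores = det$scores,
                        tuning = attr(beta, "tuning"),
                        n_masked = length(masked),
                        n_trimmed = length(det$trimmed))
  }
  prof <- if (length(results)) {
    suppressWarnings(relative_abundance(results, cluster_A))
  } else empty
  attr(prof, "cluster_hits") <- hits
  attr(prof, "diagnostics") <- list(
    clusters = diag,
    depth_conversion = 250 / (250 - cst$k + 1))
  prof
}

relative_abundance_empty <- function() {
  out <- data.frame(strain_id = character(0), cluster_id = character(0),
                    rank = integer(0), depth = numeric(0),
                    within_cluster_abundance = numeric(0),
                    relative_abundance = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("strain_profile", class(out))
  out
}

#' Write a strain profile to TSV
#'
#' @param profile a `"strain_profile"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num])
    if (!is.integer(df[[cn]])) df[[cn]] <- sprintf("%.6f", df[[cn]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Evaluate a predicted profile against a truth profile
#'
#' Convenience wrapper combining [prf()] at both levels with the
#' Jensen-Shannon divergence of the abundance vectors.
#'
#' @param truth named numeric vector of true relative abundances
#'   (strain_id -> abundance).
#' @param predicted named numeric vector of predicted relative abundances.
#' @param cluster_map named character vector strain_id -> cluster_id
#'   (enables cluster-level metrics).
#' @return A one-row data.frame with strain-level TP/FP/FN,
#'   precision/recall/F1, JSD, and cluster-level metrics when a map is
#'   given.
#' @export
evaluate_profile <- function(truth, predicted, cluster_map = NULL) {
  stopifnot(!is.null(names(truth)))
  s <- prf(names(truth), names(predicted), "strain")
  out <- data.frame(TP = s$TP, FP = s$FP, FN = s$FN,
                    precision = s$precision, recall = s$recall, f1 = s$f1)
  if (!is.null(cluster_map)) {
    cl <- prf(names(truth), names(predicted), "cluster", cluster_map)
    out$cluster_precision <- cl$precision
    out$cluster_recall <- cl$recall
    out$cluster_f1 <- cl$f1
  }
  out$jsd <- if (length(predicted)) jsd(truth, predicted) else 1
  out
}
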