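INDEX_FORMAT_VERSION <- "1"

#' Build a strainsift index from reference genomes
#'
#' Full indexing pipeline: extract canonical k-mer sets per genome,
#' dereplicate near-identical references (complete linkage at
#' `derep_threshold`, keeping the member with the highest average
#' similarity), cluster the representatives by single linkage at `H`, build
#' the cluster search tree with prevalence-filtered leaf sets, augment weak
#' nodes, and construct one discriminative k-mer matrix per cluster.
#'
#' @param genomes named character vector of genome sequences, a directory
#'   containing FASTA files, or a character vector of FASTA paths.
#' @param config a [run_config()].
#' @return An object of class `"strainsift_index"`: list with `config`,
#'   `manifest` (genome_id, cluster_id, representative, n_kmers),
#'   `similarity` (representatives), `assignment`, `cst`, `cluster_union`
#'   (per-cluster union of member strain k-mers) and `matrices` (per-cluster
#'   `strain_matrix`).
#' @export
build_index <- function(genomes, config = run_config()) {
  seqs <- .load_genomes(genomes)
  if (length(seqs) == 0L) stop("no input genomes", call. = FALSE)
  sets <- lapply(names(seqs), function(id)
    extract_canonical_kmers(unname(seqs[[id]]), k = config$k,
                            genome_id = id))
  names(sets) <- names(seqs)
  S_all <- build_similarity_matrix(sets)
  reps <- dereplicate(S_all, config$derep_threshold)
  dropped <- setdiff(names(seqs), reps)
  if (length(dropped))
    warning("dereplicated ", length(dropped), " near-identical genome(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  S <- S_all[reps, reps, drop = FALSE]
  assignment <- single_linkage_clusters(S, config$H)
  leaf_sets <- build_leaf_sets(assignment, sets, config$alpha)
  cst <- build_cst(assignment$cluster_tree, leaf_sets, k = config$k)
  cst <- .prune_nonunique_node_kmers(cst, sets[reps], assignment$clusters)
  cst <- augment_weak_nodes(cst, sets[reps], assignment$clusters,
                            config$min_kmers)
  cluster_union <- lapply(assignment$clusters, function(members)
    sort(unique(unlist(lapply(sets[members], .kmers_of),
                       use.names = FALSE))))
  matrices <- lapply(names(assignment$clusters), function(cid)
    build_strain_matrix(lapply(sets[assignment$clusters[[cid]]], .kmers_of),
                        cluster_id = cid,
                        cap_single = config$single_strain_cap))
  names(matrices) <- names(assignment$clusters)
  membership <- assignment$membership
  manifest <- data.frame(
    genome_id = names(seqs),
    cluster_id = ifelse(names(seqs) %in% reps,
                        unname(membership[names(seqs)]), NA_character_),
    representative = names(seqs) %in% reps,
    n_kmers = vapply(sets, function(s) length(s$kmers), integer(1)),
    stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  structure(list(config = config, manifest = manifest, similarity = S,
                 assignment = assignment, cst = cst,
                 cluster_union = cluster_union, matrices = matrices),
            class = "strainsift_index")
}

# Normalise genome input to a named list genome_id -> character vector of
# contig sequences. Accepts a named character vector of sequences, a
# directory of FASTA files, or a vector of FASTA paths.
.load_genomes <- function(genomes) {
  if (is.character(genomes) && !is.null(names(genomes)) &&
      !any(file.exists(genomes)))
    return(lapply(as.list(toupper(genomes)), unname))
  if (is.character(genomes) && length(genomes) == 1L &&
      dir.exists(genomes)) {
    files <- sort(list.files(genomes, "\\.(fa|fasta|fna)(\\.gz)?$",
                             full.names = TRUE))
    if (!length(files)) stop("no FASTA files in ", genomes, call. = FALSE)
    genomes <- files
  }
  if (is.character(genomes) && all(file.exists(genomes))) {
    errs <- character(0)
    out <- list()
    for (f in genomes) {
      res <- tryCatch(list(ok = read_fasta(f)), error = function(e)
        list(err = conditionMessage(e)))
      if (!is.null(res$err)) {
        errs <- c(errs, res$err)
      } else {
        id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(f))
        out[[id]] <- unname(res$ok)
      }
    }
    if (length(errs)) stop("unreadable FASTA input:\n  ",
                           paste(errs, collapse = "\n  "), call. = FALSE)
    return(out)
  }
  stop("cannot interpret 'genomes' input", call. = FALSE)
}

#' @export
print.strainsift_index <- function(x, ...) {
  cat(sprintf("strainsift index: %d genomes (%d representatives), %d clusters, k = %d\n",
              nrow(x$manifest), sum(x$manifest$representative),
              length(x$assignment$clusters), x$config$k))
  print(x$cst)
  invisible(x)
}

.fmt_num <- function(x) sprintf("%.17g", x)

#' Serialize an index to a directory
#'
#' Writes a versioned plain-text index layout: `config.json`,
#' `manifest.tsv`, `similarity.tsv`, `tree.tsv`, `node_kmers.tsv` (long
#' format with an `augmented` flag), `cluster_unions.tsv` and one matrix
#' TSV per cluster under `matrices/`. Output is deterministic: the same
#' index serializes to byte-identical files.
#'
#' @param index a `"strainsift_index"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_index <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "matrices"), showWarnings = FALSE)
  cfg <- index$config
  cfg_out <- c(list(format_version = INDEX_FORMAT_VERSION),
               unclass(cfg))
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(index$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  S <- index$similarity
  sim_df <- data.frame(genome_id = rownames(S),
                       apply(S, 2L, .fmt_num),
                       stringsAsFactors = FALSE, check.names = FALSE)
  write.table(sim_df, file.path(dir, "similarity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(index$cst$tree, file.path(dir, "tree.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  nk <- index$cst$node_kmers
  aug <- index$cst$augmented
  node_df <- do.call(rbind, lapply(index$cst$tree$node_id, function(v) {
    kms <- nk[[v]]
    if (!length(kms)) return(NULL)
    data.frame(node_id = v, kmer = kms,
               augmented = as.integer(kms %in% aug[[v]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(node_df))
    node_df <- data.frame(node_id = character(0), kmer = character(0),
                          augmented = integer(0))
  write.table(node_df, file.path(dir, "node_kmers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cu <- do.call(rbind, lapply(names(index$cluster_union), function(cid)
    data.frame(cluster_id = cid, kmer = index$cluster_union[[cid]],
               stringsAsFactors = FALSE)))
  write.table(cu, file.path(dir, "cluster_unions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (cid in names(index$matrices)) {
    m <- index$matrices[[cid]]
    df <- data.frame(kmer = m$kmers, pattern_class = m$pattern_class,
                     stringsAsFactors = FALSE)
    for (sid in m$strain_ids) df[[sid]] <- as.integer(m$X[, sid])
    attr_line <- sprintf("#single_strain=%d", as.integer(m$single_strain))
    path <- file.path(dir, "matrices", paste0(cid, ".tsv"))
    con <- file(path, "wb")
    writeLines(attr_line, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(dir)
}

#' Load a serialized index
#'
#' @param dir directory written by [write_index()].
#' @return A `"strainsift_index"` equivalent to the serialized one (the
#'   in-memory `assignment` is restored in reduced form: clusters and
#'   membership, without the strain dendrogram).
#' @export
read_index <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path))
    stop("not an index directory (missing config.json): ", dir,
         call. = FALSE)
  cfg <- tryCatch(jsonlite::read_json(cfg_path, simplifyVector = TRUE),
                  error = function(e)
                    stop("corrupt index config: ", conditionMessage(e),
                         call. = FALSE))
  if (is.null(cfg$format_version) ||
      !identical(as.character(cfg$format_version), INDEX_FORMAT_VERSION))
    stop("index format version mismatch (found ",
         cfg$format_version %||% "none", ", expected ",
         INDEX_FORMAT_VERSION, ")", call. = FALSE)
  cfg$format_version <- NULL
  config <- do.call(run_config, cfg)
  req <- c("manifest.tsv", "similarity.tsv", "tree.tsv", "node_kmers.tsv",
           "cluster_unions.tsv")
  miss <- req[!file.exists(file.path(dir, req))]
  if (length(miss))
    stop("corrupt index: missing ", paste(miss, collapse = ", "),
         call. = FALSE)
  manifest <- read.delim(file.path(dir, "manifest.tsv"),
                         stringsAsFactors = FALSE)
  manifest$representative <- as.logical(manifest$representative)
  sim <- read.delim(file.path(dir, "similarity.tsv"), check.names = FALSE,
                    stringsAsFactors = FALSE)
  S <- as.matrix(sim[, -1, drop = FALSE])
  rownames(S) <- sim$genome_id
  mode(S) <- "numeric"
  tree <- read.delim(file.path(dir, "tree.tsv"), stringsAsFactors = FALSE,
                     na.strings = "NA")
  tree$is_leaf <- as.logical(tree$is_leaf)
  rownames(tree) <- tree$node_id
  node_df <- read.delim(file.path(dir, "node_kmers.tsv"),
                        stringsAsFactors = FALSE)
  node_kmers <- setNames(vector("list", nrow(tree)), tree$node_id)
  augmented <- setNames(vector("list", nrow(tree)), tree$node_id)
  for (v in tree$node_id) {
    sel <- node_df$node_id == v
    node_kmers[[v]] <- node_df$kmer[sel]
    aug <- node_df$kmer[sel & node_df$augmented == 1L]
    if (length(aug)) augmented[[v]] <- aug
  }
  cst <- structure(list(tree = tree, node_kmers = node_kmers,
                        augmented = augmented, k = config$k),
                   class = "cst")
  cu_df <- read.delim(file.path(dir, "cluster_unions.tsv"),
                      stringsAsFactors = FALSE)
  cluster_union <- split(cu_df$kmer, cu_df$cluster_id)
  cid_order <- function(ids) ids[order(suppressWarnings(
    as.integer(sub("^C", "", ids))), ids)]
  cluster_union <- cluster_union[cid_order(names(cluster_union))]
  mat_files <- list.files(file.path(dir, "matrices"), "\\.tsv$",
                          full.names = TRUE)
  matrices <- lapply(mat_files, .read_matrix_tsv)
  names(matrices) <- vapply(matrices, `[[`, character(1), "cluster_id")
  matrices <- matrices[cid_order(names(matrices))]
  clusters <- lapply(matrices, `[[`, "strain_ids")
  membership <- rep(names(clusters), lengths(clusters))
  names(membership) <- unlist(clusters, use.names = FALSE)
  assignment <- structure(list(dendrogram = NULL, clusters = clusters,
                               membership = membership, H = config$H,
                               cluster_tree = tree),
                          class = "cluster_assignment")
  structure(list(config = config, manifest = manifest, similarity = S,
                 assignment = assignment, cst = cst,
                 cluster_union = cluster_union, matrices = matrices),
            class = "strainsift_index")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_matrix_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#single_strain=", first))
    stop("corrupt matrix file: ", path, call. = FALSE)
  single <- grepl("=1$", first)
  df <- read.delim(path, skip = 1L, stringsAsFactors = FALSE,
                   check.names = FALSE)
  sids <- setdiff(colnames(df), c("kmer", "pattern_class"))
  X <- as.matrix(df[, sids, drop = FALSE]) == 1L
  colnames(X) <- sids
  rownames(X) <- NULL
  structure(list(cluster_id = sub("\\.tsv$", "", basename(path)),
                 kmers = df$kmer, strain_ids = sids, X = X,
                 pattern_class = df$pattern_class,
                 single_strain = single),
            class = "strain_matrix")
}
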