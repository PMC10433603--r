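#' Discriminative k-mer presence matrix of a cluster
#'
#' Builds the binary matrix `X` (k-mers x strains) used to tell apart the
#' highly similar strains of one cluster: every k-mer of every member strain
#' is hashed to its presence bit-pattern across the strains and rows with a
#' non-constant pattern are kept. Rows are annotated by pattern class:
#' `strain_specific` (present in exactly one strain), `joint` (a SNV/indel
#' alternative: a Hamming-distance-1 partner k-mer with the complementary
#' pattern exists in the matrix) or `group_specific` (shared structural
#' variants). The annotation is diagnostic; identification uses all rows.
#'
#' Single-strain clusters get a degenerate matrix: an evenly spaced sample
#' (up to `cap_single`) of the strain's k-mers with one all-ones column,
#' used only for depth estimation.
#'
#' @param cluster_kmers named list strain_id -> `kmer_set`/character vector
#'   for the members of one cluster.
#' @param cluster_id identifier stored with the matrix.
#' @param cap_single k-mer cap for the single-strain degenerate matrix.
#' @param annotate_joint set `FALSE` to skip the Hamming-1 scan (cheaper).
#' @return An object of class `"strain_matrix"`: list with `cluster_id`,
#'   `kmers` (row names, sorted), `strain_ids`, logical matrix `X`,
#'   `pattern_class` and `single_strain` flag.
#' @export
build_strain_matrix <- function(cluster_kmers, cluster_id = "C1",
                                cap_single = 5000L, annotate_joint = TRUE) {
  if (length(cluster_kmers) == 0L)
    stop("empty cluster", call. = FALSE)
  sets <- lapply(cluster_kmers, .kmers_of)
  ids <- names(sets)
  if (is.null(ids) || anyDuplicated(ids))
    stop("cluster strains must have unique names", call. = FALSE)
  if (length(sets) == 1L) {
    kms <- sort(sets[[1]])
    if (length(kms) > cap_single)
      kms <- kms[round(seq(1L, length(kms), length.out = cap_single))]
    X <- matrix(TRUE, length(kms), 1L, dimnames = list(NULL, ids))
    return(structure(list(cluster_id = cluster_id, kmers = kms,
                          strain_ids = ids, X = X,
                          pattern_class = rep("core", length(kms)),
                          single_strain = TRUE),
                     class = "strain_matrix"))
  }
  u <- sort(unique(unlist(sets, use.names = FALSE)))
  X <- vapply(sets, function(s) u %in% s, logical(length(u)))
  rs <- rowSums(X)
  keep <- rs > 0L & rs < length(sets)
  if (!any(keep))
    stop("strain columns are not distinct: ",
         paste(ids, collapse = ", "), call. = FALSE)
  X <- X[keep, , drop = FALSE]
  kms <- u[keep]
  rs <- rs[keep]
  # identifiability: all columns distinct
  colkey <- apply(X, 2L, function(col) paste(as.integer(col), collapse = ""))
  if (anyDuplicated(colkey)) {
    dup <- ids[colkey %in% colkey[duplicated(colkey)]]
    stop("strain columns are not distinct: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  cls <- ifelse(rs == 1L, "strain_specific", "group_specific")
  if (annotate_joint) {
    code <- as.integer(X %*% 2^(seq_len(ncol(X)) - 1L))
    full <- 2^ncol(X) - 1L
    joint <- .has_complementary_neighbor(kms, code, full)
    cls[joint & rs > 1L] <- "joint"
  }
  structure(list(cluster_id = cluster_id, kmers = kms, strain_ids = ids,
                 X = X, pattern_class = cls, single_strain = FALSE),
            class = "strain_matrix")
}

# TRUE for k-mers having a Hamming-distance-1 canonical neighbour in the
# same matrix whose presence pattern is the bitwise complement of theirs
# (the signature of a substitution alternative in shared context).
.has_complementary_neighbor <- function(kms, code, full) {
  if (!length(kms)) return(logical(0))
  k <- nchar(kms[[1]])
  pat_of <- code
  names(pat_of) <- kms
  hit <- logical(length(kms))
  bases <- c("A", "C", "G", "T")
  for (pos in seq_len(k)) {
    cur <- substr(kms, pos, pos)
    for (b in bases) {
      sel <- which(cur != b & !hit)
      if (!length(sel)) next
      nb <- kms[sel]
      substr(nb, pos, pos) <- b
      nb <- cpp_canonicalize(nb)
      m <- match(nb, kms)
      ok <- !is.na(m) & (code[m] == full - code[sel])
      hit[sel[ok]] <- TRUE
    }
  }
  hit
}

#' @export
print.strain_matrix <- function(x, ...) {
  cat(sprintf("strain matrix for %s: %d k-mers x %d strains\n",
              x$cluster_id, length(x$kmers), length(x$strain_ids)))
  print(table(x$pattern_class))
  invisible(x)
}
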