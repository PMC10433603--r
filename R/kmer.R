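#' Canonical k-mer set of a genome
#'
#' Extracts all canonical k-mers (the lexicographically smaller of a window
#' and its reverse complement) from one or more sequence records, e.g. the
#' contigs of one genome. Windows containing any non-ACGT character are
#' skipped; input case is folded.
#'
#' @param seqs character vector of sequences (contigs/records), or a path to
#'   a FASTA file.
#' @param k odd k-mer length between 1 and 63. Default 31.
#' @param genome_id identifier stored with the set; defaults to the name of
#'   the first record or the file name.
#' @return An object of class `"kmer_set"`: list with `genome_id`, `k` and
#'   the sorted character vector `kmers`.
#' @examples
#' ks <- extract_canonical_kmers(c(g = "ACGT"), k = 3)
#' ks$kmers  # "ACG": the two windows are reverse complements of each other
#' @export
extract_canonical_kmers <- function(seqs, k = 31L, genome_id = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 63L || k %% 2L == 0L)
    stop("'k' must be an odd integer between 1 and 63", call. = FALSE)
  if (is.character(seqs) && length(seqs) == 1L && is.null(names(seqs)) &&
      file.exists(seqs)) {
    if (is.null(genome_id))
      genome_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(seqs))
    seqs <- read_fasta(seqs)
  }
  if (length(seqs) == 0L)
    stop("no input sequences", call. = FALSE)
  if (is.null(genome_id))
    genome_id <- if (!is.null(names(seqs))) names(seqs)[[1]] else "genome"
  kmer_set(genome_id, cpp_extract_kmers(as.character(seqs), k), k,
           validate = FALSE)
}

#' Construct a k-mer set object
#'
#' @param genome_id identifier of the genome the set was derived from.
#' @param kmers character vector of canonical k-mers.
#' @param k k-mer length.
#' @param validate check that all keys are canonical, length-k ACGT strings.
#' @return An object of class `"kmer_set"`.
#' @export
kmer_set <- function(genome_id, kmers, k, validate = TRUE) {
  k <- as.integer(k)
  kmers <- sort(unique(as.character(kmers)))
  if (validate && length(kmers)) {
    if (any(nchar(kmers) != k))
      stop("all k-mers must have length k = ", k, call. = FALSE)
    canon <- cpp_canonicalize(kmers)
    if (anyNA(canon) || any(canon != kmers))
      stop("k-mer keys must be canonical ACGT strings", call. = FALSE)
  }
  structure(list(genome_id = genome_id, k = k, kmers = kmers),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("kmer_set '%s': %d canonical %d-mers\n",
              x$genome_id, length(x$kmers), x$k))
  invisible(x)
}

.kmers_of <- function(x) {
  if (inherits(x, "kmer_set")) x$kmers else as.character(x)
}

#' Canonicalize k-mers
#'
#' Maps each k-mer to the lexicographically smaller of itself and its
#' reverse complement. Strings containing non-ACGT characters yield `NA`.
#'
#' @param kmers character vector.
#' @return Character vector of canonical forms.
#' @export
canonicalize <- function(kmers) cpp_canonicalize(as.character(kmers))

#' Reverse complement
#'
#' @param seqs character vector of DNA sequences.
#' @return Character vector of reverse complements (non-ACGT characters
#'   become `N`).
#' @export
revcomp <- function(seqs) cpp_revcomp(as.character(seqs))

#' Count query k-mers in sequencing reads
#'
#' Streams all reads and counts, for every canonical k-mer in `query`, how
#' often it occurs (canonically, i.e. on either strand) across the reads.
#' K-mers outside the query are not stored; query k-mers never observed get
#' count 0.
#'
#' @param fastq_paths character vector of FASTQ paths (single or paired,
#'   gzip allowed). Ignored when `reads` is given.
#' @param query character vector (or `kmer_set`) of canonical k-mers.
#' @param k k-mer length.
#' @param reads optional character vector of read sequences, bypassing file
#'   input.
#' @return An object of class `"kmer_count_table"`: list with `k` and the
#'   named integer vector `counts` (names = query k-mers).
#' @export
count_kmers_in_reads <- function(fastq_paths = NULL, query, k = 31L,
                                 reads = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 63L || k %% 2L == 0L)
    stop("'k' must be an odd integer between 1 and 63", call. = FALSE)
  query <- .kmers_of(query)
  if (length(query) == 0L) stop("'query' must be non-empty", call. = FALSE)
  if (is.null(reads)) {
    if (is.null(fastq_paths)) stop("either 'fastq_paths' or 'reads' required",
                                   call. = FALSE)
    reads <- read_fastq(fastq_paths)
  }
  counts <- cpp_count_kmers(as.character(reads), k, query)
  names(counts) <- query
  structure(list(k = k, counts = counts), class = "kmer_count_table")
}

#' Exact Jaccard similarity of two k-mer sets
#'
#' `|A` \eqn{\cap} `B| / |A` \eqn{\cup} `B|`, computed on the full sets (no
#' sketching).
#'
#' @param a,b `kmer_set` objects (or plain character vectors) built with the
#'   same k.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (inherits(a, "kmer_set") && inherits(b, "kmer_set") && a$k != b$k)
    stop("k mismatch between k-mer sets (", a$k, " vs ", b$k, ")",
         call. = FALSE)
  ka <- .kmers_of(a); kb <- .kmers_of(b)
  if (length(ka) == 0L && length(kb) == 0L)
    stop("Jaccard similarity undefined for two empty sets", call. = FALSE)
  inter <- sum(ka %in% kb)
  inter / (length(ka) + length(kb) - inter)
}

#' Mash distance from a Jaccard similarity
#'
#' Point estimate of the mutation distance between two genomes from their
#' k-mer Jaccard similarity `j`: `-(1/k) * log(2j / (1 + j))`. Identical
#' sets give 0; disjoint sets are capped at 1.
#'
#' @param j Jaccard similarity in `[0, 1]`.
#' @param k k-mer length used to compute `j`.
#' @return Distance `>= 0`.
#' @export
mash_distance <- function(j, k = 31L) {
  if (any(!is.finite(j)) || any(j < 0) || any(j > 1))
    stop("'j' must lie in [0, 1]", call. = FALSE)
  d <- ifelse(j == 1, 0,
              ifelse(j == 0, 1, pmin(1, -log(2 * j / (1 + j)) / k)))
  d
}
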