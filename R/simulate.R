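#' Configuration for the synthetic strain-set generator
#'
#' Describes a synthetic species: an ancestral genome from which one
#' ancestor per cluster is evolved (between-cluster rates), and from each
#' cluster ancestor the individual strains (within-cluster rates plus small
#' structural events). The defaults produce within-cluster k-mer Jaccard
#' similarities of roughly 0.96--0.98 -- above the default clustering cutoff
#' of 0.95 yet safely below the 0.99 dereplication threshold -- and
#' between-cluster similarities well below the cutoff, the similarity
#' regime the hierarchical search is designed for; the generator verifies
#' the cutoff empirically after generation and retries with a derived seed
#' a bounded number of times.
#'
#' @param genome_length ancestral genome length in bp. Default 50000 (a
#'   desk-scale stand-in for Mb-sized bacterial genomes; all k-mer
#'   statistics scale linearly with length).
#' @param n_clusters number of strain clusters. Default 6.
#' @param strains_per_cluster integer vector (recycled) of cluster sizes.
#'   Default `c(5, 4, 4, 3, 2, 2)` (20 strains).
#' @param between_sub_rate,between_indel_rate per-base substitution/indel
#'   rates on the ancestor -> cluster-ancestor branches.
#' @param between_sv_events mean number (Poisson) of structural events
#'   (deletion or tandem duplication) per cluster ancestor.
#' @param between_sv_len structural event length range (bp).
#' @param within_sub_rate,within_indel_rate per-base rates on the cluster
#'   ancestor -> strain branches.
#' @param within_sv_prob probability that a strain carries one structural
#'   event.
#' @param within_sv_len event length range within clusters.
#' @param indel_geom_p geometric length parameter for small indels.
#' @param k k-mer length used for the post-generation similarity check.
#' @param check_H similarity cutoff the generated set must respect
#'   (within-cluster Jaccard >= `check_H`, between-cluster < `check_H`).
#' @param max_retries bounded retries when the similarity targets are
#'   missed.
#' @param seed integer seed; generation is bit-for-bit reproducible.
#' @return List of class `"strain_sim_config"`.
#' @export
strain_sim_config <- function(genome_length = 50000L, n_clusters = 6L,
                              strains_per_cluster = c(5L, 4L, 4L, 3L, 2L, 2L),
                              between_sub_rate = 0.02,
                              between_indel_rate = 1e-3,
                              between_sv_events = 2,
                              between_sv_len = c(500L, 2000L),
                              within_sub_rate = 2.4e-4,
                              within_indel_rate = 2e-5,
                              within_sv_prob = 0.25,
                              within_sv_len = c(80L, 150L),
                              indel_geom_p = 0.5,
                              k = 31L, check_H = 0.95,
                              max_retries = 5L, seed = 1L) {
  rates <- c(between_sub_rate, between_indel_rate, within_sub_rate,
             within_indel_rate, within_sv_prob)
  if (any(rates < 0) || any(rates >= 1))
    stop("rates must lie in [0, 1)", call. = FALSE)
  if (genome_length <= 0) stop("genome_length must be positive",
                               call. = FALSE)
  structure(list(genome_length = as.integer(genome_length),
                 n_clusters = as.integer(n_clusters),
                 strains_per_cluster =
                   rep_len(as.integer(strains_per_cluster),
                           as.integer(n_clusters)),
                 between_sub_rate = between_sub_rate,
                 between_indel_rate = between_indel_rate,
                 between_sv_events = between_sv_events,
                 between_sv_len = as.integer(between_sv_len),
                 within_sub_rate = within_sub_rate,
                 within_indel_rate = within_indel_rate,
                 within_sv_prob = within_sv_prob,
                 within_sv_len = as.integer(within_sv_len),
                 indel_geom_p = indel_geom_p,
                 k = as.integer(k), check_H = check_H,
                 max_retries = as.integer(max_retries),
                 seed = as.integer(seed)),
            class = "strain_sim_config")
}

#' Configuration for the paired-end read simulator
#'
#' Mirrors the conventional Illumina simulation protocol for paired 250 bp
#' reads with a normal fragment length of mean 600 and sd 150 and a uniform
#' substitution error rate (1% by default, matching the scalar error rate
#' assumed by the binomial traversal test). Quality strings are constant.
#'
#' @param read_length read length in bp. Default 250.
#' @param paired simulate read pairs (default) or single-end reads.
#' @param fragment_mean,fragment_sd fragment length distribution;
#'   fragments are truncated to `[read_length, genome length]`.
#' @param depth target per-base sequencing depth (fold coverage).
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @return List of class `"read_sim_config"`.
#' @export
read_sim_config <- function(read_length = 250L, paired = TRUE,
                            fragment_mean = 600, fragment_sd = 150,
                            depth = 10, error_rate = 0.01, seed = 1L) {
  if (depth <= 0) stop("'depth' must be positive", call. = FALSE)
  if (read_length > fragment_mean)
    stop("read length must not exceed the mean fragment length",
         call. = FALSE)
  if (error_rate < 0 || error_rate >= 1)
    stop("'error_rate' must lie in [0, 1)", call. = FALSE)
  structure(list(read_length = as.integer(read_length), paired = paired,
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 depth = depth, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

.BASES <- c("A", "C", "G", "T")

.random_genome <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# apply substitutions, small indels and structural events to a genome
# string; returns list(seq, n_sub, n_indel, n_sv)
.mutate_genome <- function(seq, sub_rate, indel_rate, sv_events = 0,
                           sv_len = c(100L, 250L), indel_geom_p = 0.5) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  n_sub <- rbinom(1L, L, sub_rate)
  if (n_sub > 0L) {
    pos <- sample.int(L, n_sub)
    for (p in pos) {
      chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
    }
  }
  n_indel <- rbinom(1L, L, indel_rate)
  if (n_indel > 0L) {
    for (i in seq_len(n_indel)) {
      p <- sample.int(length(chars), 1L)
      len <- min(rgeom(1L, indel_geom_p) + 1L, 10L)
      if (runif(1) < 0.5) {                        # deletion
        chars <- chars[-(p:min(p + len - 1L, length(chars)))]
      } else {                                    # insertion
        ins <- sample(.BASES, len, replace = TRUE)
        chars <- append(chars, ins, after = p)
      }
    }
  }
  n_sv <- if (sv_events <= 0) 0L
  else if (sv_events < 1) rbinom(1L, 1L, sv_events)
  else rpois(1L, sv_events)
  if (n_sv > 0L) {
    for (i in seq_len(n_sv)) {
      len <- sample(seq(sv_len[1], sv_len[2]), 1L)
      if (length(chars) <= len + 1L) next
      p <- sample.int(length(chars) - len, 1L)
      if (runif(1) < 0.5) {                        # segment deletion
        chars <- chars[-(p:(p + len - 1L))]
      } else {                                    # tandem duplication
        chars <- append(chars, chars[p:(p + len - 1L)], after = p + len - 1L)
      }
    }
  }
  list(seq = paste(chars, collapse = ""), n_sub = n_sub,
       n_indel = n_indel, n_sv = n_sv)
}

#' Simulate a synthetic strain set with controlled similarity structure
#'
#' Generates an ancestral genome, evolves one ancestor per cluster and from
#' it the member strains, then verifies with exact k-mer Jaccard that every
#' within-cluster pair is at least as similar as `check_H` and every
#' between-cluster pair less similar; on failure the whole set is
#' regenerated with a derived seed up to `max_retries` times.
#'
#' @param config a [strain_sim_config()].
#' @param out_dir optional directory; when given, one FASTA per strain and a
#'   `manifest.tsv` are written there.
#' @return List with `sequences` (named character vector, names =
#'   strain ids `S01`, ...), `manifest` (data.frame with `strain_id`,
#'   `cluster_id`, `length`, mutation counts) and `similarity` (the k-mer
#'   Jaccard matrix of the generated set).
#' @export
simulate_strain_set <- function(config = strain_sim_config(),
                                out_dir = NULL) {
  for (attempt in 0:config$max_retries) {
    seed <- config$seed + attempt * 7919L
    res <- .simulate_strain_set_once(config, seed)
    if (res$ok) break
  }
  if (!res$ok)
    stop("similarity targets (within >= ", config$check_H,
         ", between < ", config$check_H, ") unreachable after ",
         config$max_retries + 1L,
         " attempts; adjust the mutation rates", call. = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(res$sequences))
      write_fasta(res$sequences[id], file.path(out_dir, paste0(id, ".fasta")))
    write.table(res$manifest, file.path(out_dir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res[c("sequences", "manifest", "similarity")]
}

.simulate_strain_set_once <- function(config, seed) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  anc <- .random_genome(config$genome_length)
  seqs <- character(0)
  rows <- list()
  cluster_of <- character(0)
  s_idx <- 0L
  for (ci in seq_len(config$n_clusters)) {
    canc <- .mutate_genome(anc, config$between_sub_rate,
                           config$between_indel_rate,
                           config$between_sv_events,
                           config$between_sv_len,
                           config$indel_geom_p)
    for (si in seq_len(config$strains_per_cluster[ci])) {
      s_idx <- s_idx + 1L
      mut <- .mutate_genome(canc$seq, config$within_sub_rate,
                            config$within_indel_rate,
                            config$within_sv_prob,
                            config$within_sv_len,
                            config$indel_geom_p)
      id <- sprintf("S%02d", s_idx)
      seqs[id] <- mut$seq
      cluster_of[id] <- sprintf("T%d", ci)
      rows[[s_idx]] <- data.frame(
        strain_id = id, cluster_id = sprintf("T%d", ci),
        length = nchar(mut$seq), n_sub = mut$n_sub,
        n_indel = mut$n_indel, n_sv = mut$n_sv,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  # empirical similarity check
  sets <- lapply(names(seqs), function(id)
    extract_canonical_kmers(seqs[id], k = config$k, genome_id = id))
  S <- build_similarity_matrix(sets)
  ok <- TRUE
  for (i in seq_len(nrow(S) - 1L)) {
    for (j in seq(i + 1L, nrow(S))) {
      same <- cluster_of[rownames(S)[i]] == cluster_of[rownames(S)[j]]
      if (same && S[i, j] < config$check_H) ok <- FALSE
      if (!same && S[i, j] >= config$check_H) ok <- FALSE
    }
  }
  list(ok = ok, sequences = seqs, manifest = manifest, similarity = S)
}

#' Simulate paired-end reads from one genome
#'
#' Fragment starts are uniform over the genome; fragment lengths are
#' normal(`fragment_mean`, `fragment_sd`) truncated to
#' `[read_length, genome length]`; each fragment is sequenced from a random
#' strand, read 1 from its 5' end and read 2 as the reverse complement of
#' its 3' end. Substitution errors are uniform at `error_rate`. The number
#' of pairs is `round(depth * L / (2 * read_length))`.
#'
#' @param genome a single sequence (character string) or path to a FASTA.
#' @param config a [read_sim_config()].
#' @param out_prefix optional path prefix; when given, reads are written to
#'   `<prefix>_1.fastq` and `<prefix>_2.fastq` (or `<prefix>.fastq` for
#'   single-end) and the paths are returned in `files`.
#' @return List with `r1`, `r2` (character vectors of read sequences; `r2`
#'   is `NULL` for single-end), `ids`, and optionally `files`.
#' @export
simulate_reads <- function(genome, config = read_sim_config(),
                           out_prefix = NULL) {
  if (length(genome) == 1L && is.null(names(genome)) &&
      nchar(genome) < 500L && file.exists(genome))
    genome <- read_fasta(genome)[[1]]
  genome <- toupper(as.character(genome)[[1]])
  L <- nchar(genome)
  if (L <= config$fragment_mean)
    stop("genome shorter than the mean fragment length", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  rl <- config$read_length
  n_pairs <- max(1L, as.integer(round(config$depth * L /
                                        ((if (config$paired) 2 else 1) * rl))))
  flen <- as.integer(round(rnorm(n_pairs, config$fragment_mean,
                                 config$fragment_sd)))
  flen <- pmin(pmax(flen, rl), L)
  start <- vapply(flen, function(f) sample.int(L - f + 1L, 1L), integer(1))
  frag <- substring(genome, start, start + flen - 1L)
  flip <- runif(n_pairs) < 0.5
  frag[flip] <- cpp_revcomp(frag[flip])
  r1 <- substring(frag, 1L, rl)
  if (config$paired) {
    r2 <- cpp_revcomp(substring(frag, flen - rl + 1L, flen))
  } else r2 <- NULL
  r1 <- .add_read_errors(r1, config$error_rate)
  if (!is.null(r2)) r2 <- .add_read_errors(r2, config$error_rate)
  ids <- sprintf("sim_%06d", seq_len(n_pairs))
  out <- list(r1 = r1, r2 = r2, ids = ids)
  if (!is.null(out_prefix)) {
    if (config$paired) {
      f1 <- paste0(out_prefix, "_1.fastq")
      f2 <- paste0(out_prefix, "_2.fastq")
      write_fastq(r1, f1, ids = paste0(ids, "/1"))
      write_fastq(r2, f2, ids = paste0(ids, "/2"))
      out$files <- c(f1, f2)
    } else {
      f1 <- paste0(out_prefix, ".fastq")
      write_fastq(r1, f1, ids = ids)
      out$files <- f1
    }
  }
  out
}

# uniform substitution errors over a vector of equal-ish length reads
.add_read_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  lens <- nchar(reads)
  total <- sum(lens)
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0L) return(reads)
  flat <- sort(sample.int(total, n_err))
  ends <- cumsum(lens)
  ridx <- findInterval(flat - 1L, c(0L, ends), rightmost.closed = FALSE)
  pos <- flat - c(0L, ends)[ridx]
  alt <- matrix(c("C", "G", "T",   # alternatives to A
                  "A", "G", "T",   # to C
                  "A", "C", "T",   # to G
                  "A", "C", "G"),  # to T
                nrow = 4L, byrow = TRUE)
  draw <- sample.int(3L, n_err, replace = TRUE)
  # apply errors round by round so multiple errors in one read all land
  remaining <- seq_len(n_err)
  while (length(remaining)) {
    first <- remaining[!duplicated(ridx[remaining])]
    cur <- reads[ridx[first]]
    orig <- substr(cur, pos[first], pos[first])
    newb <- alt[cbind(match(orig, .BASES), draw[first])]
    newb[is.na(newb)] <- "N"   # non-ACGT base hit by an error
    substr(cur, pos[first], pos[first]) <- newb
    reads[ridx[first]] <- cur
    remaining <- setdiff(remaining, first)
  }
  reads
}

#' Simulate a strain mixture read set
#'
#' Simulates reads per strain at the given depths, concatenates and
#' shuffles the pairs, and records the true relative abundance profile
#' `depth_i * length_i / sum_j depth_j * length_j`.
#'
#' @param sequences named character vector of strain genomes.
#' @param depths numeric vector of per-strain depths (same length/order as
#'   `sequences`).
#' @param config a [read_sim_config()] (its `depth` field is ignored).
#' @param out_prefix optional FASTQ path prefix, as in [simulate_reads()].
#' @return List with `r1`, `r2`, `ids`, `truth` (named true relative
#'   abundances) and optionally `files`.
#' @export
simulate_mixture <- function(sequences, depths,
                             config = read_sim_config(),
                             out_prefix = NULL) {
  if (length(depths) != length(sequences))
    stop("'depths' must match the number of strains", call. = FALSE)
  if (any(depths <= 0)) stop("depths must be positive", call. = FALSE)
  r1 <- r2 <- ids <- character(0)
  lens <- nchar(sequences)
  for (i in seq_along(sequences)) {
    ci <- config
    ci$depth <- depths[[i]]
    ci$seed <- config$seed + i * 131L
    rd <- simulate_reads(sequences[[i]], ci)
    r1 <- c(r1, rd$r1)
    if (config$paired) r2 <- c(r2, rd$r2)
    ids <- c(ids, paste0(names(sequences)[i], "_", rd$ids))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  perm <- sample.int(length(r1))
  r1 <- r1[perm]; ids <- ids[perm]
  if (config$paired) r2 <- r2[perm] else r2 <- NULL
  truth <- depths * lens / sum(depths * lens)
  names(truth) <- names(sequences)
  out <- list(r1 = r1, r2 = r2, ids = ids, truth = truth)
  if (!is.null(out_prefix)) {
    if (config$paired) {
      f1 <- paste0(out_prefix, "_1.fastq")
      f2 <- paste0(out_prefix, "_2.fastq")
      write_fastq(r1, f1, ids = paste0(ids, "/1"))
      write_fastq(r2, f2, ids = paste0(ids, "/2"))
      out$files <- c(f1, f2)
    } else {
      f1 <- paste0(out_prefix, ".fastq")
      write_fastq(r1, f1, ids = ids)
      out$files <- f1
    }
  }
  out
}
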