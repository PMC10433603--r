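#' Read genome sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]. Sequences are returned
#' as an uppercase named character vector; gzip-compressed files are read
#' transparently. Record names are truncated at the first whitespace.
#'
#' @param path path to a (possibly gzipped) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("failed to parse FASTA '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  if (length(ss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

#' Read sequences from FASTQ
#'
#' Strict 4-line-per-record parser so malformed input can be reported with
#' the index of the offending record. Gzip-compressed files are read
#' transparently. Quality strings are discarded (counting is not
#' quality-aware).
#'
#' @param paths character vector of FASTQ paths (e.g. an R1/R2 pair).
#' @return Character vector of read sequences (uppercase).
#' @export
read_fastq <- function(paths) {
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (!file.exists(p)) stop("FASTQ file not found: ", p, call. = FALSE)
    lines <- readLines(p)
    if (length(lines) == 0L) { out[[i]] <- character(); next }
    if (length(lines) %% 4L != 0L)
      stop(sprintf("malformed FASTQ '%s': truncated record %d", p,
                   length(lines) %/% 4L + 1L), call. = FALSE)
    hdr <- lines[seq(1L, length(lines), by = 4L)]
    plus <- lines[seq(3L, length(lines), by = 4L)]
    bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
    if (length(bad))
      stop(sprintf("malformed FASTQ '%s': bad record %d", p, bad[1L]),
           call. = FALSE)
    out[[i]] <- toupper(lines[seq(2L, length(lines), by = 4L)])
  }
  unlist(out, use.names = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads character vector of read sequences.
#' @param path output path; `.gz` triggers compression.
#' @param ids read identifiers (defaults to `read1`, `read2`, ...).
#' @param qual_char single character used to fill constant quality strings.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, ids = NULL, qual_char = "I") {
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(reads)) {
    quals <- vapply(nchar(reads), function(n)
      paste(rep(qual_char, n), collapse = ""), character(1))
    block <- rbind(paste0("@", ids), reads, "+", quals)
    writeLines(as.vector(block), con)
  }
  invisible(path)
}
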