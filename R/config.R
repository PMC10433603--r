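#' Pipeline configuration
#'
#' Bundles every tunable threshold of the indexing and search pipeline with
#' its default value. All stages take a `run_config` so that a run is fully
#' described by one object, and the configuration is serialized verbatim into
#' every index for provenance.
#'
#' @param k k-mer length (odd, 1--63). Default 31.
#' @param H similarity cutoff used to cut the single-linkage dendrogram into
#'   strain clusters; strains with pairwise Jaccard `>= H` end up in one
#'   cluster. Default 0.95.
#' @param alpha prevalence percentage for leaf k-mer sets: a k-mer enters a
#'   multi-strain cluster's leaf set only if it occurs in at least `alpha`%
#'   of the member strains. Default 90.
#' @param min_kmers nodes of the cluster search tree with fewer unique k-mers
#'   than this are augmented with additional subtree-unique k-mers. Default
#'   1000.
#' @param derep_threshold complete-linkage Jaccard similarity above which
#'   near-identical references are dereplicated to one representative.
#'   Default 0.99.
#' @param e assumed per-base sequencing error rate used by the binomial
#'   traversal test. Default 0.01.
#' @param beta significance level of the binomial traversal test. Default
#'   0.05.
#' @param frac_floor when the fraction of matched node k-mers falls below
#'   this floor the node's abundance score is forced to 0. Default 0.1.
#' @param F_cutoff minimum weighted matched-k-mer fraction for a cluster hit
#'   to be reported. Default 0.4.
#' @param stop_kmers iterative strain detection stops when fewer than this
#'   many matrix k-mers still have nonzero counts. Default `31 * 40 = 1240`.
#' @param stop_scale_rows for matrices with fewer than this many rows the
#'   stop threshold is scaled proportionally (`stop_kmers / stop_scale_rows`
#'   of the rows) so small matrices terminate sensibly. Default 12400.
#' @param adjust_mode how counts of k-mers shared with another identified
#'   cluster are corrected when computing a hit's path statistics:
#'   `"subtract"` subtracts the other cluster's abundance estimate (floored
#'   at 0), `"exclude"` drops the shared k-mers instead.
#' @param jsd_align how abundance vectors of different composition are
#'   aligned before the Jensen-Shannon divergence: `"id"` matches strains by
#'   name and appends unmatched ones, `"dimension"` pads the shorter vector
#'   with zeros positionally.
#' @param single_strain_cap number of k-mers sampled (evenly over the sorted
#'   set) for the degenerate one-strain-cluster matrix used only for depth
#'   estimation. Default 5000.
#' @param en_alpha_grid elastic-net mixing values scanned by cross-validation.
#' @param nfolds cross-validation folds for the elastic net. Default 5.
#' @param seed integer seed driving every stochastic step (CV folds).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(k = 31L, H = 0.95, alpha = 90, min_kmers = 1000L,
                       derep_threshold = 0.99, e = 0.01, beta = 0.05,
                       frac_floor = 0.1, F_cutoff = 0.4,
                       stop_kmers = 1240L, stop_scale_rows = 12400L,
                       adjust_mode = c("subtract", "exclude"),
                       jsd_align = c("id", "dimension"),
                       single_strain_cap = 5000L,
                       en_alpha_grid = seq(0.1, 1, by = 0.1),
                       nfolds = 5L, seed = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 63L || k %% 2L == 0L)
    stop("'k' must be an odd integer between 1 and 63", call. = FALSE)
  if (!is.numeric(H) || H <= 0 || H > 1)
    stop("'H' must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 100)
    stop("'alpha' must lie in (0, 100]", call. = FALSE)
  if (!is.numeric(e) || e <= 0 || e >= 1)
    stop("'e' must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(beta) || beta <= 0 || beta >= 1)
    stop("'beta' must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(derep_threshold) || derep_threshold <= 0 || derep_threshold > 1)
    stop("'derep_threshold' must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(F_cutoff) || F_cutoff < 0 || F_cutoff > 1)
    stop("'F_cutoff' must lie in [0, 1]", call. = FALSE)
  structure(list(
    k = k, H = H, alpha = alpha, min_kmers = as.integer(min_kmers),
    derep_threshold = derep_threshold, e = e, beta = beta,
    frac_floor = frac_floor, F_cutoff = F_cutoff,
    stop_kmers = as.integer(stop_kmers),
    stop_scale_rows = as.integer(stop_scale_rows),
    adjust_mode = match.arg(adjust_mode),
    jsd_align = match.arg(jsd_align),
    single_strain_cap = as.integer(single_strain_cap),
    en_alpha_grid = en_alpha_grid, nfolds = as.integer(nfolds),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("strainsift run configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm, paste(format(v), collapse = " ")))
  }
  invisible(x)
}
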