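#' Mask counts of k-mers shared with other identified clusters
#'
#' K-mers of the matrix that also occur in any strain of another cluster
#' identified by the tree search get their observed occurrence replaced
#' with 0, removing cross-cluster contamination of the within-cluster
#' deconvolution. Idempotent.
#'
#' @param y numeric vector of k-mer occurrences aligned to `matrix$kmers`.
#' @param matrix a `"strain_matrix"`.
#' @param other_unions list of character vectors: the k-mer unions of the
#'   *other* identified clusters.
#' @return `y` with masked entries set to 0; the masked indices are attached
#'   as attribute `"masked"`.
#' @export
mask_cross_cluster <- function(y, matrix, other_unions = list()) {
  stopifnot(length(y) == length(matrix$kmers))
  masked <- integer(0)
  if (length(other_unions)) {
    shared <- matrix$kmers %in% unique(unlist(other_unions,
                                              use.names = FALSE))
    masked <- which(shared)
    y[masked] <- 0
  }
  prev <- attr(y, "masked")
  attr(y, "masked") <- sort(unique(c(prev, masked)))
  y
}

# zero y entries outside the [5th, 95th] percentile of its positive
# entries (computed once, before iteration); returns y with attribute
# "trimmed" holding the zeroed indices
.trim_outliers <- function(y, lower = 0.05, upper = 0.95) {
  pos <- which(y > 0)
  if (length(pos) < 2L) { attr(y, "trimmed") <- integer(0); return(y) }
  qs <- stats::quantile(y[pos], c(lower, upper), names = FALSE)
  out <- pos[y[pos] < qs[1] | y[pos] > qs[2]]
  y[out] <- 0
  attr(y, "trimmed") <- out
  y
}

#' Iterative strain detection by matrix multiplication
#'
#' Repeatedly scores every not-yet-selected strain by the dot product of its
#' presence column with the observed occurrence vector, selects the top
#' strain and zeroes the occurrences of all its k-mers. Occurrences outside
#' the 5th--95th percentile of the positive entries are zeroed once before
#' iterating. Iteration continues while some strain scores positive and, for
#' iterations after the first, while at least `stop_kmers` k-mers still have
#' nonzero occurrence (scaled to `M * stop_kmers / stop_scale_rows` for
#' matrices with fewer than `stop_scale_rows` rows).
#'
#' @param matrix a `"strain_matrix"`.
#' @param y numeric occurrence vector aligned to `matrix$kmers` (already
#'   masked for other clusters where applicable).
#' @param stop_kmers,stop_scale_rows see [run_config()].
#' @param trim apply the percentile outlier trim (default `TRUE`).
#' @return List with `selected` (strain ids in selection order), `scores`
#'   (score trace per iteration), `y` (the trimmed vector before iterative
#'   zeroing) and `trimmed` (indices zeroed by the outlier trim).
#' @export
iterative_strain_detection <- function(matrix, y, stop_kmers = 1240L,
                                       stop_scale_rows = 12400L,
                                       trim = TRUE) {
  X <- matrix$X
  stopifnot(length(y) == nrow(X))
  if (trim) y <- .trim_outliers(y)
  trimmed <- attr(y, "trimmed")
  y0 <- y
  M <- nrow(X)
  stop_eff <- if (M < stop_scale_rows)
    max(1L, as.integer(floor(M * stop_kmers / stop_scale_rows)))
  else as.integer(stop_kmers)
  selected <- character(0)
  traces <- list()
  ycur <- as.numeric(y)
  repeat {
    remaining <- setdiff(matrix$strain_ids, selected)
    if (!length(remaining)) break
    if (length(selected) > 0L && sum(ycur > 0) < stop_eff) break
    f <- as.numeric(crossprod(X[, remaining, drop = FALSE], ycur))
    names(f) <- remaining
    if (max(f) <= 0) break
    top <- remaining[f == max(f)]
    pick <- min(top)  # deterministic tie-break
    selected <- c(selected, pick)
    traces[[length(traces) + 1L]] <- f
    ycur[X[, pick]] <- 0
  }
  list(selected = selected, scores = traces, y = y0, trimmed = trimmed)
}

#' Non-negative elastic-net depth estimation
#'
#' Estimates per-strain sequencing depths (in expected per-k-mer coverage
#' units) by minimising the elastic-net penalised residual sum of squares
#' `||y - X b||^2 + lambda * (alpha |b|_1 + (1-alpha)/2 |b|_2^2)` subject to
#' `b >= 0`. The mixing parameter and penalty strength are chosen by k-fold
#' cross-validation over a grid (`en_alpha_grid` x a 50-value log-spaced
#' lambda path); folds are drawn deterministically from `seed`. Columns are
#' not standardised (all-binary design) and no intercept is fit.
#'
#' @param X binary design matrix (k-mers x selected strains) with strain
#'   column names.
#' @param y numeric occurrence vector.
#' @param exclude row indices to drop from the fit (entries zeroed by
#'   masking or outlier trimming are artifacts, not observations).
#' @param en_alpha_grid,nfolds,seed see [run_config()].
#' @return Named numeric vector of non-negative depth estimates, with the
#'   chosen `(alpha, lambda)` as attribute `"tuning"`.
#' @export
estimate_depths <- function(X, y, exclude = NULL,
                            en_alpha_grid = seq(0.1, 1, by = 0.1),
                            nfolds = 5L, seed = 1L) {
  stopifnot(is.matrix(X) || inherits(X, "Matrix"))
  X <- as.matrix(X) * 1.0
  if (is.null(colnames(X)))
    colnames(X) <- paste0("strain", seq_len(ncol(X)))
  colkey <- apply(X, 2L, paste, collapse = "")
  if (anyDuplicated(colkey)) {
    dup <- colnames(X)[colkey %in% colkey[duplicated(colkey)]]
    stop("duplicate strain columns in design: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (length(exclude)) {
    X <- X[-exclude, , drop = FALSE]
    y <- y[-exclude]
  }
  n <- nrow(X)
  if (n < ncol(X)) stop("need at least as many k-mers as strains",
                        call. = FALSE)
  if (all(y == 0)) {
    beta <- setNames(rep(0, ncol(X)), colnames(X))
    attr(beta, "tuning") <- c(alpha = NA_real_, lambda = NA_real_)
    return(beta)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nfolds), n))
  if (ncol(X) == 1L) {
    return(.en_single_column(X, y, foldid, en_alpha_grid))
  }
  best <- NULL
  for (a in en_alpha_grid) {
    cv <- glmnet::cv.glmnet(X, y, alpha = a, foldid = foldid,
                            lower.limits = 0, intercept = FALSE,
                            standardize = FALSE, nlambda = 50)
    err <- min(cv$cvm)
    if (is.null(best) || err < best$err)
      best <- list(err = err, cv = cv, alpha = a)
  }
  beta <- as.numeric(stats::coef(best$cv, s = "lambda.min"))[-1]
  beta <- pmax(beta, 0)
  names(beta) <- colnames(X)
  attr(beta, "tuning") <- c(alpha = best$alpha,
                            lambda = best$cv$lambda.min)
  beta
}

# closed-form one-variable non-negative elastic net over the same CV grid
# (the general solver requires >= 2 columns)
.en_single_column <- function(X, y, foldid, alpha_grid) {
  x <- X[, 1L]
  n <- length(y)
  solve1 <- function(x, y, lambda, a) {
    num <- sum(x * y) / length(y) - lambda * a
    den <- sum(x * x) / length(y) + lambda * (1 - a)
    max(0, num / den)
  }
  best <- NULL
  for (a in alpha_grid) {
    lmax <- max(abs(sum(x * y)) / n / a, 1e-8)
    lams <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 50))
    for (lam in lams) {
      # k-fold CV error
      err <- 0
      for (f in sort(unique(foldid))) {
        tr <- foldid != f
        b <- solve1(x[tr], y[tr], lam, a)
        err <- err + sum((y[!tr] - b * x[!tr])^2)
      }
      if (is.null(best) || err < best$err)
        best <- list(err = err, alpha = a, lambda = lam)
    }
  }
  beta <- setNames(solve1(x, y, best$lambda, best$alpha), colnames(X))
  attr(beta, "tuning") <- c(alpha = best$alpha, lambda = best$lambda)
  beta
}

#' Merge per-cluster depth estimates into a relative abundance profile
#'
#' Within each cluster the depth estimates are normalised to within-cluster
#' abundances; across clusters each strain is weighted by its cluster's
#' tree-search abundance estimate `A`, so the final relative abundance of
#' strain i in cluster c is `a_i * A_c / sum_j a_j * A_{c(j)}`. Strains with
#' zero estimated depth are dropped.
#'
#' @param cluster_results list (one element per identified cluster) of lists
#'   with `cluster_id` and `beta` (named depth estimates).
#' @param cluster_A named numeric vector cluster_id -> tree-search
#'   abundance `A_v`.
#' @return A data.frame (class `"strain_profile"`) with columns
#'   `strain_id`, `cluster_id`, `rank`, `depth`, `within_cluster_abundance`,
#'   `relative_abundance`, sorted by decreasing relative abundance.
#' @export
relative_abundance <- function(cluster_results, cluster_A) {
  rows <- list()
  for (res in cluster_results) {
    beta <- res$beta[res$beta > 0]
    if (!length(beta)) next
    a <- beta / sum(beta)
    rows[[length(rows) + 1L]] <- data.frame(
      strain_id = names(beta), cluster_id = res$cluster_id,
      rank = seq_along(beta), depth = unname(beta),
      within_cluster_abundance = unname(a),
      weight = unname(a) * cluster_A[[res$cluster_id]],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("all depth estimates are zero; empty profile", call. = FALSE)
    out <- data.frame(strain_id = character(0), cluster_id = character(0),
                      rank = integer(0), depth = numeric(0),
                      within_cluster_abundance = numeric(0),
                      relative_abundance = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("strain_profile", class(out))
    return(out)
  }
  df <- do.call(rbind, rows)
  df$relative_abundance <- df$weight / sum(df$weight)
  df$weight <- NULL
  df <- df[order(-df$relative_abundance, df$strain_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("strain_profile", class(df))
  df
}

#' @export
print.strain_profile <- function(x, ...) {
  cat(sprintf("strain profile: %d strain(s) in %d cluster(s)\n",
              nrow(x), length(unique(x$cluster_id))))
  if (nrow(x)) print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
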