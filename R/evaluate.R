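#' Precision, recall and F1 of a strain prediction
#'
#' At strain level a prediction is a true positive iff the exact strain is
#' in the truth set. At cluster level a predicted strain counts as a true
#' positive if it belongs to the same cluster as some truth strain (and a
#' truth strain is found if some prediction lands in its cluster).
#'
#' @param truth character vector of true strain ids (non-empty).
#' @param predicted character vector of predicted strain ids.
#' @param level `"strain"` or `"cluster"`.
#' @param cluster_map named character vector strain_id -> cluster_id
#'   (required at cluster level).
#' @return List with `TP`, `FP`, `FN`, `precision`, `recall`, `f1`.
#'   Empty-denominator conventions: a metric whose denominator is 0 is 0.
#' @export
prf <- function(truth, predicted, level = c("strain", "cluster"),
                cluster_map = NULL) {
  level <- match.arg(level)
  truth <- unique(as.character(truth))
  predicted <- unique(as.character(predicted))
  if (!length(truth)) stop("'truth' must be non-empty", call. = FALSE)
  if (level == "cluster") {
    if (is.null(cluster_map))
      stop("'cluster_map' required for cluster-level evaluation",
           call. = FALSE)
    missing <- setdiff(c(truth, predicted), names(cluster_map))
    if (length(missing))
      stop("strains absent from cluster_map: ",
           paste(missing, collapse = ", "), call. = FALSE)
    tc <- unique(unname(cluster_map[truth]))
    pc <- unname(cluster_map[predicted])
    TP <- sum(pc %in% tc)
    FP <- sum(!pc %in% tc)
    FN <- sum(!tc %in% pc)
  } else {
    TP <- length(intersect(truth, predicted))
    FP <- length(setdiff(predicted, truth))
    FN <- length(setdiff(truth, predicted))
  }
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(TP = TP, FP = FP, FN = FN, precision = precision, recall = recall,
       f1 = f1)
}

#' Jensen-Shannon divergence of two abundance profiles
#'
#' Base-2 Jensen-Shannon divergence, which lies in `[0, 1]`:
#' `JSD(T, P) = D(T || K)/2 + D(P || K)/2` with `K = (T + P)/2` and `D` the
#' Kullback-Leibler divergence (`0 log 0 = 0`). Vectors of different
#' composition are aligned before the computation: by strain name (unmatched
#' strains appended with zero mass) when both are named and `align = "id"`,
#' otherwise by zero-padding the shorter vector positionally.
#'
#' @param T,P non-negative vectors summing to 1 (tolerance 1e-9), optionally
#'   named by strain.
#' @param align `"id"` or `"dimension"`.
#' @return Divergence in `[0, 1]`.
#' @export
jsd <- function(T, P, align = c("id", "dimension")) {
  align <- match.arg(align)
  if (any(T < 0) || any(P < 0))
    stop("abundance vectors must be non-negative", call. = FALSE)
  if (abs(sum(T) - 1) > 1e-9 || abs(sum(P) - 1) > 1e-9)
    stop("abundance vectors must sum to 1", call. = FALSE)
  if (align == "id" && !is.null(names(T)) && !is.null(names(P))) {
    ids <- union(names(T), names(P))
    T <- setNames(T[match(ids, names(T))], ids)
    P <- setNames(P[match(ids, names(P))], ids)
    T[is.na(T)] <- 0
    P[is.na(P)] <- 0
  } else {
    n <- max(length(T), length(P))
    T <- c(unname(T), rep(0, n - length(T)))
    P <- c(unname(P), rep(0, n - length(P)))
  }
  K <- (T + P) / 2
  kl <- function(A) {
    i <- A > 0
    sum(A[i] * log2(A[i] / K[i]))
  }
  (kl(T) + kl(P)) / 2
}
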