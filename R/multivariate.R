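#' Wide sample-by-element matrix for multivariate analysis
#'
#' Builds the matrix entering the dissimilarity-based analyses. Because C, N
#' and S are measured on small per-inflorescence subsamples while the other
#' nine elements are measured on pooled subsamples, a full 12-element row
#' does not exist for any single subsample. The default (\code{"merged"})
#' takes the pooled subsamples as rows and attaches each array's mean C, N
#' and S to them; \code{"pooled9"} keeps only the nine pooled elements;
#' \code{"cns"} uses the C/N/S subsamples with three columns.
#'
#' @param t A \code{\link{composition_table}}.
#' @param element_set \code{"merged"}, \code{"pooled9"} or \code{"cns"}.
#' @return A numeric matrix (rows = subsamples, columns = elements, mg/kg)
#'   with a \code{"meta"} attribute data.frame (treatment, array_id,
#'   subsample_id).
#' @export
composition_matrix <- function(t, element_set = c("merged", "pooled9",
                                                  "cns")) {
  element_set <- match.arg(element_set)
  t <- to_common_units(t, "mg_per_kg")
  cns <- c("C", "N", "S")
  pooled <- setdiff(supported_elements(), cns)
  present <- unique(t$element)

  base_elements <- switch(element_set,
    merged = intersect(supported_elements(), present),
    pooled9 = intersect(pooled, present),
    cns = intersect(cns, present))
  row_elements <- switch(element_set,
    merged = intersect(pooled, present),
    pooled9 = intersect(pooled, present),
    cns = intersect(cns, present))
  if (length(row_elements) == 0L) {
    stop("no elements available for element_set = '", element_set, "'")
  }

  rows <- t[t$element %in% row_elements, , drop = FALSE]
  key <- unique(rows[c("treatment", "array_id", "subsample_id")])
  key <- key[order(key$treatment, key$array_id, key$subsample_id), ]
  m <- matrix(NA_real_, nrow = nrow(key), ncol = length(base_elements),
              dimnames = list(paste(key$array_id, key$subsample_id,
                                    sep = ":"),
                              base_elements))
  idx_row <- match(paste(rows$array_id, rows$subsample_id),
                   paste(key$array_id, key$subsample_id))
  m[cbind(idx_row, match(rows$element, base_elements))] <- rows$concentration

  if (element_set == "merged") {
    cns_rows <- t[t$element %in% intersect(cns, base_elements), ,
                  drop = FALSE]
    if (nrow(cns_rows) > 0L) {
      mean_by <- stats::aggregate(concentration ~ array_id + element,
                                  data = cns_rows, FUN = mean)
      for (j in intersect(cns, base_elements)) {
        mj <- mean_by[mean_by$element == j, ]
        m[, j] <- mj$concentration[match(key$array_id, mj$array_id)]
      }
    }
  }
  if (anyNA(m)) {
    stop("incomplete element measurements: matrix has missing cells for ",
         paste(colnames(m)[colSums(is.na(m)) > 0], collapse = ", "))
  }
  attr(m, "meta") <- key
  m
}

#' Normalise element profiles
#'
#' Elements are measured on very different scales (percent dry mass vs
#' mg/kg), so profiles are rescaled per element before computing
#' dissimilarities. The default min-max scaling maps each element to [0, 1],
#' which keeps Bray-Curtis well defined; z-scoring is offered for use with
#' Euclidean distances but produces negatives incompatible with
#' Bray-Curtis.
#'
#' @param m Numeric matrix, rows = samples, columns = elements.
#' @param method \code{"minmax"} (default) or \code{"zscore"}.
#' @return The rescaled matrix (attributes preserved).
#' @export
normalize_profiles <- function(m, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  if (nrow(m) < 2L) stop("need at least 2 samples to normalise")
  rng <- apply(m, 2L, function(x) diff(range(x)))
  constant <- colnames(m)[rng == 0]
  if (length(constant) > 0L) {
    stop("constant element column(s) cannot be normalised: ",
         paste(constant, collapse = ", "))
  }
  out <- if (method == "minmax") {
    apply(m, 2L, function(x) (x - min(x)) / diff(range(x)))
  } else {
    scale(m)[, , drop = FALSE]
  }
  out <- matrix(out, nrow = nrow(m), dimnames = dimnames(m))
  attr(out, "meta") <- attr(m, "meta")
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' \code{d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)} over elements; bounded
#' in [0, 1] for non-negative profiles. Note Bray-Curtis is a
#' semimetric: the triangle inequality is not guaranteed.
#'
#' @param m Non-negative numeric matrix, rows = samples.
#' @return A symmetric n x n matrix with zero diagonal and the input's row
#'   names.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) {
    stop("Bray-Curtis requires non-negative profiles; ",
         "use min-max normalisation rather than z-scores")
  }
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("all-zero row(s): ",
         paste(which(totals == 0), collapse = ", "))
  }
  manhattan <- as.matrix(stats::dist(m, method = "manhattan"))
  denom <- outer(totals, totals, "+")
  d <- manhattan / denom
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the sum of squared dissimilarities between and within groups
#' and tests the pseudo-F statistic by permuting the group labels freely
#' across samples. The p-value includes the observed statistic in numerator
#' and denominator: \code{p = (1 + #[F_perm >= F_obs]) / (n_perm + 1)}.
#' For tiny samples \code{method = "exact"} enumerates every label
#' permutation, and \code{p} is the exact proportion of permutations
#' (including the identity) reaching the observed F.
#'
#' Free permutation is exact only when samples are exchangeable under the
#' null. Subsamples nested in arrays are not exchangeable when array
#' variance is present; interpret subsample-level tests accordingly.
#'
#' @param d Distance matrix (matrix or \code{dist}).
#' @param labels Group labels, one per sample; at least two groups.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Optional RNG seed for the permutations.
#' @param method \code{"sampled"} (default) or \code{"exact"} (all
#'   permutations; only for small n).
#' @return An object of class \code{permanova_result}: \code{r2},
#'   \code{pseudo_f}, \code{df_model}, \code{df_residual}, \code{p},
#'   \code{n_permutations}, \code{seed}, \code{ss} (total/between/within).
#' @export
permanova <- function(d, labels, n_perm = 999, seed = NULL,
                      method = c("sampled", "exact")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- as.factor(labels)
  if (length(labels) != n) stop("labels must match the distance matrix")
  a <- nlevels(droplevels(labels))
  if (a < 2L) stop("need at least two groups")
  if (any(table(labels) < 1L)) stop("each group needs at least one sample")
  if (method == "sampled" && n_perm < 1L) stop("n_perm must be >= 1")

  D2 <- d^2
  ss_total <- sum(D2[lower.tri(D2)]) / n
  ss_within_for <- function(lab) {
    s <- 0
    for (lv in levels(lab)) {
      idx <- which(lab == lv)
      if (length(idx) > 1L) {
        s <- s + sum(D2[idx, idx]) / (2 * length(idx))
      }
    }
    s
  }
  f_for <- function(lab) {
    ssw <- ss_within_for(lab)
    ssb <- ss_total - ssw
    if (ssw <= 0) return(Inf)
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  ss_within <- ss_within_for(labels)
  ss_between <- ss_total - ss_within
  f_obs <- f_for(labels)
  eps <- 1e-12 * max(1, abs(f_obs))

  if (method == "exact") {
    perms <- all_permutations(n)
    f_perm <- vapply(perms, function(idx) f_for(labels[idx]), numeric(1L))
    p <- mean(f_perm >= f_obs - eps)
    n_perm <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    f_perm <- vapply(seq_len(n_perm), function(i) {
      f_for(sample(labels))
    }, numeric(1L))
    p <- (1 + sum(f_perm >= f_obs - eps)) / (n_perm + 1)
  }

  structure(list(
    r2 = ss_between / ss_total,
    pseudo_f = f_obs,
    df_model = a - 1L,
    df_residual = n - a,
    p = p,
    n_permutations = n_perm,
    seed = seed,
    method = method,
    ss = c(total = ss_total, between = ss_between, within = ss_within)
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: R2 = %.3f, pseudo-F_%d,%d = %.3f, p = %.4g (%s, %d perms)\n",
    x$r2, x$df_model, x$df_residual, x$pseudo_f, x$p, x$method,
    x$n_permutations))
  invisible(x)
}

# All permutations of 1..n (n small), as a list of index vectors.
all_permutations <- function(n) {
  if (n > 9L) stop("exact enumeration limited to n <= 9")
  if (n == 1L) return(list(1L))
  smaller <- all_permutations(n - 1L)
  out <- vector("list", n * length(smaller))
  k <- 1L
  for (p in smaller) {
    for (pos in 0:(n - 1L)) {
      out[[k]] <- append(p, n, after = pos)
      k <- k + 1L
    }
  }
  out
}
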