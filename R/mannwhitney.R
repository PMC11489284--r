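#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The statistic is the
#' number of pairs with \code{x > y}, counting ties as one half. For small
#' untied samples (\code{min(n) <= 8}) the null distribution is enumerated
#' exactly over all assignments of the pooled values; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param x,y Numeric samples, each with at least one observation.
#' @param alternative Only \code{"two_sided"} is offered.
#' @return A list with \code{u}, \code{p}, \code{method}
#'   (\code{"exact"} or \code{"normal"}), \code{n_x}, \code{n_y}.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(x, y, alternative = "two_sided") {
  alternative <- match.arg(alternative, "two_sided")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must contain at least one observation")
  }
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  n_x <- length(x); n_y <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n_x)]) - n_x * (n_x + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L

  if (!has_ties && min(n_x, n_y) <= 8L) {
    counts <- mw_exact_counts(n_x + n_y, n_x)
    total <- sum(counts)
    # counts[k] is the number of rank assignments with U = k - 1
    p_le <- sum(counts[seq_len(round(u) + 1L)]) / total
    p_ge <- sum(counts[(round(u) + 1L):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    n <- n_x + n_y
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n_x * n_y / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - n_x * n_y / 2
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(u = u, p = p, method = method, n_x = n_x, n_y = n_y)
}

# Exact null distribution of U for untied samples: counts over all
# choose(n, n_x) assignments of the pooled ranks, built by the standard
# rank-sum counting recursion (equivalent to full enumeration).
mw_exact_counts <- function(n, n_x) {
  max_sum <- sum((n - n_x + 1):n)
  # dp[j + 1, s + 1] = number of j-subsets of the ranks seen so far with
  # rank sum s
  dp <- matrix(0, n_x + 1L, max_sum + 1L)
  dp[1L, 1L] <- 1
  for (r in seq_len(n)) {
    jmax <- min(r, n_x)
    for (j in jmax:1L) {
      cols <- (r + 1L):(max_sum + 1L)
      dp[j + 1L, cols] <- dp[j + 1L, cols] + dp[j, cols - r]
    }
  }
  sums <- dp[n_x + 1L, ]
  offset <- n_x * (n_x + 1L) / 2   # U = ranksum - offset
  sums[(offset + 1L):(max_sum + 1L)]
}

#' Treatment comparison of TSR distributions
#'
#' Per species and element, compares the ambient- and elevated-CO2 TSR
#' distributions with the Mann-Whitney test. Two variants are reported: the
#' subsample-style test on the full cross-product records (as many values as
#' arrays x consumer replicates per group, which treats the cross product as
#' independent observations) and a conservative array-level variant on the
#' per-array mean TSRs (n = number of arrays per group).
#'
#' @param records TSR records from \code{\link{compute_tsr}} containing both
#'   treatments.
#' @param tiers Named numeric vector of significance thresholds mapping
#'   label to upper p bound (defaults \code{***} 0.001, \code{**} 0.01,
#'   \code{*} 0.05).
#' @return A data.frame per species x element with \code{u}, \code{p},
#'   \code{tier} (cross-product test) and \code{u_array}, \code{p_array}
#'   (array-level test), plus group sizes.
#' @export
compare_treatments <- function(records,
                               tiers = c(`***` = 0.001, `**` = 0.01,
                                         `*` = 0.05)) {
  if (!all(c("aCO2", "eCO2") %in% unique(records$treatment))) {
    stop("both treatments (aCO2, eCO2) must be present in the TSR records")
  }
  tiers <- sort(tiers)
  grp <- interaction(records$species, records$element, drop = TRUE,
                     sep = "\r")
  pieces <- lapply(split(records, grp), function(g) {
    a <- g$tsr[g$treatment == "aCO2"]
    e <- g$tsr[g$treatment == "eCO2"]
    if (length(a) == 0L || length(e) == 0L) {
      stop("treatment missing for ", g$species[1L], " / ", g$element[1L])
    }
    mw <- mann_whitney(a, e)
    by_array <- stats::aggregate(
      tsr ~ treatment + food_array_id, data = g, FUN = mean)
    mwa <- mann_whitney(by_array$tsr[by_array$treatment == "aCO2"],
                        by_array$tsr[by_array$treatment == "eCO2"])
    data.frame(species = g$species[1L], element = g$element[1L],
               n_aCO2 = length(a), n_eCO2 = length(e),
               u = mw$u, p = mw$p, tier = p_tier(mw$p, tiers),
               u_array = mwa$u, p_array = mwa$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$species, out$element), ]
  rownames(out) <- NULL
  out
}

p_tier <- function(p, tiers) {
  vapply(p, function(pi) {
    hit <- which(pi < tiers)
    if (length(hit) == 0L) "ns" else names(tiers)[hit[1L]]
  }, character(1L))
}
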