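#' Non-metric multidimensional scaling
#'
#' Embeds samples in \code{k} dimensions so that configuration distances
#' preserve the rank order of the input dissimilarities. Each restart
#' alternates isotonic (monotone) regression of configuration distances on
#' the dissimilarity ranks with a Guttman-transform update of the
#' configuration, minimising Kruskal stress-1
#' \code{sqrt(sum((d - dhat)^2) / sum(d^2))}. The first start is the metric
#' (principal-coordinates) configuration, the remaining starts are random;
#' the best (lowest-stress) converged solution is returned, so reported
#' stress is non-increasing in the number of restarts.
#'
#' @param d Dissimilarity matrix (matrix or \code{dist}).
#' @param k Number of dimensions (default 2).
#' @param restarts Number of starts including the metric start (default 20).
#' @param max_iter Maximum iterations per start (default 300).
#' @param tol Stress-change convergence tolerance (default 1e-6).
#' @param seed Optional RNG seed for the random starts.
#' @return An object of class \code{nmds_result}: \code{points} (n x k,
#'   centred, principal-axis rotated), \code{stress}, \code{k},
#'   \code{restarts}, \code{converged} (any restart converged),
#'   \code{best_restart}, \code{seed}.
#' @export
nmds <- function(d, k = 2L, restarts = 20L, max_iter = 300L, tol = 1e-6,
                 seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 samples")
  if (!is.null(seed)) set.seed(seed)

  if (n == 2L) {
    pts <- matrix(0, 2L, k, dimnames = list(rownames(d), NULL))
    pts[2L, 1L] <- d[1L, 2L]
    pts <- scale(pts, scale = FALSE)
    return(structure(list(points = pts, stress = 0, k = k,
                          restarts = restarts, converged = TRUE,
                          best_restart = 1L, seed = seed),
                     class = "nmds_result"))
  }

  dv <- d[lower.tri(d)]
  best <- list(stress = Inf, points = NULL, converged = FALSE,
               restart = NA_integer_)
  for (r in seq_len(restarts)) {
    x0 <- if (r == 1L) {
      mds <- stats::cmdscale(stats::as.dist(d), k = k)
      if (ncol(mds) < k) {
        mds <- cbind(mds, matrix(0, n, k - ncol(mds)))
      }
      mds
    } else {
      matrix(stats::runif(n * k, -0.5, 0.5), n, k)
    }
    run <- nmds_one_start(dv, x0, n, k, max_iter, tol)
    if (run$stress < best$stress) {
      best <- list(stress = run$stress, points = run$points,
                   converged = run$converged, restart = r)
    }
  }

  pts <- scale(best$points, scale = FALSE)
  if (k > 1L && nrow(pts) > k) {
    sv <- svd(pts)
    pts <- sv$u %*% diag(sv$d, k, k)
  }
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = pts, stress = best$stress, k = k,
                 restarts = restarts, converged = best$converged,
                 best_restart = best$restart, seed = seed),
            class = "nmds_result")
}

nmds_one_start <- function(dv, x, n, k, max_iter, tol) {
  stress_prev <- Inf
  converged <- FALSE
  stress <- Inf
  for (iter in seq_len(max_iter)) {
    cd <- as.vector(stats::dist(x))
    # monotone regression: disparities nondecreasing in the dissimilarity
    # order (ties broken by configuration distance - Kruskal's primary
    # approach)
    ord <- order(dv, cd)
    dhat <- numeric(length(dv))
    dhat[ord] <- stats::isoreg(cd[ord])$yf
    denom <- sum(cd^2)
    if (denom == 0) {
      stress <- 1
      break
    }
    stress <- sqrt(sum((cd - dhat)^2) / denom)
    if (is.finite(stress_prev) && abs(stress_prev - stress) < tol) {
      converged <- TRUE
      break
    }
    stress_prev <- stress
    # Guttman transform with the disparities as target distances
    ratio <- ifelse(cd > 0, dhat / cd, 0)
    B <- matrix(0, n, n)
    B[lower.tri(B)] <- -ratio
    B <- B + t(B)
    diag(B) <- -rowSums(B)
    x <- B %*% x / n
  }
  list(points = x, stress = stress, converged = converged)
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf(
    "NMDS (k = %d): stress = %.4f, %d restarts (best #%d)%s\n",
    x$k, x$stress, x$restarts, x$best_restart,
    if (x$converged) "" else " [no restart converged]"))
  invisible(x)
}

#' Fit environmental variables onto an ordination
#'
#' For each variable, regresses the (centred) variable on the ordination
#' axes by least squares; the fitted arrow is the unit direction of the
#' coefficient vector scaled by \code{sqrt(r2)}. Significance is assessed
#' by permuting the variable across samples and recomputing r2.
#'
#' @param ord An \code{nmds_result} (or any list with a \code{points}
#'   matrix).
#' @param variables A data.frame of per-sample variables; numeric columns
#'   are fitted directly, two-level factors/characters as 0/1 indicators.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional RNG seed.
#' @return A data.frame with one row per fitted variable: arrow coordinates
#'   (one column per axis), \code{r2} and \code{p}. Zero-variance variables
#'   are skipped with a warning.
#' @export
fit_environment <- function(ord, variables, n_perm = 999, seed = NULL) {
  x <- ord$points
  if (nrow(variables) != nrow(x)) {
    stop("variables must have one row per ordination sample")
  }
  if (!is.null(seed)) set.seed(seed)
  xc <- scale(x, scale = FALSE)
  rows <- list()
  for (nm in names(variables)) {
    v <- variables[[nm]]
    if (is.character(v)) v <- factor(v)
    if (is.factor(v)) {
      if (nlevels(droplevels(v)) != 2L) {
        stop("factor variable '", nm, "' must have exactly 2 levels")
      }
      v <- as.numeric(droplevels(v)) - 1
    }
    if (stats::var(v) == 0) {
      warning("skipping zero-variance variable '", nm, "'")
      next
    }
    r2_of <- function(vv) {
      fit <- stats::lm.fit(cbind(1, xc), vv)
      1 - sum(fit$residuals^2) / sum((vv - mean(vv))^2)
    }
    r2 <- r2_of(v)
    coefs <- stats::lm.fit(cbind(1, xc), v)$coefficients[-1L]
    len <- sqrt(sum(coefs^2))
    arrow <- if (len > 0) coefs / len * sqrt(max(r2, 0)) else coefs * 0
    r2_perm <- vapply(seq_len(n_perm), function(i) r2_of(sample(v)),
                      numeric(1L))
    p <- (1 + sum(r2_perm >= r2 - 1e-12)) / (n_perm + 1)
    row <- as.data.frame(as.list(arrow))
    names(row) <- colnames(x)
    row$variable <- nm
    row$r2 <- r2
    row$p <- p
    rows[[nm]] <- row
  }
  if (length(rows) == 0L) stop("no fittable variables")
  out <- do.call(rbind, rows)
  out <- out[c("variable", colnames(x), "r2", "p")]
  rownames(out) <- NULL
  out
}
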