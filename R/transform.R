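#' Transformation specification
#'
#' Describes the normalising transform applied to a response before mixed
#' modelling: identity, natural log, or Box-Cox
#' (\code{((x + shift)^lambda - 1) / lambda}, with \code{lambda = 0} equal
#' to the log). Transforms are invertible on positive data.
#'
#' @param kind \code{"identity"}, \code{"log"} or \code{"box_cox"}.
#' @param lambda Box-Cox exponent (required for \code{"box_cox"}).
#' @param shift Offset added before transforming (default 0); required when
#'   the data contain non-positive values.
#' @return An object of class \code{transform_spec}.
#' @export
transform_spec <- function(kind = c("identity", "log", "box_cox"),
                           lambda = NULL, shift = 0) {
  kind <- match.arg(kind)
  if (kind == "box_cox") {
    if (is.null(lambda) || !is.finite(lambda)) {
      stop("box_cox requires a finite lambda")
    }
  } else {
    lambda <- NULL
  }
  structure(list(kind = kind, lambda = lambda, shift = shift),
            class = "transform_spec")
}

#' Apply a transformation
#'
#' @param spec A \code{\link{transform_spec}}.
#' @param x Numeric vector.
#' @return Transformed values.
#' @export
apply_transform <- function(spec, x) {
  x <- x + spec$shift
  switch(spec$kind,
    identity = x,
    log = {
      if (any(x <= 0)) {
        stop("log transform requires positive values (set a shift)")
      }
      log(x)
    },
    box_cox = {
      if (any(x <= 0)) {
        stop("Box-Cox transform requires positive values (set a shift)")
      }
      if (abs(spec$lambda) < 1e-12) log(x) else
        (x^spec$lambda - 1) / spec$lambda
    })
}

#' @export
print.transform_spec <- function(x, ...) {
  cat(switch(x$kind,
    identity = "transform: identity",
    log = "transform: log",
    box_cox = sprintf("transform: Box-Cox (lambda = %.2f)", x$lambda)))
  if (x$shift != 0) cat(sprintf(" [shift %g]", x$shift))
  cat("\n")
  invisible(x)
}

#' Profile-likelihood Box-Cox exponent
#'
#' Maximises the Box-Cox profile log-likelihood over a grid of lambda in
#' [-2, 2] (step 0.01). Likelihood ties are broken toward lambda = 1.
#'
#' @param x Positive numeric sample.
#' @param grid Candidate lambda values.
#' @return The selected lambda.
#' @export
box_cox_lambda <- function(x, grid = seq(-2, 2, by = 0.01)) {
  if (any(x <= 0)) stop("Box-Cox requires positive values")
  n <- length(x)
  slog <- sum(log(x))
  ll <- vapply(grid, function(lam) {
    y <- apply_transform(transform_spec("box_cox", lambda = lam), x)
    s2 <- sum((y - mean(y))^2) / n
    if (s2 <= 0) return(-Inf)
    -n / 2 * log(s2) + (lam - 1) * slog
  }, numeric(1L))
  top <- which(ll >= max(ll) - 1e-9)
  grid[top[which.min(abs(grid[top] - 1))]]
}

#' Select a normalising transform
#'
#' Compares the identity, log and profile-optimised Box-Cox transforms on a
#' sample and returns the one whose transformed values have the highest
#' Shapiro-Wilk W. Log and Box-Cox are only considered for strictly
#' positive data. Intended as a simple automatic selector; responses can be
#' pinned to a fixed transform instead via configuration.
#'
#' @param values Numeric sample, n >= 5.
#' @return A \code{\link{transform_spec}} with the achieved W in the
#'   \code{"shapiro_w"} attribute.
#' @export
select_transform <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5L) stop("need at least 5 observations")
  if (stats::var(values) == 0) {
    spec <- transform_spec("identity")
    attr(spec, "shapiro_w") <- NA_real_
    return(spec)
  }
  candidates <- list(transform_spec("identity"))
  if (all(values > 0)) {
    candidates <- c(candidates, list(
      transform_spec("log"),
      transform_spec("box_cox", lambda = box_cox_lambda(values))))
  }
  w <- vapply(candidates, function(spec) {
    y <- apply_transform(spec, values)
    if (stats::var(y) == 0) return(-Inf)
    stats::shapiro.test(y)$statistic
  }, numeric(1L))
  best <- candidates[[which.max(w)]]
  attr(best, "shapiro_w") <- max(w)
  best
}
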