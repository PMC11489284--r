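#' Linear mixed model for one response against CO2 treatment
#'
#' Fits (by REML) \code{response ~ treatment + (1 | array_id)}: a fixed CO2
#' effect with a random intercept per array, the array being the true
#' replicate. Subsamples are the observation unit, so a further
#' subsample-level intercept would be confounded with the residual and a
#' single array-level random intercept is used. Wald t tests use
#' between-within degrees of freedom: \code{n_arrays - 2} for the treatment
#' effect (4 in the canonical 2 x 3-array design) and
#' \code{n_obs - n_arrays} for the intercept.
#'
#' @param data A data.frame with columns \code{treatment} (aCO2/eCO2),
#'   \code{array_id}, and the response column.
#' @param response Name of the response column.
#' @param transform A \code{\link{transform_spec}} applied to the response
#'   before fitting (default identity). Estimates are reported on the
#'   transformed scale; back-transformed group means are attached as a
#'   convenience.
#' @return An object of class \code{mixed_model_fit}: \code{coefficients}
#'   (term, estimate, se, df, t, p), variance components
#'   (\code{sigma2_array}, \code{sigma2_resid}, \code{sigma2_fixed}),
#'   \code{r2_marginal}, \code{r2_conditional}, \code{diagnostics},
#'   \code{singular}/\code{degenerate} flags and back-transformed group
#'   means.
#' @export
fit_lmm <- function(data, response,
                    transform = transform_spec("identity")) {
  required <- c("treatment", "array_id", response)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("data is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- data[stats::complete.cases(data[required]), , drop = FALSE]
  data$treatment <- factor(data$treatment, levels = c("aCO2", "eCO2"))
  arrays_per_trt <- tapply(data$array_id, data$treatment,
                           function(x) length(unique(x)))
  if (any(is.na(arrays_per_trt)) || any(arrays_per_trt < 2L)) {
    stop("need at least 2 arrays per treatment to separate the CO2 effect ",
         "from array-to-array variation")
  }
  n_obs <- nrow(data)
  n_arrays <- length(unique(data$array_id))
  y <- apply_transform(transform, data[[response]])
  df_trt <- n_arrays - 2L
  df_int <- n_obs - n_arrays

  if (stats::var(y) == 0) {
    coefs <- data.frame(
      term = c("(Intercept)", "CO2"),
      estimate = c(y[1L], 0), se = c(0, 0), df = c(df_int, df_trt),
      t = c(NA_real_, NA_real_), p = c(NA_real_, NA_real_),
      stringsAsFactors = FALSE)
    return(structure(list(
      response = response, transform = transform, coefficients = coefs,
      sigma2_array = 0, sigma2_resid = 0, sigma2_fixed = 0,
      r2_marginal = NA_real_, r2_conditional = NA_real_,
      diagnostics = list(shapiro_w = NA_real_, shapiro_p = NA_real_,
                         levene_f = NA_real_, levene_p = NA_real_),
      singular = TRUE, degenerate = TRUE,
      n_obs = n_obs, n_arrays = n_arrays,
      group_means = tapply(data[[response]], data$treatment, mean)
    ), class = "mixed_model_fit"))
  }

  fdat <- data.frame(y = y, treatment = data$treatment,
                     array_id = factor(data$array_id))
  fit <- suppressMessages(
    lme4::lmer(y ~ treatment + (1 | array_id), data = fdat, REML = TRUE))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tval <- fe / se
  dfs <- c(df_int, df_trt)
  pval <- 2 * stats::pt(-abs(tval), dfs)
  coefs <- data.frame(
    term = c("(Intercept)", "CO2"),
    estimate = unname(fe), se = unname(se), df = dfs,
    t = unname(tval), p = unname(pval), stringsAsFactors = FALSE)

  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_array <- vc$vcov[vc$grp == "array_id"]
  sigma2_resid <- vc$vcov[vc$grp == "Residual"]
  fitted_fixed <- stats::model.matrix(fit) %*% fe
  sigma2_fixed <- sum((fitted_fixed - mean(fitted_fixed))^2) / n_obs

  res <- stats::residuals(fit) / stats::sigma(fit)
  shapiro <- if (n_obs >= 3L && n_obs <= 5000L && stats::var(res) > 0) {
    st <- stats::shapiro.test(res)
    c(unname(st$statistic), st$p.value)
  } else c(NA_real_, NA_real_)
  levene <- levene_by_treatment(res, fdat$treatment)

  r2 <- r2_components(sigma2_fixed, sigma2_array, sigma2_resid)
  structure(list(
    response = response, transform = transform, coefficients = coefs,
    sigma2_array = sigma2_array, sigma2_resid = sigma2_resid,
    sigma2_fixed = sigma2_fixed,
    r2_marginal = r2[1L], r2_conditional = r2[2L],
    diagnostics = list(shapiro_w = shapiro[1L], shapiro_p = shapiro[2L],
                       levene_f = levene[1L], levene_p = levene[2L]),
    singular = lme4::isSingular(fit), degenerate = FALSE,
    n_obs = n_obs, n_arrays = n_arrays,
    group_means = tapply(data[[response]], data$treatment, mean)
  ), class = "mixed_model_fit")
}

# Brown-Forsythe style spread comparison of residuals across treatments.
levene_by_treatment <- function(res, treatment) {
  med <- tapply(res, treatment, stats::median)
  z <- abs(res - med[treatment])
  if (stats::var(z) == 0) return(c(NA_real_, NA_real_))
  an <- stats::anova(stats::lm(z ~ treatment))
  c(an$`F value`[1L], an$`Pr(>F)`[1L])
}

r2_components <- function(sigma2_fixed, sigma2_random, sigma2_resid) {
  total <- sigma2_fixed + sigma2_random + sigma2_resid
  if (total <= 0) stop("all variance components are zero; R2 undefined")
  c(sigma2_fixed / total, (sigma2_fixed + sigma2_random) / total)
}

#' Marginal and conditional R2 for a mixed model
#'
#' Variance explained by the fixed effects alone (marginal) and by fixed
#' plus random effects (conditional):
#' \code{R2m = s2_f / (s2_f + s2_r + s2_e)},
#' \code{R2c = (s2_f + s2_r) / (s2_f + s2_r + s2_e)}, where \code{s2_f} is
#' the variance of the fitted fixed-effect values.
#'
#' @param fit A \code{\link{fit_lmm}} result, or \code{NULL} when supplying
#'   the components directly.
#' @param sigma2_fixed,sigma2_random,sigma2_resid Variance components
#'   (ignored when \code{fit} is given).
#' @return Named numeric vector \code{c(r2_marginal, r2_conditional)}.
#' @examples
#' r2_nakagawa(sigma2_fixed = 1, sigma2_random = 1, sigma2_resid = 2)
#' @export
r2_nakagawa <- function(fit = NULL, sigma2_fixed = NULL,
                        sigma2_random = NULL, sigma2_resid = NULL) {
  if (!is.null(fit)) {
    sigma2_fixed <- fit$sigma2_fixed
    sigma2_random <- fit$sigma2_array
    sigma2_resid <- fit$sigma2_resid
  }
  out <- r2_components(sigma2_fixed, sigma2_random, sigma2_resid)
  names(out) <- c("r2_marginal", "r2_conditional")
  out
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("LMM fit: %s (%s)%s\n", x$response, x$transform$kind,
              if (x$singular) " [singular]" else ""))
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("  sigma2 array %.4g, residual %.4g; R2m %.3f, R2c %.3f\n",
              x$sigma2_array, x$sigma2_resid, x$r2_marginal,
              x$r2_conditional))
  invisible(x)
}

default_transforms <- function() {
  list(C = "box_cox", N = "box_cox", `C:N` = "box_cox", Mn = "log")
}

resolve_transform <- function(name, values, transforms) {
  kind <- transforms[[name]]
  if (is.null(kind)) return(transform_spec("identity"))
  if (inherits(kind, "transform_spec")) return(kind)
  if (kind == "box_cox") {
    transform_spec("box_cox", lambda = box_cox_lambda(values))
  } else {
    transform_spec(kind)
  }
}

#' Fit the full set of per-response mixed models
#'
#' Fits one LMM per element concentration (12 responses) and per ratio
#' (C:N, C:P, N:P), mirroring the study's univariate analysis. By default
#' C, N and C:N are Box-Cox transformed (profile-optimised lambda) and Mn
#' is log transformed; other responses are untransformed. Any response can
#' be re-pinned through \code{transforms}, or set
#' \code{transforms = "auto"} to pick each transform by Shapiro-Wilk W.
#'
#' @param comp A \code{\link{composition_table}}.
#' @param transforms Named list mapping response name to \code{"identity"},
#'   \code{"log"}, \code{"box_cox"} or a \code{\link{transform_spec}};
#'   or the string \code{"auto"}.
#' @return Named list of \code{mixed_model_fit} objects.
#' @export
fit_study_lmms <- function(comp, transforms = default_transforms()) {
  auto <- identical(transforms, "auto")
  fits <- list()
  for (el in intersect(supported_elements(), unique(comp$element))) {
    sub <- comp[comp$element == el, , drop = FALSE]
    dat <- data.frame(treatment = sub$treatment, array_id = sub$array_id,
                      value = sub$concentration)
    spec <- if (auto) select_transform(dat$value) else
      resolve_transform(el, dat$value, transforms)
    fits[[el]] <- fit_lmm(dat, "value", transform = spec)
    fits[[el]]$response <- el
  }
  ratio_defs <- list(`C:N` = c("C", "N"), `C:P` = c("C", "P"),
                     `N:P` = c("N", "P"))
  present <- unique(comp$element)
  for (nm in names(ratio_defs)) {
    pair <- ratio_defs[[nm]]
    if (!all(pair %in% present)) next
    r <- compute_element_ratio(comp, pair[1L], pair[2L])
    dat <- data.frame(treatment = r$treatment, array_id = r$array_id,
                      value = r$value)
    spec <- if (auto) select_transform(dat$value) else
      resolve_transform(nm, dat$value, transforms)
    fits[[nm]] <- fit_lmm(dat, "value", transform = spec)
    fits[[nm]]$response <- nm
  }
  fits
}

#' Assemble the coefficient summary table
#'
#' Stacks the intercept and CO2-effect rows of each mixed model fit into
#' one report table (two rows per response) with the transform used,
#' variance-explained summaries and fit flags. Expected responses that are
#' missing from \code{fits} are listed in the \code{"missing"} attribute
#' rather than raising an error. Reported p-values are raw (no multiple
#' testing correction is applied).
#'
#' @param fits Named list of \code{\link{fit_lmm}} results.
#' @param expected Character vector of expected response names (default:
#'   the 12 elements plus C:N, C:P, N:P).
#' @return A data.frame with columns \code{response}, \code{term},
#'   \code{estimate}, \code{se}, \code{df}, \code{t}, \code{p},
#'   \code{r2_marginal}, \code{r2_conditional}, \code{transform},
#'   \code{singular}.
#' @export
build_table1 <- function(fits,
                         expected = c(supported_elements(),
                                      "C:N", "C:P", "N:P")) {
  rows <- lapply(fits, function(f) {
    co <- f$coefficients
    co$response <- f$response
    co$r2_marginal <- f$r2_marginal
    co$r2_conditional <- f$r2_conditional
    co$transform <- if (f$transform$kind == "box_cox") {
      sprintf("box_cox(%.2f)", f$transform$lambda)
    } else f$transform$kind
    co$singular <- f$singular
    co
  })
  out <- do.call(rbind, rows)
  out <- out[c("response", "term", "estimate", "se", "df", "t", "p",
               "r2_marginal", "r2_conditional", "transform", "singular")]
  rownames(out) <- NULL
  attr(out, "missing") <- setdiff(expected, names(fits))
  out
}
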