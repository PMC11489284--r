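#' Element-to-element concentration ratios per subsample
#'
#' Computes dimensionless ratios of two element concentrations for every
#' analytical subsample, after conversion to a common unit (mg/kg dry mass).
#' When the numerator element is not measured on a subsample (C, N and S are
#' measured on separate small subsamples, the other nine elements on pooled
#' subsamples), the array-mean numerator concentration is paired with the
#' subsample's denominator instead; the pairing used is recorded in the
#' \code{num_source} column.
#'
#' @param t A \code{\link{composition_table}}.
#' @param numerator Element symbol for the numerator (e.g. \code{"C"}).
#' @param denominator Element symbol(s) for the denominator.
#' @param basis \code{"mass"} (ratio of mass concentrations, the default) or
#'   \code{"molar"} (mass ratio times \code{atomic_mass(den)/atomic_mass(num)}).
#' @return A data.frame with one row per subsample and denominator element:
#'   \code{treatment}, \code{array_id}, \code{subsample_id}, \code{element}
#'   (the denominator), \code{value}, \code{basis}, \code{num_source}.
#'   Subsamples with a zero denominator are excluded with a warning and
#'   listed in the \code{"excluded"} attribute.
#' @export
compute_element_ratio <- function(t, numerator, denominator,
                                  basis = c("mass", "molar")) {
  basis <- match.arg(basis)
  stopifnot(length(numerator) == 1L)
  if (!numerator %in% supported_elements()) {
    stop("unknown numerator element: ", numerator)
  }
  bad <- setdiff(denominator, supported_elements())
  if (length(bad) > 0L) {
    stop("unknown denominator element(s): ", paste(bad, collapse = ", "))
  }
  t <- to_common_units(t, "mg_per_kg")

  num_rows <- t[t$element == numerator, , drop = FALSE]
  if (nrow(num_rows) == 0L) {
    stop("numerator element ", numerator, " has no measurements")
  }
  num_by_sub <- num_rows$concentration
  names(num_by_sub) <- paste(num_rows$array_id, num_rows$subsample_id)
  num_array_mean <- tapply(num_rows$concentration, num_rows$array_id, mean)

  out <- vector("list", length(denominator))
  excluded <- list()
  for (i in seq_along(denominator)) {
    el <- denominator[i]
    den_rows <- t[t$element == el, , drop = FALSE]
    if (nrow(den_rows) == 0L) next
    miss_num <- setdiff(unique(den_rows$array_id), names(num_array_mean))
    if (length(miss_num) > 0L) {
      stop("numerator element ", numerator,
           " missing for array(s): ", paste(miss_num, collapse = ", "))
    }
    key <- paste(den_rows$array_id, den_rows$subsample_id)
    num_val <- num_by_sub[key]
    src <- ifelse(is.na(num_val), "array_mean", "subsample")
    num_val[is.na(num_val)] <- num_array_mean[den_rows$array_id[src ==
                                                                "array_mean"]]
    zero <- den_rows$concentration == 0
    if (any(zero)) {
      warning(sum(zero), " subsample(s) with zero ", el,
              " excluded from ", numerator, ":", el, " ratios")
      excluded[[el]] <- den_rows[zero, c("treatment", "array_id",
                                         "subsample_id", "element")]
    }
    value <- num_val / den_rows$concentration
    if (basis == "molar") {
      value <- value * atomic_mass(el) / atomic_mass(numerator)
    }
    out[[i]] <- data.frame(
      treatment = den_rows$treatment,
      array_id = den_rows$array_id,
      subsample_id = den_rows$subsample_id,
      element = el,
      value = value,
      basis = basis,
      num_source = src,
      stringsAsFactors = FALSE
    )[!zero, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L) {
    stop("no ", numerator, ":X ratios could be computed for the requested ",
         "denominator element(s)")
  }
  rownames(res) <- NULL
  attr(res, "excluded") <- if (length(excluded) > 0L)
    do.call(rbind, excluded) else NULL
  res
}

#' Carbon-to-element (C:X) ratios per subsample
#'
#' Convenience wrapper around \code{\link{compute_element_ratio}} with carbon
#' as numerator; returns the package's ratio-table layout with a
#' \code{cx_value} column.
#'
#' @param t A \code{\link{composition_table}}.
#' @param elements Denominator elements (default: all supported non-carbon
#'   elements present in \code{t}).
#' @param basis \code{"mass"} or \code{"molar"}.
#' @return A ratio table: \code{treatment}, \code{array_id},
#'   \code{subsample_id}, \code{element}, \code{cx_value}, \code{basis},
#'   \code{c_source}.
#' @examples
#' df <- data.frame(treatment = "aCO2", array_id = "a1", tree_id = "t1",
#'                  subsample_id = "s1", element = c("C", "N"),
#'                  concentration = c(50, 5), unit = "percent_dry_mass")
#' compute_cx_ratios(composition_table(df))
#' @export
compute_cx_ratios <- function(t, elements = NULL,
                              basis = c("mass", "molar")) {
  basis <- match.arg(basis)
  if (is.null(elements)) {
    elements <- intersect(supported_elements(), unique(t$element))
    elements <- setdiff(elements, "C")
  }
  if ("C" %in% elements) stop("C cannot be a denominator of a C:X ratio")
  r <- compute_element_ratio(t, "C", elements, basis = basis)
  names(r)[names(r) == "value"] <- "cx_value"
  names(r)[names(r) == "num_source"] <- "c_source"
  r
}

#' Array-level food C:X ratios
#'
#' Averages subsample-level C:X ratios within each array (the true
#' replicate); these array means are the food terms entering the trophic
#' stoichiometric ratio.
#'
#' @param r A ratio table from \code{\link{compute_cx_ratios}}.
#' @return A data.frame keyed by \code{treatment}, \code{array_id},
#'   \code{element} with the mean \code{cx_value}, \code{basis} and the
#'   number of subsamples averaged (\code{n_subsamples}).
#' @export
aggregate_food_ratios <- function(r) {
  stopifnot(all(c("treatment", "array_id", "element", "cx_value",
                  "basis") %in% names(r)))
  if (nrow(r) == 0L) stop("empty ratio table")
  if (length(unique(r$basis)) > 1L) {
    stop("mixed mass/molar bases in one ratio table")
  }
  if (anyNA(r$cx_value)) {
    bad <- unique(paste(r$treatment, r$array_id, r$element)[is.na(r$cx_value)])
    stop("missing ratio values in group(s): ", paste(bad, collapse = "; "))
  }
  agg <- stats::aggregate(cx_value ~ treatment + array_id + element,
                          data = r, FUN = mean)
  n <- stats::aggregate(cbind(n_subsamples = cx_value) ~ treatment +
                          array_id + element, data = r, FUN = length)
  out <- merge(agg, n, by = c("treatment", "array_id", "element"),
               sort = TRUE)
  out$basis <- r$basis[1L]
  out[order(out$treatment, out$array_id, out$element), ]
}
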