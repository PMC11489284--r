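#' Default generator parameters per element
#'
#' Ambient-treatment means and additive elevated-CO2 effects for the twelve
#' elements, in each element's conventional reporting unit, together with
#' the hierarchical noise scales. Means and effects follow the study
#' conditions the generator emulates (e.g. S 0.21 percent with effect
#' -0.02; K 19,254 mg/kg with effect -1,568.7; Fe 118.19 mg/kg with effect
#' -20.66; Mn back-transformed from its log-scale fit). Array-to-array and
#' residual standard deviations are unpublished and are set to 10 percent
#' and 1.5 percent of the ambient mean, which makes the array level
#' dominate the variance (conditional R2 above 0.9 with small marginal R2
#' even under the sampling noise of a 6-array design).
#'
#' @return A data.frame with columns \code{element}, \code{unit},
#'   \code{mean_aco2}, \code{effect_eco2}, \code{sd_array},
#'   \code{sd_resid}.
#' @export
default_element_params <- function() {
  p <- data.frame(
    element = c("C", "N", "P", "S", "K", "Na",
                "Ca", "Mg", "Cu", "Zn", "Fe", "Mn"),
    unit = c(rep("percent_dry_mass", 4), rep("mg_per_kg_dry_mass", 8)),
    mean_aco2 = c(49.7, 4.75, 0.35, 0.21, 19254.03, 328.53,
                  3621.62, 3856.04, 22.67, 67.08, 118.19, 42.10),
    effect_eco2 = c(0.10, 0.05, -0.02, -0.02, -1568.7, -52.08,
                    36.16, 228.92, -1.59, -3.08, -20.66, -4.38),
    stringsAsFactors = FALSE
  )
  p$sd_array <- 0.10 * p$mean_aco2
  p$sd_resid <- 0.015 * p$mean_aco2
  p
}

#' Configuration for the synthetic study generator
#'
#' Describes the hierarchical sampling design the generator emulates: two
#' CO2 treatments, three arrays per treatment with one tree each, 6-10
#' per-inflorescence analytical subsamples per tree for C/N/S and 3-5
#' pooled subsamples per tree for the other nine elements.
#'
#' @param arrays_per_treatment Number of arrays (= trees) per treatment,
#'   default 3.
#' @param subsamples_cns Integer range (min, max) of C/N/S subsamples per
#'   tree, default \code{c(6, 10)}.
#' @param subsamples_pooled Integer range of pooled subsamples per tree,
#'   default \code{c(3, 5)}.
#' @param elements Per-element parameter table in the layout of
#'   \code{\link{default_element_params}} (rows may be overridden or
#'   dropped).
#' @param seed Default RNG seed used by \code{\link{generate_study}} when
#'   none is supplied there.
#' @return An object of class \code{synthetic_study_config}.
#' @export
synthetic_study_config <- function(arrays_per_treatment = 3L,
                                   subsamples_cns = c(6L, 10L),
                                   subsamples_pooled = c(3L, 5L),
                                   elements = default_element_params(),
                                   seed = 1L) {
  if (arrays_per_treatment < 1L) stop("arrays_per_treatment must be >= 1")
  for (rng in list(subsamples_cns, subsamples_pooled)) {
    if (length(rng) != 2L || any(rng < 1L) || rng[1L] > rng[2L]) {
      stop("subsample ranges must be (min, max) with 1 <= min <= max")
    }
  }
  needed <- c("element", "unit", "mean_aco2", "effect_eco2", "sd_array",
              "sd_resid")
  if (!all(needed %in% names(elements))) {
    stop("elements table must have columns: ",
         paste(needed, collapse = ", "))
  }
  if (any(elements$mean_aco2 <= 0)) stop("element means must be positive")
  if (any(elements$sd_array < 0) || any(elements$sd_resid < 0)) {
    stop("noise SDs must be non-negative")
  }
  structure(list(arrays_per_treatment = as.integer(arrays_per_treatment),
                 subsamples_cns = as.integer(subsamples_cns),
                 subsamples_pooled = as.integer(subsamples_pooled),
                 elements = elements, seed = seed),
            class = "synthetic_study_config")
}

#' Generate a synthetic composition table
#'
#' Draws a study-shaped dataset from the hierarchical model: for each array
#' (tree) and element an array effect \code{Normal(0, sd_array)} is shared
#' by all of the tree's subsamples, and each observation adds
#' \code{Normal(0, sd_resid)} residual noise to
#' \code{mean + effect(treatment) + array effect}, truncated at zero. C, N
#' and S are placed on the per-inflorescence subsamples and the remaining
#' elements on the pooled subsamples. Fully reproducible from the seed.
#'
#' @param cfg A \code{\link{synthetic_study_config}}.
#' @param seed RNG seed; defaults to the one in \code{cfg}.
#' @return A \code{\link{composition_table}}.
#' @examples
#' comp <- generate_study(synthetic_study_config(), seed = 42)
#' table(comp$treatment, comp$element %in% c("C", "N", "S"))
#' @export
generate_study <- function(cfg = synthetic_study_config(), seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_study_config"))
  if (is.null(seed)) seed <- cfg$seed
  if (!is.null(seed)) set.seed(seed)
  el <- cfg$elements
  cns <- intersect(el$element, c("C", "N", "S"))
  pooled <- setdiff(el$element, cns)
  rows <- list()
  k <- 1L
  for (trt in c("aCO2", "eCO2")) {
    for (ai in seq_len(cfg$arrays_per_treatment)) {
      array_id <- sprintf("%s_array%d", sub("CO2", "", trt), ai)
      tree_id <- paste0("tree_", array_id)
      array_eff <- stats::rnorm(nrow(el), 0, el$sd_array)
      names(array_eff) <- el$element
      mu <- el$mean_aco2 + if (trt == "eCO2") el$effect_eco2 else 0
      names(mu) <- el$element

      draw <- function(elements, sub_prefix, n_sub) {
        out <- vector("list", n_sub)
        for (s in seq_len(n_sub)) {
          idx <- match(elements, el$element)
          val <- pmax(0, mu[elements] + array_eff[elements] +
                        stats::rnorm(length(elements), 0,
                                     el$sd_resid[idx]))
          out[[s]] <- data.frame(
            treatment = trt, array_id = array_id, tree_id = tree_id,
            subsample_id = sprintf("%s_%s%02d", array_id, sub_prefix, s),
            element = elements, concentration = unname(val),
            unit = el$unit[idx], stringsAsFactors = FALSE)
        }
        do.call(rbind, out)
      }
      if (length(cns) > 0L) {
        n_cns <- sample(seq(cfg$subsamples_cns[1L],
                            cfg$subsamples_cns[2L]), 1L)
        rows[[k]] <- draw(cns, "infl", n_cns); k <- k + 1L
      }
      if (length(pooled) > 0L) {
        n_pool <- sample(seq(cfg$subsamples_pooled[1L],
                             cfg$subsamples_pooled[2L]), 1L)
        rows[[k]] <- draw(pooled, "pool", n_pool); k <- k + 1L
      }
    }
  }
  composition_table(do.call(rbind, rows))
}

#' Configuration for synthetic consumer profiles
#'
#' @param species \code{"O_bicornis"} or \code{"A_mellifera"}.
#' @param n_replicates Number of replicate C:X profiles; defaults to the
#'   conventional 30 for the red mason bee and 45 for the honey bee.
#' @param medians Named vector of per-element C:X medians (> 0); default:
#'   back-calculated so that TSRs of default ambient food reproduce the
#'   published ambient TSR medians (see
#'   \code{\link{back_calculate_consumer_medians}}).
#' @param sd_log Log-scale standard deviation of the replicate-to-replicate
#'   variation (default 0.1, i.e. about 10 percent CV).
#' @param seed Default RNG seed for \code{\link{generate_consumers}}.
#' @return An object of class \code{synthetic_consumer_config}.
#' @export
synthetic_consumer_config <- function(species = c("O_bicornis",
                                                  "A_mellifera"),
                                      n_replicates = NULL,
                                      medians = NULL,
                                      sd_log = 0.1, seed = 1L) {
  species <- match.arg(species)
  if (is.null(n_replicates)) {
    n_replicates <- if (species == "O_bicornis") 30L else 45L
  }
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (is.null(medians)) medians <- default_consumer_medians(species)
  if (is.null(names(medians)) ||
      !all(names(medians) %in% setdiff(supported_elements(), "C"))) {
    stop("medians must be named by supported non-carbon elements")
  }
  if (any(!is.finite(medians)) || any(medians <= 0)) {
    stop("consumer C:X medians must be positive")
  }
  if (sd_log < 0) stop("sd_log must be non-negative")
  structure(list(species = species,
                 n_replicates = as.integer(n_replicates),
                 medians = medians, sd_log = sd_log, seed = seed),
            class = "synthetic_consumer_config")
}

#' Generate synthetic consumer C:X profiles
#'
#' Per replicate and element, draws
#' \code{C:X ~ lognormal(log median, sd_log)}; with \code{sd_log = 0} every
#' replicate equals the median exactly.
#'
#' @param cfg A \code{\link{synthetic_consumer_config}}.
#' @param seed RNG seed; defaults to the one in \code{cfg}.
#' @return A \code{\link{consumer_profile}} with
#'   \code{n_replicates} rows per element.
#' @export
generate_consumers <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_consumer_config"))
  if (is.null(seed)) seed <- cfg$seed
  if (!is.null(seed)) set.seed(seed)
  elements <- names(cfg$medians)
  grid <- expand.grid(replicate_id = sprintf("%s_r%02d", cfg$species,
                                             seq_len(cfg$n_replicates)),
                      element = elements, stringsAsFactors = FALSE)
  med <- cfg$medians[grid$element]
  grid$cx_value <- exp(stats::rnorm(nrow(grid), log(med), cfg$sd_log))
  grid$species <- cfg$species
  consumer_profile(grid[c("species", "replicate_id", "element",
                          "cx_value")])
}

#' Published TSR quartile reference
#'
#' Reference TSR quartiles (median, 25th, 75th percentile) for the red
#' mason bee and honey bee feeding on oak pollen-bearing flowers under
#' ambient and elevated CO2, shipped as a plain-text table. Used for the
#' assimilation-sensitivity re-classification check and to seed the default
#' synthetic consumer medians.
#'
#' @return A data.frame: \code{species}, \code{element}, \code{treatment},
#'   \code{median}, \code{q25}, \code{q75}.
#' @export
reference_tsr_quartiles <- function() {
  path <- system.file("extdata", "reference_tsr_quartiles.csv",
                      package = "pollenstoich", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Back-calculate consumer C:X medians from food ratios and TSR medians
#'
#' Rearranges the TSR definition: given the food C:X and a target TSR
#' median per element, the implied consumer C:X is
#' \code{food C:X / TSR median}. Used to seed the synthetic consumer
#' generator so default runs land near the reference TSR medians.
#'
#' @param food_cx Data frame with columns \code{element} and
#'   \code{cx_value} (array-level values are averaged per element).
#' @param tsr_medians Data frame with columns \code{element} and
#'   \code{median} (> 0).
#' @return Named numeric vector of consumer C:X medians for the shared
#'   elements.
#' @export
back_calculate_consumer_medians <- function(food_cx, tsr_medians) {
  stopifnot(all(c("element", "cx_value") %in% names(food_cx)),
            all(c("element", "median") %in% names(tsr_medians)))
  food <- tapply(food_cx$cx_value, food_cx$element, mean)
  shared <- intersect(names(food), tsr_medians$element)
  if (length(shared) == 0L) {
    stop("food ratios and TSR medians share no elements")
  }
  med <- tsr_medians$median[match(shared, tsr_medians$element)]
  if (any(med == 0)) stop("TSR medians must be non-zero")
  out <- food[shared] / med
  names(out) <- shared
  out
}

# Expected food C:X under the default ambient generator means (mass basis).
default_food_cx <- function() {
  p <- default_element_params()
  conc <- convert_concentration(p$mean_aco2, p$unit, "mg_per_kg_dry_mass")
  names(conc) <- p$element
  cx <- conc["C"] / conc[setdiff(p$element, "C")]
  data.frame(element = setdiff(p$element, "C"), cx_value = unname(cx),
             stringsAsFactors = FALSE)
}

default_consumer_medians <- function(species) {
  ref <- reference_tsr_quartiles()
  ref <- ref[ref$species == species & ref$treatment == "aCO2", ]
  back_calculate_consumer_medians(default_food_cx(), ref)
}
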