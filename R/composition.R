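#' Construct and validate a composition table
#'
#' A composition table is the package's central long-format container for
#' elemental concentrations: one row per analytical subsample and element,
#' with the sampling lineage (CO2 treatment, array, tree, subsample) kept
#' alongside the measurement. Each array contains exactly one sampled tree,
#' so the array is the true replicate.
#'
#' @param df A data.frame with columns \code{treatment} (\code{"aCO2"} or
#'   \code{"eCO2"}), \code{array_id}, \code{tree_id}, \code{subsample_id},
#'   \code{element}, \code{concentration} and \code{unit}.
#' @return The validated data.frame with class \code{composition_table}.
#' @examples
#' df <- data.frame(treatment = "aCO2", array_id = "a1", tree_id = "t1",
#'                  subsample_id = "s1", element = c("C", "N"),
#'                  concentration = c(49.7, 4.75), unit = "percent_dry_mass")
#' composition_table(df)
#' @export
composition_table <- function(df) {
  required <- c("treatment", "array_id", "tree_id", "subsample_id",
                "element", "concentration", "unit")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("composition table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$treatment <- as.character(df$treatment)
  df$array_id <- as.character(df$array_id)
  df$tree_id <- as.character(df$tree_id)
  df$subsample_id <- as.character(df$subsample_id)
  df$element <- as.character(df$element)
  df$unit <- as.character(df$unit)

  problems <- character(0)
  bad_trt <- which(!df$treatment %in% c("aCO2", "eCO2"))
  if (length(bad_trt) > 0L) {
    problems <- c(problems, sprintf(
      "rows %s: treatment must be 'aCO2' or 'eCO2'",
      paste(utils::head(bad_trt, 10L), collapse = ",")))
  }
  bad_elem <- which(!df$element %in% supported_elements())
  if (length(bad_elem) > 0L) {
    problems <- c(problems, sprintf(
      "rows %s: unknown element symbol(s) %s",
      paste(utils::head(bad_elem, 10L), collapse = ","),
      paste(unique(df$element[bad_elem]), collapse = ", ")))
  }
  bad_unit <- which(!df$unit %in% supported_units())
  if (length(bad_unit) > 0L) {
    problems <- c(problems, sprintf(
      "rows %s: unrecognised unit(s) %s",
      paste(utils::head(bad_unit, 10L), collapse = ","),
      paste(unique(df$unit[bad_unit]), collapse = ", ")))
  }
  bad_conc <- which(!is.finite(df$concentration) | df$concentration < 0)
  if (length(bad_conc) > 0L) {
    problems <- c(problems, sprintf(
      "rows %s: concentrations must be finite and non-negative",
      paste(utils::head(bad_conc, 10L), collapse = ",")))
  }
  key <- paste(df$treatment, df$array_id, df$subsample_id, df$element,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    problems <- c(problems, sprintf(
      "rows %s: duplicate (subsample_id, element) measurement",
      paste(utils::head(dup, 10L), collapse = ",")))
  }
  # one tree per array: tree_id must be a function of array_id
  trees_per_array <- tapply(df$tree_id, df$array_id,
                            function(x) length(unique(x)))
  multi <- names(trees_per_array)[trees_per_array > 1L]
  if (length(multi) > 0L) {
    problems <- c(problems, sprintf(
      "array(s) %s map to more than one tree (one tree per array required)",
      paste(multi, collapse = ", ")))
  }
  if (length(problems) > 0L) {
    stop("invalid composition table:\n  ",
         paste(problems, collapse = "\n  "))
  }
  rownames(df) <- NULL
  class(df) <- c("composition_table", "data.frame")
  df
}

#' Read a composition table from CSV
#'
#' Reads a long-format elemental composition CSV (UTF-8, comma separated,
#' header row, decimal point) and validates it. Column names can be remapped
#' through \code{schema} when the file uses different headers.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   \code{c(concentration = "value")}.
#' @return A \code{\link{composition_table}}.
#' @export
read_composition <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(raw)) {
        stop("schema column '", src, "' not present in ", path)
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  required <- c("treatment", "array_id", "tree_id", "subsample_id",
                "element", "concentration", "unit")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("CSV ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  composition_table(raw)
}

#' Convert a composition table to a common unit
#'
#' Rescales all concentrations to one reporting unit using
#' 1 percent dry mass = 10,000 mg/kg dry mass.
#'
#' @param t A \code{\link{composition_table}}.
#' @param target \code{"mg_per_kg"} (or \code{"mg_per_kg_dry_mass"}) or
#'   \code{"mass_fraction"} (i.e. \code{"percent_dry_mass"}).
#' @return A \code{composition_table} in the target unit.
#' @examples
#' df <- data.frame(treatment = "aCO2", array_id = "a1", tree_id = "t1",
#'                  subsample_id = "s1", element = "P",
#'                  concentration = 0.35, unit = "percent_dry_mass")
#' to_common_units(composition_table(df), "mg_per_kg")
#' @export
to_common_units <- function(t, target = "mg_per_kg") {
  target <- match.arg(target, c("mg_per_kg", "mass_fraction",
                                "mg_per_kg_dry_mass", "percent_dry_mass"))
  unit <- if (target %in% c("mg_per_kg", "mg_per_kg_dry_mass"))
    "mg_per_kg_dry_mass" else "percent_dry_mass"
  t$concentration <- convert_concentration(t$concentration, t$unit, unit)
  t$unit <- unit
  t
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf(
    "Composition table: %d measurements, %d elements, %d arrays (%s)\n",
    nrow(x), length(unique(x$element)), length(unique(x$array_id)),
    paste(sort(unique(x$treatment)), collapse = " vs ")))
  NextMethod()
}

#' Write a data.frame to CSV with logging
#'
#' Helper used by the pipeline so every file write is recorded.
#' @param df Data frame to write.
#' @param path Output path.
#' @param log Optional function called with a message string.
#' @keywords internal
write_csv_logged <- function(df, path, log = NULL) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(log)) log(sprintf("wrote %s (%d rows)", path, nrow(df)))
  invisible(path)
}
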