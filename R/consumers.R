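#' Construct and validate a consumer stoichiometry profile
#'
#' Consumer profiles hold the denominator of the trophic stoichiometric
#' ratio: per-replicate C:X ratios of the matter a bee must synthesise
#' during larval development (the adult body, plus the cocoon for the red
#' mason bee, whose cocoon is a major elemental sink; the honey bee cocoon
#' is too thin and contaminated to measure, so only its adult body is used).
#'
#' @param df A data.frame with columns \code{species} (\code{"O_bicornis"}
#'   or \code{"A_mellifera"}), \code{replicate_id}, \code{element},
#'   \code{cx_value} (> 0) and optionally \code{basis} (default
#'   \code{"mass"}).
#' @return The validated data.frame with class \code{consumer_profile}.
#' @export
consumer_profile <- function(df) {
  required <- c("species", "replicate_id", "element", "cx_value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("consumer profile is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)
  if (!"basis" %in% names(df)) df$basis <- "mass"
  df <- df[c(required, "basis")]
  df$species <- as.character(df$species)
  df$replicate_id <- as.character(df$replicate_id)
  df$element <- as.character(df$element)

  problems <- character(0)
  bad_sp <- which(!df$species %in% c("O_bicornis", "A_mellifera"))
  if (length(bad_sp) > 0L) {
    problems <- c(problems, sprintf(
      "rows %s: species must be 'O_bicornis' or 'A_mellifera'",
      paste(utils::head(bad_sp, 10L), collapse = ",")))
  }
  bad_elem <- which(!df$element %in% setdiff(supported_elements(), "C"))
  if (length(bad_elem) > 0L) {
    problems <- c(problems, sprintf(
      "rows %s: element must be a supported non-carbon symbol",
      paste(utils::head(bad_elem, 10L), collapse = ",")))
  }
  bad_cx <- which(!is.finite(df$cx_value) | df$cx_value <= 0)
  if (length(bad_cx) > 0L) {
    problems <- c(problems, sprintf(
      "rows %s: cx_value must be finite and > 0",
      paste(utils::head(bad_cx, 10L), collapse = ",")))
  }
  if (length(problems) > 0L) {
    stop("invalid consumer profile:\n  ",
         paste(problems, collapse = "\n  "))
  }
  rownames(df) <- NULL
  class(df) <- c("consumer_profile", "data.frame")
  df
}

#' Read consumer C:X profiles from CSV
#'
#' @param path CSV with columns
#'   \code{species,replicate_id,element,cx_value}.
#' @return A \code{\link{consumer_profile}}.
#' @export
read_consumers <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  consumer_profile(utils::read.csv(path, stringsAsFactors = FALSE,
                                   fileEncoding = "UTF-8"))
}
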