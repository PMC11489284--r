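default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    input = list(composition_csv = NULL, consumers_csv = NULL),
    synthetic = list(study = list(), consumers = list()),
    basis = "mass",
    assimilation = list(a_c = 0.25, a_x = 1),
    extra_a_x = NULL,
    multivariate = list(element_set = "merged", normalization = "minmax",
                        n_permutations = 999L, nmds_restarts = 20L,
                        nmds_max_iter = 300L, nmds_tol = 1e-6),
    transforms = NULL
  )
}

#' Validate a pipeline run configuration
#'
#' Reads a configuration from a JSON/YAML file or a list, fills defaults,
#' and checks every cross-field constraint before any computation.
#' Violations are aggregated into one human-readable error.
#'
#' @param config A named list, or a path to a \code{.json}, \code{.yaml} or
#'   \code{.yml} file.
#' @return The completed configuration (class \code{run_config}).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("config must be a list or a file path")
  cfg <- utils::modifyList(default_run_config(), config)

  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L ||
      !is.finite(cfg$seed)) {
    note("seed must be a single finite number")
  }
  ac <- cfg$assimilation$a_c
  if (!is.numeric(ac) || length(ac) != 1L || !is.finite(ac) || ac <= 0 ||
      ac > 1) {
    note("assimilation a_c must be in (0, 1]")
  }
  ax <- cfg$assimilation$a_x
  if (!is.numeric(unlist(ax)) || any(unlist(ax) <= 0) ||
      any(unlist(ax) > 1)) {
    note("assimilation a_x must be value(s) in (0, 1]")
  }
  if (!is.null(cfg$extra_a_x)) {
    if (!is.numeric(cfg$extra_a_x) || any(cfg$extra_a_x <= 0) ||
        any(cfg$extra_a_x > 1)) {
      note("extra_a_x must be value(s) in (0, 1]")
    }
  }
  if (!cfg$basis %in% c("mass", "molar")) {
    note("basis must be 'mass' or 'molar'")
  }
  apt <- cfg$synthetic$study$arrays_per_treatment
  if (!is.null(apt) && apt < 2L) {
    note(paste0("arrays_per_treatment must be >= 2: a single array per ",
                "treatment confounds the CO2 effect with the tree ",
                "(pseudoreplication)"))
  }
  mv <- cfg$multivariate
  if (!mv$element_set %in% c("merged", "pooled9", "cns")) {
    note("multivariate element_set must be 'merged', 'pooled9' or 'cns'")
  }
  if (!mv$normalization %in% c("minmax", "zscore")) {
    note("multivariate normalization must be 'minmax' or 'zscore'")
  }
  if (!is.numeric(mv$n_permutations) || mv$n_permutations < 1) {
    note("multivariate n_permutations must be >= 1")
  }
  if (!is.numeric(mv$nmds_restarts) || mv$nmds_restarts < 1) {
    note("multivariate nmds_restarts must be >= 1")
  }
  if (!is.null(cfg$input$composition_csv) &&
      !file.exists(cfg$input$composition_csv)) {
    note(paste0("input composition_csv does not exist: ",
                cfg$input$composition_csv))
  }
  if (!is.null(cfg$input$consumers_csv) &&
      !file.exists(cfg$input$consumers_csv)) {
    note(paste0("input consumers_csv does not exist: ",
                cfg$input$consumers_csv))
  }
  if (length(errors) > 0L) {
    stop("invalid run configuration:\n  ",
         paste(errors, collapse = "\n  "))
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Run the full analysis pipeline
#'
#' Chains every stage on one dataset (read from CSV inputs or drawn from
#' the synthetic generator): subsample and array-level C:X ratios;
#' normalisation, Bray-Curtis dissimilarity, PERMANOVA, NMDS and
#' environmental fitting; the per-response mixed-model coefficient table;
#' TSR records, quartile summaries and treatment comparisons for both bee
#' species. All declared artifacts are written to the output directory
#' together with the serialised configuration and a structured log, so
#' every output is re-derivable from config + seed alone.
#'
#' @param config A configuration list/path (see
#'   \code{\link{validate_config}}); must provide \code{output_dir}.
#' @return Invisibly, a list with all stage results and the vector of
#'   written file paths.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  if (is.null(cfg$output_dir)) stop("config must set output_dir")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(cfg$output_dir, name)

  log_lines <- character(0)
  log <- function(msg, stage = "pipeline") {
    log_lines <<- c(log_lines, jsonlite::toJSON(
      list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
           stage = stage, message = msg), auto_unbox = TRUE))
  }
  fail <- function(stage, e) {
    log(paste0("FAILED: ", conditionMessage(e)), stage)
    writeLines(unlist(log_lines), out("run_log.jsonl"))
    writeLines(stage, out("FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  jsonlite::write_json(unclass(cfg), out("config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  set.seed(cfg$seed)
  log(sprintf("seed %d; package version %s", cfg$seed,
              as.character(utils::packageVersion("pollenstoich"))))

  # --- stage: data ---------------------------------------------------------
  res <- list()
  tryCatch({
    if (!is.null(cfg$input$composition_csv)) {
      comp <- read_composition(cfg$input$composition_csv)
      log(sprintf("read %d composition rows from %s", nrow(comp),
                  cfg$input$composition_csv), "data")
    } else {
      study_cfg <- do.call(synthetic_study_config, cfg$synthetic$study)
      comp <- generate_study(study_cfg, seed = cfg$seed)
      log(sprintf("generated %d synthetic composition rows", nrow(comp)),
          "data")
    }
    if (!is.null(cfg$input$consumers_csv)) {
      consumers <- read_consumers(cfg$input$consumers_csv)
    } else {
      consumers <- rbind(
        generate_consumers(do.call(synthetic_consumer_config,
                                   utils::modifyList(
                                     list(species = "O_bicornis"),
                                     cfg$synthetic$consumers)),
                           seed = cfg$seed + 1L),
        generate_consumers(do.call(synthetic_consumer_config,
                                   utils::modifyList(
                                     list(species = "A_mellifera"),
                                     cfg$synthetic$consumers)),
                           seed = cfg$seed + 2L))
      consumers <- consumer_profile(consumers)
    }
    res$composition <- comp
    res$consumers <- consumers
  }, error = function(e) fail("data", e))

  # --- stage: ratios -------------------------------------------------------
  tryCatch({
    ratios <- withCallingHandlers(
      compute_cx_ratios(comp, basis = cfg$basis),
      warning = function(w) {
        log(conditionMessage(w), "ratios")
        invokeRestart("muffleWarning")
      })
    excluded <- attr(ratios, "excluded")
    if (!is.null(excluded)) {
      log(sprintf("%d subsample ratio(s) excluded (zero denominator)",
                  nrow(excluded)), "ratios")
    }
    food <- aggregate_food_ratios(ratios)
    res$ratios_subsample <- ratios
    res$ratios_array <- food
    write_csv_logged(ratios, out("ratios_subsample.csv"), log)
    write_csv_logged(food, out("ratios_array.csv"), log)
  }, error = function(e) fail("ratios", e))

  # --- stage: multivariate -------------------------------------------------
  tryCatch({
    mv <- cfg$multivariate
    m <- composition_matrix(comp, element_set = mv$element_set)
    meta <- attr(m, "meta")
    mn <- normalize_profiles(m, method = mv$normalization)
    d <- if (mv$normalization == "minmax") bray_curtis(mn) else
      as.matrix(stats::dist(mn))
    perm <- permanova(d, meta$treatment, n_perm = mv$n_permutations,
                      seed = cfg$seed + 10L)
    ord <- nmds(d, k = 2L, restarts = mv$nmds_restarts,
                max_iter = mv$nmds_max_iter, tol = mv$nmds_tol,
                seed = cfg$seed + 11L)
    env <- as.data.frame(mn[, , drop = FALSE])
    env$treatment <- meta$treatment
    fits <- fit_environment(ord, env, n_perm = mv$n_permutations,
                            seed = cfg$seed + 12L)
    res$distance <- d
    res$permanova <- perm
    res$nmds <- ord
    res$envfit <- fits
    jsonlite::write_json(unclass(perm)[c("r2", "pseudo_f", "df_model",
                                         "df_residual", "p",
                                         "n_permutations", "method")],
                         out("permanova.json"), auto_unbox = TRUE,
                         digits = NA)
    coords <- data.frame(meta, ord$points, stress = ord$stress)
    write_csv_logged(coords, out("ordination.csv"), log)
    write_csv_logged(fits, out("ordination_fit.csv"), log)
    log(sprintf("PERMANOVA R2=%.3f F=%.2f p=%.3f; NMDS stress=%.4f",
                perm$r2, perm$pseudo_f, perm$p, ord$stress),
        "multivariate")
  }, error = function(e) fail("multivariate", e))

  # --- stage: univariate ---------------------------------------------------
  tryCatch({
    transforms <- if (is.null(cfg$transforms)) default_transforms() else
      cfg$transforms
    fits <- fit_study_lmms(comp, transforms = transforms)
    tab1 <- build_table1(fits)
    for (nm in names(fits)) {
      if (fits[[nm]]$singular) {
        log(sprintf("singular/degenerate fit flagged for %s", nm),
            "univariate")
      }
    }
    res$lmm_fits <- fits
    res$table1 <- tab1
    write_csv_logged(tab1, out("table1.csv"), log)
  }, error = function(e) fail("univariate", e))

  # --- stage: tsr ----------------------------------------------------------
  tryCatch({
    assim <- assimilation_config(a_c = cfg$assimilation$a_c,
                                 a_x = cfg$assimilation$a_x)
    records <- compute_tsr(res$ratios_array, consumers, assim)
    summary <- summarize_tsr(records, assim)
    if (!is.null(cfg$extra_a_x)) {
      alt <- assimilation_config(a_c = cfg$assimilation$a_c,
                                 a_x = cfg$extra_a_x)
      alt_records <- compute_tsr(res$ratios_array, consumers, alt)
      alt_summary <- summarize_tsr(alt_records, alt)
      col <- sprintf("limiting_at_%02.0f", 100 * cfg$extra_a_x[1L])
      summary[[col]] <- alt_summary$limiting_at_median[
        match(paste(summary$species, summary$treatment, summary$element),
              paste(alt_summary$species, alt_summary$treatment,
                    alt_summary$element))]
    }
    comparisons <- compare_treatments(records)
    box <- tsr_box_stats(records, threshold = assim$threshold)
    res$tsr_records <- records
    res$tsr_summary <- summary
    res$tsr_comparisons <- comparisons
    res$tsr_box_stats <- box
    write_csv_logged(as.data.frame(records), out("tsr_records.csv"), log)
    write_csv_logged(summary, out("tsr_summary.csv"), log)
    write_csv_logged(comparisons, out("tsr_comparisons.csv"), log)
    write_csv_logged(box, out("tsr_box_stats.csv"), log)
  }, error = function(e) fail("tsr", e))

  writeLines(unlist(log_lines), out("run_log.jsonl"))
  res$files <- list.files(cfg$output_dir, full.names = TRUE)
  res$config <- cfg
  invisible(res)
}

#' Boxplot statistics of the TSR distributions
#'
#' Per species, treatment and element: median, quartiles, whisker ends
#' (most extreme values within 1.5 interquartile ranges of the box) and
#' outlier count, plus the limitation threshold line, i.e. everything
#' needed to re-draw the TSR boxplot figure.
#'
#' @param records TSR records from \code{\link{compute_tsr}}.
#' @param threshold Limitation threshold to annotate (default 4).
#' @return A data.frame of boxplot statistics.
#' @export
tsr_box_stats <- function(records, threshold = 4) {
  grp <- interaction(records$species, records$treatment, records$element,
                     drop = TRUE, sep = "\r")
  pieces <- lapply(split(records, grp), function(g) {
    q <- stats::quantile(g$tsr, c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
    iqr <- q[3L] - q[1L]
    lo <- min(g$tsr[g$tsr >= q[1L] - 1.5 * iqr])
    hi <- max(g$tsr[g$tsr <= q[3L] + 1.5 * iqr])
    data.frame(species = g$species[1L], treatment = g$treatment[1L],
               element = g$element[1L], median = q[2L], q25 = q[1L],
               q75 = q[3L], whisker_low = lo, whisker_high = hi,
               n_outliers = sum(g$tsr < lo | g$tsr > hi), n = nrow(g),
               threshold = threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$species, out$element, out$treatment), ]
  rownames(out) <- NULL
  out
}
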