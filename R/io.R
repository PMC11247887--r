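.survey_cols <- c("id", "age", "sex", "survey_year", "disease", "weight")

#' Read a survey microdata CSV
#'
#' Expects the exact header `id,age,sex,survey_year,disease,weight`
#' (comma-separated, UTF-8, `.` decimal point), `sex` in `male`/`female`,
#' `disease` in 0/1, positive weights. Validation errors cite the offending
#' row number.
#'
#' @param path file path.
#' @param permissive if `TRUE`, extra columns are tolerated (and dropped);
#'   by default unknown columns are an error.
#' @return Data frame of validated survey records.
#' @export
read_survey <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.survey_cols, names(d))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(d), .survey_cols)
  if (length(extra) && !permissive)
    stop(path, ": unknown column(s): ", paste(extra, collapse = ", "),
         " (use permissive = TRUE to ignore)", call. = FALSE)
  d <- d[.survey_cols]
  if (nrow(d) == 0L) stop(path, ": no records", call. = FALSE)
  bad <- which(!d$disease %in% c(0L, 1L))
  if (length(bad))
    stop(path, ": disease must be 0 or 1 (row ", bad[1], ")", call. = FALSE)
  bad <- which(!is.finite(d$weight) | d$weight <= 0)
  if (length(bad))
    stop(path, ": weight must be positive (row ", bad[1], ")", call. = FALSE)
  bad <- which(!d$sex %in% c("male", "female"))
  if (length(bad))
    stop(path, ": sex must be 'male' or 'female' (row ", bad[1], ")",
         call. = FALSE)
  bad <- which(!is.finite(d$age) | d$age != round(d$age))
  if (length(bad))
    stop(path, ": age must be an integer (row ", bad[1], ")", call. = FALSE)
  d
}

#' Write a survey microdata CSV
#'
#' Columns are emitted in the dialect's exact order.
#'
#' @param records survey data frame.
#' @param path output path.
#' @export
write_survey <- function(records, path) {
  .validate_survey(records)
  utils::write.csv(records[.survey_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a mortality schedule CSV
#'
#' Header `year,sex,age,rate` with `rate` in deaths per person-year;
#' duplicate (year, sex, age) combinations and negative rates are rejected.
#'
#' @param path file path.
#' @return A [mortality_schedule()].
#' @export
read_mortality <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("year", "sex", "age", "rate"), names(d))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tryCatch(mortality_schedule(d),
           error = function(e) stop(path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' Write a mortality schedule CSV
#' @param schedule a [mortality_schedule()].
#' @param path output path.
#' @export
write_mortality <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a standard population CSV
#'
#' Header `age_lo,age_hi,weight`; weights are normalized to sum to one.
#'
#' @param path file path.
#' @return A [standard_population()].
#' @export
read_standard <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("age_lo", "age_hi", "weight"), names(d))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tryCatch(standard_population(d$age_lo, d$age_hi, d$weight),
           error = function(e) stop(path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' Write a standard population CSV
#' @param std a [standard_population()].
#' @param path output path.
#' @export
write_standard <- function(std, path) {
  utils::write.csv(std[c("age_lo", "age_hi", "weight")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a prevalence surface to JSON
#'
#' Stores the coefficient vector, the covariance matrix (row-major), the
#' basis description and the domain, so a fitted surface can move between
#' the `fit` and `estimate` pipeline stages.
#'
#' @param surface a `prevalence_surface`.
#' @param path output path.
#' @export
write_surface <- function(surface, path) {
  obj <- list(
    coef = unname(surface$coef),
    vcov = list(dim = dim(surface$vcov),
                values = as.vector(t(surface$vcov))),
    basis = surface$basis,
    years = surface$years,
    sigma2 = surface$sigma2,
    df_residual = surface$df_residual,
    year_domain = surface$year_domain)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a prevalence surface from JSON
#' @param path file path written by [write_surface()].
#' @return A `prevalence_surface`.
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  V <- matrix(obj$vcov$values, nrow = obj$vcov$dim[1], byrow = TRUE)
  structure(list(coef = obj$coef, vcov = V,
                 basis = list(knots = obj$basis$knots,
                              boundary = obj$basis$boundary,
                              age_domain = obj$basis$age_domain,
                              year_center = obj$basis$year_center,
                              sex_levels = obj$basis$sex_levels),
                 years = obj$years, sigma2 = obj$sigma2,
                 df_residual = obj$df_residual,
                 year_domain = obj$year_domain),
            class = "prevalence_surface")
}

#' Write pipeline results to a directory
#'
#' Emits `report.csv` (the [report_table()] rows), `incidence_by_age.csv`
#' (per-cell point estimate and percentile band, per 1000 person-years) and
#' `run_metadata.json` (seed, repetitions, configuration echo, package
#' version) into `dir`.
#'
#' @param result an [resample()] result built with a standard population.
#' @param dir output directory (created if absent).
#' @param config optional configuration list echoed into the metadata.
#' @return The directory, invisibly.
#' @export
write_results <- function(result, dir, config = NULL) {
  stopifnot(inherits(result, "incidence_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep_tab <- report_table(result)
  .write_csv_full <- function(d, path) {
    # %.17g round-trips doubles exactly through text
    num <- vapply(d, is.double, logical(1))
    d[num] <- lapply(d[num], function(x) sprintf("%.17g", x))
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  .write_csv_full(as.data.frame(rep_tab), file.path(dir, "report.csv"))
  by_age <- data.frame(result$cells,
                       rate = result$band[, "median"] * 1000,
                       lo = result$band[, "lo"] * 1000,
                       hi = result$band[, "hi"] * 1000,
                       point = result$point * 1000,
                       negative = result$negative)
  .write_csv_full(by_age, file.path(dir, "incidence_by_age.csv"))
  meta <- list(seed = result$config$seed,
               repetitions = result$config$repetitions,
               mrr_lo_range = result$config$mrr_lo_range,
               mrr_hi_range = result$config$mrr_hi_range,
               years = result$years, sexes = result$sexes,
               age_range = range(result$ages),
               package_version = as.character(utils::packageVersion("idmrates")),
               config = config)
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Default pipeline configuration
#'
#' The packaged single source of truth for pipeline defaults (a YAML file
#' under `extdata`); [read_config()] overlays a user file on top of it.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  path <- system.file("extdata", "default_config.yaml", package = "idmrates")
  yaml::read_yaml(path)
}

#' Read a pipeline configuration file
#'
#' A flat YAML key-value file; keys absent from the file fall back to the
#' packaged defaults, unknown keys are an error.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop(path, ": unknown config key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    cfg[names(user)] <- user
  }
  if (cfg$repetitions < 2)
    stop("config: repetitions must be at least 2", call. = FALSE)
  if (length(cfg$wave_years) < 2)
    stop("config: at least two wave_years are required", call. = FALSE)
  if (!cfg$derivative_method %in% c("analytic", "finite_difference"))
    stop("config: derivative_method must be 'analytic' or 'finite_difference'",
         call. = FALSE)
  cfg
}
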