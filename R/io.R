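# CSV / YAML / JSON interfaces. All CSV dialects: comma-separated, header
# row, '.' decimal, UTF-8. Numeric fields are written at 17 significant
# digits so write -> read round-trips doubles exactly.

read_checked_csv <- function(path, columns, numeric_cols) {
  if (!file.exists(path)) stop_domain("file not found: %s", path)
  if (file.size(path) == 0L) stop_domain("empty file: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop_domain("no data rows in %s", path)
  extra <- setdiff(names(raw), columns)
  if (length(extra))
    stop_domain("unknown column(s) in %s: %s", path,
                paste(extra, collapse = ", "))
  missing <- setdiff(columns, names(raw))
  if (length(missing))
    stop_domain("missing column(s) in %s: %s", path,
                paste(missing, collapse = ", "))
  for (cl in numeric_cols) {
    v <- raw[[cl]]
    if (any(grepl("^[0-9]+,[0-9]+$", trimws(v)))) {
      row <- which(grepl("^[0-9]+,[0-9]+$", trimws(v)))[1L]
      stop_domain(
        "decimal comma in %s (column %s, line %d); use '.' decimals",
        path, cl, row + 1L)
    }
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad))
      stop_domain("non-numeric value '%s' in %s (column %s, line %d)",
                  v[bad[1L]], path, cl, bad[1L] + 1L)
    raw[[cl]] <- num
  }
  raw[columns]
}

write_17g_csv <- function(df, path) {
  out <- df
  for (cl in names(out))
    if (is.numeric(out[[cl]])) out[[cl]] <- vapply(out[[cl]], fmt_num, "")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write splicing time-course tables
#'
#' CSV schema: \code{time_min, frac_precursor, frac_intermediate,
#' frac_product, replicate, conc_uM}. Numeric fields are serialised at 17
#' significant digits, so a write -> read round trip is lossless. Malformed
#' input (unknown or missing columns, decimal commas, non-numeric cells,
#' empty files) raises a validation error naming file, column and line.
#'
#' @param path file path.
#' @param course time-course data frame (layout of
#'   \code{\link{simulate_time_course}}).
#' @return \code{read_time_course_csv}: a validated
#'   \code{"species_time_course"} data frame. \code{write_time_course_csv}:
#'   the path, invisibly.
#' @export
read_time_course_csv <- function(path) {
  df <- read_checked_csv(path, time_course_columns,
                         setdiff(time_course_columns, "replicate"))
  validate_time_course(df)
  class(df) <- c("species_time_course", "data.frame")
  df
}

#' @rdname read_time_course_csv
#' @export
write_time_course_csv <- function(course, path) {
  validate_time_course(course)
  write_17g_csv(course[time_course_columns], path)
}

#' Read / write k_obs series tables
#'
#' CSV schema: \code{conc_uM, kobs_per_min} with optional
#' \code{se_per_min}.
#'
#' @param path file path.
#' @param series k_obs series data frame.
#' @return \code{read_kobs_csv}: a validated data frame;
#'   \code{write_kobs_csv}: the path, invisibly.
#' @export
read_kobs_csv <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: %s", path)
  if (file.size(path) == 0L) stop_domain("empty file: %s", path)
  head <- names(utils::read.csv(path, nrows = 1L, check.names = FALSE))
  cols <- c("conc_uM", "kobs_per_min")
  if ("se_per_min" %in% head) cols <- c(cols, "se_per_min")
  read_checked_csv(path, cols, cols)
}

#' @rdname read_kobs_csv
#' @export
write_kobs_csv <- function(series, path) {
  cols <- intersect(c("conc_uM", "kobs_per_min", "se_per_min"),
                    names(series))
  write_17g_csv(series[cols], path)
}

#' Read / write ITC titrations (CSV heats + YAML metadata sidecar)
#'
#' Heats CSV schema: \code{injection_index, volume_uL,
#' heat_kcal_per_mol}. The YAML sidecar (same path with extension
#' \code{.yaml}, or given explicitly) carries \code{cell_conc_uM},
#' \code{syringe_conc_uM}, \code{cell_volume_mL} and
#' \code{temperature_C}.
#'
#' @param path CSV file path.
#' @param titration an \code{"itc_titration"} (see
#'   \code{\link{simulate_itc}}).
#' @param sidecar YAML metadata path (default: \code{path} with
#'   \code{.yaml} extension).
#' @return \code{read_itc_csv}: a list with \code{design}
#'   (\code{\link{itc_design}}) and \code{heats}, directly consumable by
#'   \code{\link{fit_itc_single_site}}. \code{write_itc_csv}: the path,
#'   invisibly.
#' @export
read_itc_csv <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.csv$", ".yaml", path)
  if (!file.exists(sidecar)) stop_domain("ITC metadata not found: %s", sidecar)
  meta <- yaml::read_yaml(sidecar)
  need <- c("cell_conc_uM", "syringe_conc_uM", "cell_volume_mL",
            "temperature_C")
  if (!all(need %in% names(meta)))
    stop_domain("ITC metadata must define %s", paste(need, collapse = ", "))
  df <- read_checked_csv(path, c("injection_index", "volume_uL",
                                 "heat_kcal_per_mol"),
                         c("injection_index", "volume_uL",
                           "heat_kcal_per_mol"))
  design <- itc_design(cell_conc_M = meta$cell_conc_uM * 1e-6,
                       syringe_conc_M = meta$syringe_conc_uM * 1e-6,
                       injection_volumes_L = df$volume_uL * 1e-6,
                       cell_volume_L = meta$cell_volume_mL * 1e-3,
                       conditions = thermo_conditions(meta$temperature_C +
                                                        273.15))
  list(design = design,
       heats = data.frame(injection = df$injection_index,
                          volume_uL = df$volume_uL,
                          heat_kcal_per_mol = df$heat_kcal_per_mol))
}

#' @rdname read_itc_csv
#' @export
write_itc_csv <- function(titration, path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.csv$", ".yaml", path)
  d <- titration$design
  h <- titration$heats
  write_17g_csv(data.frame(injection_index = h$injection,
                           volume_uL = h$volume_uL,
                           heat_kcal_per_mol = h$heat_kcal_per_mol), path)
  yaml::write_yaml(list(cell_conc_uM = d$cell_conc_M * 1e6,
                        syringe_conc_uM = d$syringe_conc_M * 1e6,
                        cell_volume_mL = d$cell_volume_L * 1e3,
                        temperature_C = d$conditions$T - 273.15), sidecar)
  invisible(path)
}

#' Read / write BLI sensorgram tables
#'
#' CSV schema: \code{time_s, response_nm, conc_uM, phase} with phase in
#' \code{association}/\code{dissociation}.
#'
#' @param path file path.
#' @param sensorgrams sensorgram data frame (see
#'   \code{\link{simulate_bli}}).
#' @return \code{read_bli_csv}: a validated data frame;
#'   \code{write_bli_csv}: the path, invisibly.
#' @export
read_bli_csv <- function(path) {
  df <- read_checked_csv(path, c("time_s", "response_nm", "conc_uM",
                                 "phase"),
                         c("time_s", "response_nm", "conc_uM"))
  bad <- setdiff(unique(df$phase), c("association", "dissociation"))
  if (length(bad))
    stop_domain("invalid phase value(s) in %s: %s", path,
                paste(bad, collapse = ", "))
  df
}

#' @rdname read_bli_csv
#' @export
write_bli_csv <- function(sensorgrams, path) {
  write_17g_csv(sensorgrams[c("time_s", "response_nm", "conc_uM",
                              "phase")], path)
}

#' Write a JSON analysis report
#'
#' Serialises estimates together with the resolved configuration, seed and
#' package version (the reproducibility contract: every report records how
#' it was produced).
#'
#' @param results named list of results; package S3 objects are serialised
#'   by their fields.
#' @param path output path.
#' @param config named list echoing the resolved run configuration.
#' @param seed the seed used (NA when the stage is deterministic).
#' @return The path, invisibly.
#' @export
write_report_json <- function(results, path, config = list(), seed = NA) {
  payload <- list(
    package = "splicekin",
    version = as.character(utils::packageVersion("splicekin")),
    seed = seed,
    config = config,
    results = results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}
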