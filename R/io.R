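# Tabular I/O: time-series CSV, measured-rate tables, flux result TSV.
# Output files carry a provenance header (comment lines) with the package
# version, seed and parameters needed to re-execute the run.

provenance_header <- function(provenance = list()) {
  pv <- tryCatch(as.character(utils::packageVersion("egflux")),
                 error = function(e) "dev")
  fields <- c(list(tool = paste0("egflux ", pv)), provenance)
  paste0("# ", names(fields), " = ",
         vapply(fields, function(x) paste(format(x), collapse = ","), ""))
}

#' Write a batch time series as CSV
#'
#' @param series A time series (see [validate_timeseries()]).
#' @param path Output path.
#' @param provenance Named list added to the comment header (seed,
#'   parameters, ...).
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(series, path, provenance = list()) {
  validate_timeseries(series)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(provenance), con)
  utils::write.csv(series, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a batch time series from CSV
#'
#' Accepts the column layout written by [write_timeseries_csv()]
#' (`time_h, od, do_percent, glc_g_l, xyl_g_l, eg_g_l, ga_g_l, gly_g_l,
#' nh4_mM, co2_mmol_l_h, o2_mmol_l_h`); missing values allowed. Malformed
#' files are reported with named-column diagnostics.
#'
#' @param path CSV path.
#' @return Validated time-series data frame.
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  missing_cols <- setdiff(c("time_h", "od"), names(df))
  if (length(missing_cols))
    stop("malformed time-series CSV ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  validate_timeseries(df)
  df
}

#' Read measured specific rates from TSV
#'
#' Two columns: `id` (reaction id) and `value` (mmol/gCDW/h, uptake
#' negative).
#'
#' @param path TSV path.
#' @return Named numeric vector suitable for [apply_measured_rates()].
#' @export
read_rates_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, comment.char = "#")
  if (!all(c("id", "value") %in% names(df)))
    stop("malformed rate table ", path, ": need columns id, value")
  stats::setNames(as.numeric(df$value), df$id)
}

#' Write flux results as TSV
#'
#' One row per reaction: flux (and, when available, uptake-normalized flux
#' and sampling statistics).
#'
#' @param solution A `flux_solution`.
#' @param path Output path.
#' @param uptake_id Optional exchange id for the normalized-flux column.
#' @param sampling Optional `sampling_summary` whose per-reaction
#'   median/sd/min/max are joined in.
#' @param provenance Named list for the comment header.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(solution, path, uptake_id = NULL,
                           sampling = NULL, provenance = list()) {
  if (!inherits(solution, "flux_solution") || solution$status != "optimal")
    stop("need an optimal flux_solution")
  tab <- data.frame(id = names(solution$fluxes),
                    flux = as.numeric(solution$fluxes), row.names = NULL)
  if (!is.null(uptake_id)) {
    nv <- normalize_by_uptake(solution, uptake_id)
    tab$normalized_flux <- as.numeric(nv[tab$id])
  }
  if (!is.null(sampling)) {
    sm <- sampling$summary
    tab <- merge(tab, sm, by = "id", all.x = TRUE, sort = FALSE)
    provenance <- c(provenance, list(n_samples = sampling$n_samples,
                                     sampling_seed = sampling$seed))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(provenance), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a physiology summary as JSON
#'
#' @param summary A `physiology_summary`.
#' @param path Output path.
#' @param provenance Named list stored under `$provenance`.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path, provenance = list()) {
  stopifnot(inherits(summary, "physiology_summary"))
  doc <- unclass(summary)
  doc$phases <- unclass(doc$phases)
  doc$provenance <- c(list(tool = paste0(
    "egflux ", tryCatch(as.character(utils::packageVersion("egflux")),
                        error = function(e) "dev"))), provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
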