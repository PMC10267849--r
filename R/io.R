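# CSV interfaces for dosing records and cohort tables.

#' Restore cohort metadata on a table read back from CSV
#'
#' CSV serialization loses factor levels and the covariate kind/role
#' attributes; this reattaches them from a generator configuration so the
#' table can flow through the weighting and modeling stages.
#'
#' @param df data.frame read from \code{cohort.csv}.
#' @param config the generator configuration the cohort was built with.
#' @return the data.frame with factor columns and kind/role attributes
#'   restored.
#' @export
as_cohort <- function(df, config) {
  df$patient_id <- as.character(df$patient_id)
  for (cv in config$covariates) {
    if (cv$kind == "categorical")
      df[[cv$name]] <- factor(df[[cv$name]], levels = cv$args$levels)
  }
  attr(df, "covariate_kinds") <- covariate_kinds(config)
  attr(df, "confounders") <- confounder_names(config)
  attr(df, "adjustment") <- adjustment_names(config)
  df
}

#' Write dosing records to CSV (events + windows)
#'
#' @param records list of \code{\link{dosing_record}}.
#' @param dosing_path events CSV: patient_id, drug, time_min, dose_ug.
#' @param windows_path windows CSV: patient_id, window_start_min,
#'   window_end_min.
#' @export
write_dosing_csv <- function(records, dosing_path, windows_path) {
  ev <- do.call(rbind, lapply(records, function(r) {
    if (nrow(r$events) == 0) return(NULL)
    data.frame(patient_id = r$patient_id, drug = r$events$drug,
               time_min = r$events$time, dose_ug = r$events$dose,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ev))
    ev <- data.frame(patient_id = character(0), drug = character(0),
                     time_min = numeric(0), dose_ug = numeric(0))
  utils::write.csv(ev, dosing_path, row.names = FALSE)
  win <- do.call(rbind, lapply(records, function(r)
    data.frame(patient_id = r$patient_id,
               window_start_min = r$window_start,
               window_end_min = r$window_end, stringsAsFactors = FALSE)))
  utils::write.csv(win, windows_path, row.names = FALSE)
  invisible(NULL)
}

#' Read dosing records from CSV (events + windows)
#'
#' @param dosing_path events CSV with columns patient_id, drug, time_min,
#'   dose_ug.
#' @param windows_path windows CSV with columns patient_id,
#'   window_start_min, window_end_min.
#' @return list of \code{\link{dosing_record}}, one per windows row.
#' @export
read_dosing_csv <- function(dosing_path, windows_path) {
  ev <- utils::read.csv(dosing_path, stringsAsFactors = FALSE)
  win <- utils::read.csv(windows_path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "drug", "time_min", "dose_ug")
  if (!all(needed %in% names(ev)))
    stop_("dosing CSV must have columns: %s", paste(needed, collapse = ", "))
  lapply(seq_len(nrow(win)), function(i) {
    pid <- win$patient_id[i]
    sub <- ev[ev$patient_id == pid, , drop = FALSE]
    events <- data.frame(time = sub$time_min, dose = sub$dose_ug,
                         drug = sub$drug, stringsAsFactors = FALSE)
    dosing_record(pid, events, win$window_start_min[i], win$window_end_min[i])
  })
}
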