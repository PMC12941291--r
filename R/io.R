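#' Read a migration-curve table
#'
#' Comma-separated, UTF-8, header row required. Expected columns:
#' `compound`, `food`, `time_h`, `replicate`, and either `mr_percent` or
#' `conc_ng_ml`. If only a migrated concentration (ng/mL of food) is
#' given, it is converted to a migration ratio through the contact-system
#' geometry: migrated mass = concentration x food volume, divided by the
#' initial additive amount in the film.
#'
#' @param path File path.
#' @param system A [contact_system()], used only for the concentration
#'   conversion.
#' @return Data frame in the migration input schema with `mr_percent`.
#' @export
read_migration_curves <- function(path, system = contact_system()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("compound", "food", "time_h", "replicate")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  if (!"mr_percent" %in% names(df)) {
    if (!"conc_ng_ml" %in% names(df))
      stop("need either an mr_percent or a conc_ng_ml column")
    m_m <- df$conc_ng_ml * system$food_volume_ml
    df$mr_percent <- migration_ratio(m_m, initial_amount(system$film))
  }
  if (any(!is.finite(df$time_h)) || any(df$time_h < 0))
    stop("time_h must be non-negative and finite")
  df
}

#' Read digestion sample and blank tables
#'
#' `read_digestion_samples()` expects columns `compound`, `food`,
#' `replicate`, `C_d_ng_ml`, `V_d_ml`, `C_s_ng_ml`, `V_s_ml`,
#' `blank_batch`; `read_blanks()` expects `batch`, `compound`,
#' `blank_ng_ml`.
#'
#' @param path File path.
#' @return Data frame in the respective schema.
#' @export
read_digestion_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("compound", "food", "replicate", "C_d_ng_ml", "V_d_ml",
            "C_s_ng_ml", "V_s_ml", "blank_batch")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' @rdname read_digestion_samples
#' @export
read_blanks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("batch", "compound", "blank_ng_ml")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Write a delimited report
#'
#' Plain comma-separated output without row names, the format used for
#' fit reports and risk tables.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
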