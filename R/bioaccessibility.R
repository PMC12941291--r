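#' Procedural-blank correction
#'
#' Subtracts a procedural-blank background concentration from a measured
#' concentration, flooring the result at zero. Correction never increases
#' a concentration. When flooring occurred the returned vector carries the
#' attribute `floored` marking the affected entries.
#'
#' @param measured Measured concentration(s), ng/mL, >= 0.
#' @param blank Blank concentration(s), ng/mL, >= 0 (recycled).
#' @return Corrected concentrations with attribute `floored` (logical).
#' @examples
#' blank_correct(50.0, 1.30)   # 48.7
#' blank_correct(0.5, 1.30)    # 0, floored
#' @export
blank_correct <- function(measured, blank) {
  if (any(!is.finite(measured)) || any(measured < 0))
    stop("measured concentrations must be non-negative")
  if (any(!is.finite(blank)) || any(blank < 0))
    stop("blank concentrations must be non-negative")
  raw <- measured - blank
  structure(pmax(raw, 0), floored = raw < 0)
}

#' Bioaccessibility from a digestion measurement
#'
#' The bioaccessible fraction of a spiked compound recovered in the
#' digestive-fluid supernatant after simulated digestion:
#'
#'   BA(%) = 100 * (C_d * V_d) / (C_s * V_s)
#'
#' where C_d, V_d are the digest supernatant concentration and digestion
#' mixture volume and C_s, V_s the spike concentration and food sample
#' volume. Only the amount products matter, so BA is invariant under
#' simultaneous rescaling of the two concentrations or the two volumes.
#' Values above 100 percent (noise) are kept but flagged with a warning.
#'
#' @param C_d Digest concentration, ng/mL, >= 0 (vectorised).
#' @param V_d Digestion-mixture volume, mL, > 0.
#' @param C_s Spiked concentration in the food, ng/mL, > 0.
#' @param V_s Food sample volume, mL, > 0.
#' @return Bioaccessibility in percent.
#' @export
compute_ba <- function(C_d, V_d, C_s, V_s) {
  if (any(!is.finite(C_s)) || any(C_s <= 0)) stop("C_s must be strictly positive")
  if (any(!is.finite(V_s)) || any(V_s <= 0)) stop("V_s must be strictly positive")
  if (any(!is.finite(V_d)) || any(V_d <= 0)) stop("V_d must be strictly positive")
  if (any(!is.finite(C_d)) || any(C_d < 0)) stop("C_d must be non-negative")
  ba <- 100 * (C_d * V_d) / (C_s * V_s)
  if (any(ba > 100))
    warning(sprintf("%d bioaccessibility value(s) exceed 100%% (kept, flagged)",
                    sum(ba > 100)))
  ba
}

#' Per-replicate bioaccessibility from a digestion sample table
#'
#' Applies blank correction (per batch and compound) and the
#' bioaccessibility formula to each replicate row of a digestion table in
#' the standard schema (`compound`, `food`, `replicate`, `C_d_ng_ml`,
#' `V_d_ml`, `C_s_ng_ml`, `V_s_ml`, `blank_batch`).
#'
#' @param samples Digestion sample table, see [read_digestion_samples()].
#' @param blanks Optional blank table with columns `batch`, `compound`,
#'   `blank_ng_ml` (several procedural blanks per batch allowed). A
#'   compound absent from its batch is treated as blank 0 with a warning.
#' @param blank_stat How to pool several blanks of one batch/compound:
#'   their mean (default) or their maximum.
#' @return `samples` with added columns `C_d_corrected`, `floored`,
#'   `ba_percent`.
#' @export
ba_from_digestion <- function(samples, blanks = NULL,
                              blank_stat = c("mean", "max")) {
  blank_stat <- match.arg(blank_stat)
  need <- c("compound", "food", "replicate", "C_d_ng_ml", "V_d_ml",
            "C_s_ng_ml", "V_s_ml")
  if (!all(need %in% names(samples)))
    stop("missing columns: ", paste(setdiff(need, names(samples)), collapse = ", "))
  bl <- rep(0, nrow(samples))
  if (!is.null(blanks) && nrow(blanks) > 0) {
    if (!"blank_batch" %in% names(samples))
      stop("samples need a blank_batch column when blanks are supplied")
    stat <- if (blank_stat == "mean") mean else max
    agg <- stats::aggregate(blank_ng_ml ~ batch + compound, blanks, stat)
    key <- paste(samples$blank_batch, samples$compound)
    m <- match(key, paste(agg$batch, agg$compound))
    if (anyNA(m)) {
      miss <- unique(samples$compound[is.na(m)])
      warning("no blank value for compound(s) ", paste(miss, collapse = ", "),
              "; treated as blank 0")
    }
    bl <- ifelse(is.na(m), 0, agg$blank_ng_ml[m])
  }
  corr <- blank_correct(samples$C_d_ng_ml, bl)
  samples$C_d_corrected <- as.numeric(corr)
  samples$floored <- attr(corr, "floored")
  samples$ba_percent <- suppressWarnings(
    compute_ba(samples$C_d_corrected, samples$V_d_ml,
               samples$C_s_ng_ml, samples$V_s_ml))
  samples
}

#' Summarise replicate bioaccessibility values
#'
#' Mean, sample standard deviation and replicate count per compound x
#' food, the form in which digestion results are usually reported
#' (mean +/- sd, n = 3).
#'
#' @param replicates Data frame with columns `compound`, `food`,
#'   `ba_percent` (one row per replicate), or a bare numeric vector of
#'   replicate values for a single group.
#' @return Data frame `compound`, `food`, `ba_percent` (mean), `ba_sd`,
#'   `n`, ordered by decreasing per-compound mean.
#' @examples
#' summarize_ba(c(40, 50, 60))  # mean 50, sd 10
#' @export
summarize_ba <- function(replicates) {
  if (is.numeric(replicates)) {
    if (length(replicates) == 0) stop("empty input")
    replicates <- data.frame(compound = "compound", food = "food",
                             ba_percent = replicates)
  }
  if (nrow(replicates) == 0) stop("empty input")
  agg <- stats::aggregate(ba_percent ~ compound + food, replicates,
                          function(v) c(mean = mean(v),
                                        sd = if (length(v) > 1) stats::sd(v) else 0,
                                        n = length(v)))
  out <- data.frame(compound = agg$compound, food = agg$food,
                    ba_percent = agg$ba_percent[, "mean"],
                    ba_sd = agg$ba_percent[, "sd"],
                    n = as.integer(agg$ba_percent[, "n"]))
  means <- tapply(out$ba_percent, out$compound, mean)
  out[order(-means[as.character(out$compound)], out$food), , drop = FALSE]
}
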