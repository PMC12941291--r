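#' Reference-dose registry
#'
#' Per-compound oral reference doses (RfD, ng per kg body weight per day)
#' used to convert estimated daily intakes into hazard quotients. The
#' default registry covers the five flame retardants assessed by the
#' packaged fixtures: TPhP 70,000; EHDPP 6,000; TBOEP 15,000; TnBP
#' 10,000; TPPO 20,000.
#'
#' @param ... Named values to add or override, e.g. `rfd_registry(X = 5e4)`.
#' @return Named numeric vector of RfD values.
#' @export
rfd_registry <- function(...) {
  rfd <- c(TPhP = 70000, EHDPP = 6000, TBOEP = 15000, TnBP = 10000,
           TPPO = 20000)
  extra <- c(...)
  if (length(extra)) rfd[names(extra)] <- extra
  if (any(rfd <= 0)) stop("reference doses must be strictly positive")
  rfd
}

#' Estimated daily intake from a food concentration
#'
#' EDI = V * C / BW: daily food intake times the compound concentration in
#' the food, normalised by body weight.
#'
#' @param V Daily intake of the food, kg/day, >= 0.
#' @param C Concentration of the compound in the food, ng/kg food.
#' @param BW Body weight, kg (default 60, the standard adult value).
#' @return EDI in ng per kg body weight per day.
#' @export
edi_concentration <- function(V, C, BW = 60) {
  if (any(!is.finite(BW)) || any(BW <= 0)) stop("body weight must be positive")
  if (any(V < 0)) stop("daily intake V must be non-negative")
  V * C / BW
}

#' Bioaccessibility-adjusted EDI from migration data
#'
#' Rewrites the intake equation in terms of the packaging parameters: the
#' food concentration is C = C_p * (MR_f/100) * m_p * 1e3 ng/kg food
#' (additive content of the packaging, times the fraction that migrated,
#' times the packaging mass per kg food, with ug -> ng), and the intake is
#' further scaled by the bioaccessible fraction BA/100:
#'
#'   EDI = V * C_p * (MR_f/100) * m_p * 1e3 / BW * (BA/100)
#'
#' With BA = 100 this reduces to [edi_concentration()] on C.
#'
#' @param V Daily intake of the food, kg/day.
#' @param mr_f Final migration ratio, percent.
#' @param ba Bioaccessibility, percent (default 100 = migration-only).
#' @param C_p Additive content of the packaging, ug/g (default 100,
#'   i.e. an incorporation level of 0.1 g/kg).
#' @param m_p Packaging mass in contact with 1 kg of food, g/kg
#'   (default 4).
#' @param BW Body weight, kg.
#' @return EDI in ng per kg body weight per day.
#' @examples
#' edi_from_migration(V = 0.6, mr_f = 50, ba = 100)  # 2000
#' @export
edi_from_migration <- function(V, mr_f, ba = 100, C_p = 100, m_p = 4,
                               BW = 60) {
  if (any(!is.finite(C_p)) || any(C_p <= 0) ||
      any(!is.finite(m_p)) || any(m_p <= 0))
    stop("packaging parameters must be strictly positive")
  if (any(mr_f < 0) || any(ba < 0))
    stop("percentages must be non-negative")
  C <- C_p * (mr_f / 100) * m_p * 1e3  # ng per kg food
  edi_concentration(V, C, BW) * (ba / 100)
}

#' Hazard quotient
#'
#' HQ = EDI / RfD. An HQ below 1 is read as acceptable risk; at or above
#' 1 a potential health concern exists.
#'
#' @param edi Estimated daily intake, ng/kg bw/day.
#' @param rfd Reference dose, ng/kg bw/day, > 0.
#' @return Dimensionless hazard quotient.
#' @examples
#' hazard_quotient(905.78, 15000)  # 6.04e-2
#' @export
hazard_quotient <- function(edi, rfd) {
  if (any(!is.finite(rfd)) || any(rfd <= 0))
    stop("reference dose must be strictly positive")
  edi / rfd
}

#' Exposure and risk per compound, food and scenario
#'
#' Joins migration, bioaccessibility and consumption into
#' bioaccessibility-adjusted EDI and HQ values.
#'
#' @param data Data frame with columns `compound`, `food`, `scenario`,
#'   `V_kg_day` (daily intake of that food under that scenario),
#'   `mr_f_percent` (final migration ratio) and `ba_percent`.
#' @param rfd Named RfD vector, see [rfd_registry()]. Every compound in
#'   `data` must be present.
#' @param C_p,m_p,BW Packaging and population parameters, see
#'   [edi_from_migration()].
#' @return `data` with added columns `edi`, `hq`, `acceptable`
#'   (HQ < 1).
#' @export
assess_exposure <- function(data, rfd = rfd_registry(), C_p = 100, m_p = 4,
                            BW = 60) {
  need <- c("compound", "food", "scenario", "V_kg_day", "mr_f_percent",
            "ba_percent")
  if (!all(need %in% names(data)))
    stop("missing columns: ", paste(setdiff(need, names(data)), collapse = ", "))
  missing_rfd <- setdiff(unique(data$compound), names(rfd))
  if (length(missing_rfd))
    stop("no reference dose for compound(s): ",
         paste(missing_rfd, collapse = ", "))
  data$edi <- edi_from_migration(data$V_kg_day, data$mr_f_percent,
                                 data$ba_percent, C_p, m_p, BW)
  data$hq <- hazard_quotient(data$edi, rfd[as.character(data$compound)])
  data$acceptable <- data$hq < 1
  data
}

#' Ranked risk report
#'
#' Condenses a table of exposure results into the quantities a risk
#' assessor scans first: the worst-case HQ per compound over all foods
#' and scenarios, the per-food EDI ranking of compounds, and any rows
#' with HQ >= 1.
#'
#' @param results Data frame with at least `compound`, `food`,
#'   `scenario`, `edi`, `hq` (e.g. from [assess_exposure()]).
#' @return Object of class `"risk_summary"`: list with `max_hq`
#'   (per-compound data frame, decreasing), `edi_ranking` (list of
#'   compound orderings per food, by decreasing EDI within the first
#'   scenario present), `flagged` (rows with HQ >= 1).
#' @export
risk_summary <- function(results) {
  if (nrow(results) == 0) stop("empty results")
  idx <- tapply(seq_len(nrow(results)), results$compound,
                function(i) i[which.max(results$hq[i])])
  max_hq <- results[unlist(idx), c("compound", "food", "scenario", "edi", "hq")]
  max_hq <- max_hq[order(-max_hq$hq), , drop = FALSE]
  rownames(max_hq) <- NULL
  sc <- results$scenario == results$scenario[1]
  edi_ranking <- lapply(split(results[sc, , drop = FALSE], results$food[sc]),
                        function(d) as.character(d$compound[order(-d$edi)]))
  flagged <- results[results$hq >= 1, , drop = FALSE]
  structure(list(max_hq = max_hq, edi_ranking = edi_ranking,
                 flagged = flagged),
            class = "risk_summary")
}

#' @export
print.risk_summary <- function(x, ...) {
  cat("Worst-case hazard quotient per compound:\n")
  df <- x$max_hq
  df$hq <- sprintf("%.3g", df$hq)
  df$edi <- sprintf("%.4g", df$edi)
  print(df, row.names = FALSE)
  if (nrow(x$flagged)) {
    cat("\nRows with HQ >= 1 (potential concern):\n")
    print(x$flagged[, c("compound", "food", "scenario", "hq")],
          row.names = FALSE)
  } else {
    cat("\nAll hazard quotients below 1 (acceptable risk range).\n")
  }
  invisible(x)
}
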