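#' Packaged reference tables
#'
#' Loads the delimited-text reference tables shipped with the package:
#' \describe{
#'   \item{`rfd_table1`}{Per-compound reference doses (ng/kg bw/day).}
#'   \item{`migration_params_table2`}{Fitted migration parameters (alpha,
#'     K_P/F, D in cm^2/s, R^2) for 5 compounds x 9 foods.}
#'   \item{`edi_table3`}{Estimated daily intake (ng/kg bw/day) and the
#'     published hazard quotient per compound, food and consumption
#'     scenario (median / 95th percentile).}
#' }
#'
#' The tables are stored exactly as published. Known internal
#' inconsistencies of the intake/HQ table are *not* repaired; they are
#' attached as an `errata` attribute (character vector) so that
#' downstream checks can avoid the affected rows. In particular, several
#' foods' HQ columns appear row-permuted relative to their EDI columns
#' (Vinegar with Soy milk, Beer with Baijiu, Cooking wine with Coconut
#' milk), and the Soda water TPhP median HQ has an apparent exponent
#' typo; only the self-consistent food blocks should be used as
#' numerical anchors.
#'
#' @param name Fixture name, one of `"rfd_table1"`,
#'   `"migration_params_table2"`, `"edi_table3"`.
#' @return A data frame; for `edi_table3` with attribute `errata`.
#' @examples
#' rfd <- load_fixture("rfd_table1")
#' rfd$rfd_ng_kg_bw_day[rfd$compound == "TBOEP"]  # 15000
#' @export
load_fixture <- function(name = c("rfd_table1", "migration_params_table2",
                                  "edi_table3")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "migrisk",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (name == "edi_table3") {
    attr(df, "errata") <- c(
      "HQ columns of several foods are row-permuted relative to their EDI columns: Vinegar <-> Soy milk, Beer <-> Baijiu, Cooking wine <-> Coconut milk.",
      "Soda water TPhP median HQ is printed as 1.06e-4; EDI/RfD gives 1.06e-3 (apparent exponent typo).",
      "Self-consistent anchor blocks: Eastern leaf and Jasmine tea (all rows); values preserved verbatim, never corrected.")
  }
  df
}

#' Foods whose published EDI and HQ columns are mutually consistent
#'
#' Helper for validation code that wants numerical anchors: the food
#' blocks of the published intake table whose HQ values equal EDI/RfD
#' row by row (see the errata on [load_fixture()]).
#'
#' @return Character vector of food names.
#' @export
consistent_edi_foods <- function() c("Eastern leaf", "Jasmine tea")
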