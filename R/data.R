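#' Example compound annotation table
#'
#' The published annotation table of a Q/TOF survey of an *Artemisiae
#' Scopariae* Herba extract: 34 compounds with molecular formula, CAS
#' number, retention time, reported monoisotopic mass, measured
#' \eqn{[M+H]^+} m/z and ppm error. Six compounds (quercetin, luteolin,
#' isorhamnetin, hydroxygenkwanin, eupatilin, chlorogenic acid) carry a
#' `topo1_inhibitor` flag: they showed larger peak areas in the
#' topoisomerase-I-containing ultrafiltration sample than in the
#' protein-free control. Formulas are given as effective compositions —
#' the adduct of row 19 ("Salidroside + NH3") and the water loss of row 28
#' are already folded in.
#'
#' @return data frame with columns `no`, `name`, `category`, `rt_min`,
#'   `formula`, `cas`, `monoisotopic_mass`, `measured_mz`, `ppm_error`,
#'   `topo1_inhibitor`.
#' @export
#' @examples
#' tab <- example_compound_table()
#' lib <- compound_library(tab)
#' max(abs(lib$monoisotopic_mass - tab$monoisotopic_mass))
example_compound_table <- function() {
  path <- system.file("extdata", "topo1_screen_compounds.csv",
                      package = "itpnet", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
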