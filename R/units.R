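#' Unit conversion between mass and molar serum concentrations
#'
#' Serum OPN and extracellular-proteasome concentrations are reported by
#' ELISA in ng/mL; the circuit model works in nM. Conversion uses the
#' molecular mass of the analyte: recombinant OPN constructs are taken as
#' 35 kDa and the 20S proteasome barrel as 700 kDa by default.
#'
#' @param x concentration in ng/mL (or nM for the inverse function).
#' @param kda molecular mass in kilodaltons.
#' @return concentration in nM (or ng/mL).
#' @examples
#' ng_ml_to_nM(100, kda = 35)   # ~2.86 nM OPN
#' nM_to_ng_ml(ng_ml_to_nM(100, 35), 35)
#' @export
ng_ml_to_nM <- function(x, kda) {
  stopifnot(is.numeric(x), is.numeric(kda), all(kda > 0))
  # ng/mL = µg/L; (µg/L) / (kDa * 1000 g/mol) * 1e3 = nmol/L
  x / kda
}

#' @rdname ng_ml_to_nM
#' @export
nM_to_ng_ml <- function(x, kda) {
  stopifnot(is.numeric(x), is.numeric(kda), all(kda > 0))
  x * kda
}

#' Default molecular masses (kDa) used for unit conversion
#' @return named numeric vector with elements `opn` and `proteasome`.
#' @export
default_masses <- function() c(opn = 35, proteasome = 700)
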