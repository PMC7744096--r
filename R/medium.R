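# Standard high-glucose DMEM amino-acid formulation (mg/L of the supplied
# compound and its molecular weight), used to recompute the reduced-medium
# concentrations: culturing at "5% AA" supplies each amino acid at 5% of
# these molar levels.
DMEM_AA <- data.frame(
  amino_acid = c("Gly", "Arg", "Cys2", "Gln", "His", "Ile", "Leu", "Lys",
                 "Met", "Phe", "Ser", "Thr", "Trp", "Tyr", "Val"),
  compound = c("Glycine", "L-Arginine hydrochloride", "L-Cystine 2HCl",
               "L-Glutamine", "L-Histidine hydrochloride-H2O",
               "L-Isoleucine", "L-Leucine", "L-Lysine hydrochloride",
               "L-Methionine", "L-Phenylalanine", "L-Serine", "L-Threonine",
               "L-Tryptophan", "L-Tyrosine disodium salt dihydrate",
               "L-Valine"),
  mg_per_l = c(30, 84, 63, 584, 42, 105, 105, 146, 30, 66, 42, 95, 16, 104, 94),
  mw = c(75.07, 210.66, 313.22, 146.15, 209.63, 131.17, 131.17, 182.65,
         149.21, 165.19, 105.09, 119.12, 204.23, 261.22, 117.15),
  stringsAsFactors = FALSE)

#' Standard DMEM amino-acid formulation
#'
#' @return data.frame with the supplied compound, its mg/L in standard
#'   high-glucose DMEM, molecular weight and the derived molar
#'   concentration in micromolar.
#' @export
dmemFormulation <- function() {
  out <- DMEM_AA
  out$concentration_uM <- out$mg_per_l / out$mw * 1000
  out
}

#' Amino-acid concentration in (reduced) DMEM
#'
#' Computes the molar concentration of an amino acid supplied at a given
#' fraction of the standard DMEM formulation; e.g. at \code{fraction =
#' 0.05} glutamine is ~200 uM and methionine ~10 uM.
#'
#' @param aminoAcid three-letter code (e.g. "Gln", "Met").
#' @param fraction fraction of the standard formulation (default 1).
#' @return concentration in micromolar.
#' @examples
#' mediumAminoAcid("Gln", 0.05)  # ~200
#' mediumAminoAcid("Met", 0.05)  # ~10
#' @export
mediumAminoAcid <- function(aminoAcid, fraction = 1) {
  f <- dmemFormulation()
  i <- match(aminoAcid, f$amino_acid)
  if (anyNA(i))
    stop("amino acid not in the DMEM formulation: ",
         paste(aminoAcid[is.na(i)], collapse = ", "))
  unname(f$concentration_uM[i] * fraction)
}
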