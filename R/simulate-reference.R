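# Common cytosolic isodecoder labels used when synthesising references.
# Gln-CTG / Gln-TTG first so small references always contain the pair whose
# selective uncharging the assay is designed to resolve.
ISODECODER_LABELS <- c(
  "Gln-CTG", "Gln-TTG", "iMet-CAT", "Met-CAT", "Val-AAC", "Val-CAC",
  "Leu-AAG", "Leu-CAG", "Arg-ACG", "Arg-TCT", "Lys-CTT", "Lys-TTT",
  "Glu-CTC", "Glu-TTC", "Gly-GCC", "Gly-TCC", "Ala-AGC", "Ser-AGA",
  "Ile-AAT", "Ile-GAT", "Thr-AGT", "Pro-AGG", "Asn-GTT", "Asp-GTC",
  "His-GTG", "Tyr-GTA", "Cys-GCA", "Trp-CCA", "Phe-GAA", "SeC-TCA")

#' Synthesize a tRNA gene set and spike-in for simulation studies
#'
#' Generates random tRNA-like gene sequences (68-78 nt, anticodon embedded
#' at positions 35-37) for the first \code{nIsodecoders} labels of a
#' standard cytosolic isodecoder panel (always including the two glutamine
#' isodecoders Gln-CTG and Gln-TTG), plus a synthetic yeast-Phe-like
#' spike-in. Sequences from different isodecoders are kept at pairwise
#' 3'-anchored Hamming distance >= \code{minSeparation}; additional gene
#' copies within an isodecoder differ from the first copy at at most one
#' internal position, exercising the within-isodecoder multimapping path.
#'
#' @param nIsodecoders number of isodecoder groups (2-30).
#' @param genesPerIsodecoder integer (recycled): gene copies per group.
#' @param minSeparation minimum cross-isodecoder Hamming distance.
#' @param seed integer RNG seed.
#' @return list with elements \code{genes} and \code{spikeIn}, data.frames
#'   ready for [buildReference()].
#' @export
simulateReference <- function(nIsodecoders = 20, genesPerIsodecoder = 1,
                              minSeparation = 3, seed = 1) {
  stopifnot(nIsodecoders >= 2, nIsodecoders <= length(ISODECODER_LABELS))
  keys <- ISODECODER_LABELS[seq_len(nIsodecoders)]
  nper <- rep_len(genesPerIsodecoder, nIsodecoders)
  withSeed(seed, {
    base <- character(nIsodecoders)
    for (i in seq_len(nIsodecoders)) {
      repeat {
        len <- sample(68:78, 1)
        s <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
        ac <- sub("^.*-", "", keys[i])
        substr(s, 35, 37) <- ac
        ok <- TRUE
        for (j in seq_len(i - 1L)) {
          # the appended CCA is shared, so genomic-tail distance is the
          # mature-sequence distance under the 3'-anchored comparison
          o <- min(nchar(s), nchar(base[j]))
          mm <- hammingRaw(substr(s, nchar(s) - o + 1L, nchar(s)),
                           substr(base[j], nchar(base[j]) - o + 1L,
                                  nchar(base[j])))
          if (mm < minSeparation) { ok <- FALSE; break }
        }
        if (ok) { base[i] <- s; break }
      }
    }
    rows <- list()
    for (i in seq_len(nIsodecoders)) {
      aa <- sub("-.*$", "", keys[i])
      ac <- sub("^.*-", "", keys[i])
      for (k in seq_len(nper[i])) {
        s <- base[i]
        if (k > 1L) {  # one internal substitution away from the first copy
          p <- sample(setdiff(5:(nchar(s) - 25L), 35:37), 1)
          substr(s, p, p) <- sample(setdiff(DNA_BASES, substr(s, p, p)), 1)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = sprintf("Syn_tRNA-%s-%s-%d-1", aa, ac, k),
          amino_acid = aa, anticodon = ac, sequence = s,
          is_spike_in = FALSE, stringsAsFactors = FALSE)
      }
    }
    genes <- do.call(rbind, rows)
    repeat {
      sp <- paste(sample(DNA_BASES, 73, replace = TRUE), collapse = "")
      dmin <- min(vapply(base, function(b) {
        o <- min(nchar(sp), nchar(b))
        hammingRaw(substr(sp, nchar(sp) - o + 1L, nchar(sp)),
                   substr(b, nchar(b) - o + 1L, nchar(b)))
      }, 1))
      if (dmin >= minSeparation) break
    }
    spikeIn <- data.frame(
      gene_id = "Synthetic_yeast_tRNA-Phe-GAA-1-1", amino_acid = "Phe",
      anticodon = "GAA", sequence = sp, is_spike_in = TRUE,
      stringsAsFactors = FALSE)
    list(genes = genes, spikeIn = spikeIn)
  })
}

#' Construct a ground-truth charging profile
#'
#' @param chargeFraction named numeric in [0, 1]; names are isodecoder keys.
#' @param abundance named numeric over the same keys; normalized to sum to
#'   1. Defaults to equal abundance.
#' @return a [ChargeProfile-class] object.
#' @export
chargeProfile <- function(chargeFraction, abundance = NULL) {
  if (is.null(abundance))
    abundance <- setNames(rep(1, length(chargeFraction)), names(chargeFraction))
  abundance <- abundance[names(chargeFraction)]
  abundance <- abundance / sum(abundance)
  new("ChargeProfile", chargeFraction = chargeFraction, abundance = abundance)
}

#' @rdname chargeProfile
#' @param profile a [ChargeProfile-class].
#' @export
chargeFractions <- function(profile) profile@chargeFraction

#' @rdname chargeProfile
#' @export
abundances <- function(profile) profile@abundance

#' Random charging profile over a reference
#'
#' Assigns each isodecoder a charge fraction drawn from \code{fractions}
#' (cycled, then shuffled) and an equal abundance; convenient for
#' parameter-recovery simulations.
#'
#' @param ref a [ChargeRefIndex-class].
#' @param fractions pool of true charge fractions to cycle over.
#' @param seed integer RNG seed.
#' @return a [ChargeProfile-class].
#' @export
simulateChargeProfile <- function(ref, fractions = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                  seed = 1) {
  keys <- isodecoderKeys(ref)
  withSeed(seed, {
    cf <- sample(rep_len(fractions, length(keys)))
  })
  chargeProfile(setNames(cf, keys))
}
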