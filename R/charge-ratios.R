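#' Per-isodecoder charge ratios from oxidized and control count tables
#'
#' Each isodecoder's count is divided by its own library's spike-in count
#' (the spike-in is added at a fixed amount per sample, so it absorbs both
#' sequencing depth and ligation-efficiency differences); the charge ratio
#' is the oxidized-to-control ratio of these normalized abundances,
#' clamped to [0, 1]. Isodecoders with fewer than \code{minControlReads}
#' control-library reads are reported with an absent ratio and a
#' \code{low_coverage} flag, the standard guard against quantifying an
#' isodecoder from a handful of reads. Library size is retained as a
#' QC covariate: a warning is emitted when the spike-in and library-size
#' scaling factors disagree by more than 3-fold between the two libraries.
#'
#' @param oxidized,control [AssignmentCounts-class] objects quantified
#'   against the same reference.
#' @param minControlReads minimum control-library reads for a reported
#'   ratio (default 100).
#' @param spikeFloor minimum spike-in count required in both libraries
#'   (default 100); below it no ratios are produced.
#' @return data.frame: isodecoder, oxidized_count, control_count,
#'   norm_oxidized, norm_control, raw_ratio, charge_ratio, flags
#'   (comma-separated subset of \code{low_coverage}, \code{clamped}).
#' @export
computeChargeRatios <- function(oxidized, control, minControlReads = 100L,
                                spikeFloor = 100L) {
  if (oxidized@spikeIn < spikeFloor || control@spikeIn < spikeFloor)
    stop("spike-in count below floor (", spikeFloor, "): oxidized=",
         oxidized@spikeIn, ", control=", control@spikeIn,
         "; normalization is unreliable, no ratios produced")
  # an isodecoder present in only one table counts 0 in the other
  keys <- union(names(oxidized@counts), names(control@counts))
  fill <- function(x) {
    out <- setNames(integer(length(keys)), keys)
    out[names(x)] <- x
    out
  }
  ox <- fill(oxidized@counts)
  ct <- fill(control@counts)
  fox <- oxidized@spikeIn / max(1L, oxidized@librarySize)
  fct <- control@spikeIn / max(1L, control@librarySize)
  if (max(fox / fct, fct / fox) > 3)
    warning("spike-in and library-size scaling factors disagree by more ",
            "than 3-fold between libraries; check spike-in input or depth")
  normOx <- ox / oxidized@spikeIn
  normCt <- ct / control@spikeIn
  raw <- ifelse(normCt > 0, normOx / normCt, NA_real_)
  low <- ct < minControlReads
  clamped <- !low & !is.na(raw) & raw > 1
  ratio <- pmin(raw, 1)
  ratio[low] <- NA_real_
  flags <- mapply(function(l, c) paste(c(if (l) "low_coverage",
                                         if (c) "clamped"), collapse = ","),
                  low, clamped)
  data.frame(isodecoder = keys, oxidized_count = as.integer(ox),
             control_count = as.integer(ct),
             norm_oxidized = as.numeric(normOx),
             norm_control = as.numeric(normCt),
             raw_ratio = as.numeric(raw), charge_ratio = as.numeric(ratio),
             flags = as.character(flags), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Charged fractions from qPCR Ct tables (spike-referenced ddCt)
#'
#' Within each sample the spike-in Ct is subtracted from the target Ct
#' (dCt = Ct_target - Ct_spike); the charged fraction for a matched
#' (replicate, target) pair of oxidized and non-oxidized arms is then
#' \code{base^(dCt_nonox - dCt_ox)}: the oxidized arm templates only the
#' charged molecules, the non-oxidized arm the total pool. Fractions above
#' 1 are clamped with a flag; an oxidized-arm Ct at the ceiling (no
#' amplification) yields fraction 0 with a flag.
#'
#' @param records data.frame with columns \code{replicate},
#'   \code{treatment} (\code{"oxidized"}/\code{"non_oxidized"}),
#'   \code{target}, \code{ct_target}, \code{ct_spike} and optionally
#'   \code{at_ceiling}.
#' @param base amplification base (default 2, i.e. 100% efficiency).
#' @param ceilingCt Ct treated as the no-amplification ceiling when no
#'   \code{at_ceiling} column is present (default 40).
#' @return data.frame: target, replicate, dct_oxidized, dct_non_oxidized,
#'   fraction, flags.
#' @export
qpcrChargedFraction <- function(records, base = 2, ceilingCt = 40) {
  needed <- c("replicate", "treatment", "target", "ct_target", "ct_spike")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(records$treatment %in% c("oxidized", "non_oxidized")))
    stop("treatment must be 'oxidized' or 'non_oxidized'")
  if (is.null(records$at_ceiling))
    records$at_ceiling <- records$ct_target >= ceilingCt
  records$dct <- records$ct_target - records$ct_spike
  keyOf <- function(d) paste(d$replicate, d$target, sep = "\r")
  ox <- records[records$treatment == "oxidized", ]
  nn <- records[records$treatment == "non_oxidized", ]
  if (anyDuplicated(keyOf(ox)) || anyDuplicated(keyOf(nn)) ||
      !setequal(keyOf(ox), keyOf(nn))) {
    orphan <- c(setdiff(keyOf(ox), keyOf(nn)), setdiff(keyOf(nn), keyOf(ox)))
    stop("records do not pair into one oxidized + one non-oxidized row per ",
         "(replicate, target)",
         if (length(orphan)) paste0("; unpaired: ",
                                    gsub("\r", "/", orphan[1])) else "")
  }
  nn <- nn[match(keyOf(ox), keyOf(nn)), ]
  frac <- base^(nn$dct - ox$dct)
  clamped <- frac > 1
  frac <- pmin(frac, 1)
  ceilinged <- ox$at_ceiling
  frac[ceilinged] <- 0
  flags <- mapply(function(cl, ce) paste(c(if (ce) "ceiling",
                                           if (cl && !ce) "clamped"),
                                         collapse = ","), clamped, ceilinged)
  data.frame(target = ox$target, replicate = ox$replicate,
             dct_oxidized = ox$dct, dct_non_oxidized = nn$dct,
             fraction = as.numeric(frac), flags = as.character(flags),
             base = base, row.names = NULL, stringsAsFactors = FALSE)
}
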