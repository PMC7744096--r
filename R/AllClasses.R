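#' @import methods
#' @importFrom stats aov ave rnorm runif setNames sd
NULL

#' ChargeRefIndex: a deduplicated, CCA-appended tRNA reference
#'
#' Central reference object for charge quantification. Gene sequences are
#' appended with the 3' CCA that marks the mature, ligatable end, identical
#' mature sequences are collapsed, and genes are grouped into isodecoders
#' (same amino acid and anticodon). A single foreign spike-in record (the
#' yeast tRNA-Phe role) is stored apart from the cellular isodecoder groups
#' and serves as the per-library internal standard.
#'
#' @slot genes data.frame with one row per input gene: \code{gene_id},
#'   \code{amino_acid}, \code{anticodon}, \code{isodecoder},
#'   \code{sequence} (genomic input), \code{mature} (CCA-appended) and
#'   \code{seq_id} (identifier of the deduplicated mature sequence).
#' @slot matureSeqs named character vector of unique mature sequences
#'   (names are \code{seq_id}s); every element ends in \code{"CCA"}.
#' @slot seqToGenes named list mapping each \code{seq_id} to the gene ids
#'   sharing that mature sequence.
#' @slot isodecoders data.frame summarising each isodecoder group:
#'   \code{key}, \code{amino_acid}, \code{anticodon}, \code{n_genes},
#'   \code{n_unique_sequences}.
#' @slot spikeIn one-row data.frame describing the spike-in gene, with the
#'   same columns as \code{genes}.
#'
#' @seealso [buildReference()], [parseTrnaFasta()]
#' @export
setClass("ChargeRefIndex", slots = c(
  genes = "data.frame",
  matureSeqs = "character",
  seqToGenes = "list",
  isodecoders = "data.frame",
  spikeIn = "data.frame"
))

setValidity("ChargeRefIndex", function(object) {
  msgs <- character()
  seqs <- object@matureSeqs
  if (!all(endsWith(seqs, "CCA")))
    msgs <- c(msgs, "every mature sequence must end in 'CCA'")
  if (anyDuplicated(seqs))
    msgs <- c(msgs, "mature sequences must be unique")
  if (anyDuplicated(object@genes$gene_id))
    msgs <- c(msgs, "gene ids must be unique")
  if (!identical(sort(names(object@seqToGenes)), sort(names(seqs))))
    msgs <- c(msgs, "seqToGenes keys must match matureSeqs names")
  key <- paste(object@genes$amino_acid, object@genes$anticodon, sep = "-")
  if (!identical(key, object@genes$isodecoder))
    msgs <- c(msgs, "each gene must belong to the isodecoder named by its amino acid and anticodon")
  if (nrow(object@spikeIn) != 1L)
    msgs <- c(msgs, "exactly one spike-in record is required")
  if (length(msgs)) msgs else TRUE
})

#' ChargeProfile: ground-truth per-isodecoder charging state
#'
#' Drives the library and qPCR simulators: for each isodecoder it records
#' the true charged proportion (the fraction of molecules carrying an amino
#' acid on their 3' CCA end, hence surviving periodate oxidation) and the
#' relative abundance of the isodecoder in the cellular tRNA pool.
#'
#' @slot chargeFraction named numeric in [0, 1], one entry per isodecoder.
#' @slot abundance named numeric, positive, summing to 1 over isodecoders.
#'
#' @seealso [chargeProfile()], [simulateReadLibrary()]
#' @export
setClass("ChargeProfile", slots = c(
  chargeFraction = "numeric",
  abundance = "numeric"
))

setValidity("ChargeProfile", function(object) {
  msgs <- character()
  cf <- object@chargeFraction
  ab <- object@abundance
  if (is.null(names(cf)) || is.null(names(ab)) ||
      !identical(sort(names(cf)), sort(names(ab))))
    msgs <- c(msgs, "chargeFraction and abundance must be named by the same isodecoder keys")
  if (any(cf < 0 | cf > 1)) msgs <- c(msgs, "charge fractions must lie in [0, 1]")
  if (any(ab <= 0)) msgs <- c(msgs, "abundances must be positive")
  if (abs(sum(ab) - 1) > 1e-6) msgs <- c(msgs, "abundances must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' AssignmentCounts: per-sample isodecoder read counts
#'
#' Output of [assignAndCount()]: reads per isodecoder plus the spike-in,
#' unassigned and cross-isodecoder-ambiguous tallies. The conservation
#' invariant (all tallies sum to the library size) is enforced by the
#' class validity method.
#'
#' @slot sampleId sample name.
#' @slot counts named integer vector, one entry per reference isodecoder.
#' @slot spikeIn integer count of spike-in reads.
#' @slot unassigned integer count of reads with no acceptable hit.
#' @slot ambiguous integer count of reads tied across >= 2 isodecoders.
#' @slot librarySize integer, total processed reads.
#'
#' @export
setClass("AssignmentCounts", slots = c(
  sampleId = "character",
  counts = "integer",
  spikeIn = "integer",
  unassigned = "integer",
  ambiguous = "integer",
  librarySize = "integer"
))

setValidity("AssignmentCounts", function(object) {
  msgs <- character()
  if (is.null(names(object@counts)))
    msgs <- c(msgs, "counts must be named by isodecoder key")
  tot <- sum(object@counts) + object@spikeIn + object@unassigned + object@ambiguous
  if (tot != object@librarySize)
    msgs <- c(msgs, sprintf(
      "status tallies (%d) must sum to librarySize (%d)", tot, object@librarySize))
  if (any(object@counts < 0) || object@spikeIn < 0 || object@unassigned < 0 ||
      object@ambiguous < 0)
    msgs <- c(msgs, "counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' ReporterConstruct: a polyQ / -1 frameshift reporter coding sequence
#'
#' A coding sequence starting with ATG whose features (insert region,
#' CAG-codon tract where present, GGGGSGGGGS-encoding linker, ATG-less
#' fluorescent-marker ORF, terminal stop) tile the sequence without
#' overlap. A recorded single-nucleotide deletion between the insert and
#' the linker places the marker in the -1 frame relative to the tract.
#'
#' @slot name construct name.
#' @slot sequence coding sequence (character, ACGT, starts with ATG).
#' @slot features data.frame with columns \code{feature}, \code{start},
#'   \code{end} (1-based, inclusive), tiling the sequence.
#' @slot deletionSite integer; 0 when no deletion, otherwise the position
#'   (in the parent, undeleted construct) of the removed nucleotide.
#'
#' @seealso [buildReporter()], [analyzeReadingFrames()]
#' @export
setClass("ReporterConstruct", slots = c(
  name = "character",
  sequence = "character",
  features = "data.frame",
  deletionSite = "integer"
))

setValidity("ReporterConstruct", function(object) {
  msgs <- character()
  if (!startsWith(object@sequence, "ATG"))
    msgs <- c(msgs, "construct must start with ATG")
  f <- object@features
  f <- f[order(f$start), , drop = FALSE]
  if (f$start[1] != 1L || f$end[nrow(f)] != nchar(object@sequence) ||
      (nrow(f) > 1 && any(f$start[-1] != f$end[-nrow(f)] + 1L)))
    msgs <- c(msgs, "features must tile the sequence without gaps or overlap")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ChargeRefIndex", function(object) {
  cat("ChargeRefIndex with", nrow(object@genes), "genes,",
      length(object@matureSeqs), "unique mature sequences,",
      nrow(object@isodecoders), "isodecoders\n")
  cat("spike-in:", object@spikeIn$gene_id, "\n")
})

setMethod("show", "ChargeProfile", function(object) {
  cat("ChargeProfile over", length(object@chargeFraction), "isodecoders\n")
  cat("charge fractions:", paste0(
    utils::head(names(object@chargeFraction), 4), "=",
    signif(utils::head(object@chargeFraction, 4), 2), collapse = ", "),
    if (length(object@chargeFraction) > 4) "..." else "", "\n")
})

setMethod("show", "AssignmentCounts", function(object) {
  cat("AssignmentCounts for sample", object@sampleId, "\n")
  cat(" library size:", object@librarySize,
      "| spike-in:", object@spikeIn,
      "| unassigned:", object@unassigned,
      "| ambiguous:", object@ambiguous, "\n")
  cat(" isodecoders with reads:", sum(object@counts > 0), "of",
      length(object@counts), "\n")
})

setMethod("show", "ReporterConstruct", function(object) {
  cat("ReporterConstruct", object@name, "(", nchar(object@sequence), "nt )\n")
  cat(" features:", paste(object@features$feature, collapse = ", "), "\n")
  if (object@deletionSite > 0L)
    cat(" single-nucleotide deletion at parent position", object@deletionSite, "\n")
})
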