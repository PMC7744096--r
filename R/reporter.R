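# Flexible GGGGSGGGGS linker (G = GGA/GGC alternating, S = TCA).
REPORTER_LINKER <- "GGAGGCGGAGGCTCAGGAGGCGGAGGCTCA"

# Post-tract flank (Pro-Asn-Ser-Gly). Chosen stop-free in frame 0 and in
# the -1 frame (including the codon spanning the last tract nucleotide),
# so a -1-shifted ribosome can traverse it; frame discrimination is done
# by the engineered stops at the start of the marker ORF instead.
REPORTER_FLANK3 <- "CCAAACTCAGGA"

# Marker ORF start (Val-Asn-Asp). Engineered so the marker region blocks
# both off frames early: read at +1 it immediately yields TAA, read at -1
# (entering after the linker's final A) it yields AGT AAA TGA.
MARKER_START <- "GTAAATGAT"

# Marker ORF terminal signature (Asp-Glu-Leu-Tyr-Lys, the C-terminal
# residues of common fluorescent-protein stand-ins).
MARKER_SIGNATURE <- "GACGAACTGTACAAG"

REPORTER_SEED <- 20210817L  # fixed: constructs are deterministic fixtures

# Sample n codons from `allowed`, rejecting any whose -1-frame codon
# (previous base + first two bases) is a stop; prevLast seeds the chain.
sampleCodons <- function(n, allowed, prevLast = NULL, checkMinus1 = FALSE) {
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      c <- sample(allowed, 1)
      if (!checkMinus1 || !(paste0(prevLast, substr(c, 1, 2)) %in% STOP_CODONS)) {
        out[i] <- c
        prevLast <- substr(c, 3, 3)
        break
      }
    }
  }
  out
}

allCodons <- function() {
  g <- expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

# Deterministic stand-in segments. The real exon-1, fluorescent-marker and
# luciferase sequences are not modeled; these synthetic segments carry the
# structural features the frame analysis needs.
reporterSegments <- function(polyqCodons) {
  codons <- allCodons()
  noStop <- setdiff(codons, STOP_CODONS)
  withSeed(REPORTER_SEED, {
    flank5 <- paste(sampleCodons(16, setdiff(noStop, c("CAA", "CAG"))),
                    collapse = "")
    markerBody <- paste(sampleCodons(42, setdiff(noStop, "ATG")),
                        collapse = "")
    nLuc <- (48 + 3 * polyqCodons + nchar(REPORTER_FLANK3)) / 3
    lucAllowed <- setdiff(noStop, c("CAA", "CAG"))
    lucCodons <- sampleCodons(nLuc - 1, lucAllowed, prevLast = "G",
                              checkMinus1 = TRUE)
    # the final codon straddles the deletion/slip boundary once the
    # construct loses its last nucleotide; a TA* start would create a
    # stop codon there
    lucCodons <- c(lucCodons,
                   sampleCodons(1, grep("^TA", lucAllowed, value = TRUE,
                                        invert = TRUE),
                                prevLast = substr(lucCodons[nLuc - 1], 3, 3),
                                checkMinus1 = TRUE))
    luc <- paste(lucCodons, collapse = "")
  })
  list(flank5 = flank5,
       marker = paste0(MARKER_START, markerBody, MARKER_SIGNATURE),
       luc = luc)
}

#' Build a polyQ / -1 frameshift reporter construct
#'
#' Three designs are supported. \code{polyq_gfp}: start codon, an
#' exon-1-like 5' flank, a pure (CAG)^n tract, a short 3' flank, a
#' GGGGSGGGGS-encoding linker and an ATG-codon-less marker ORF, all in
#' frame 0 — the marker is expressed by ordinary in-frame translation.
#' \code{polyq_minus1_gfp}: the same construct with one nucleotide deleted
#' between the tract and the linker, so the marker is reachable only via a
#' -1 ribosomal frameshift within the CAG tract (which reads the tract in
#' its (GCA)^n alanine frame). \code{luc_minus1_gfp}: the tract-containing
#' insert is replaced by a tract-free luciferase-like stand-in of equal
#' length whose -1 reading frame is engineered stop-free, with the same
#' deletion — the no-tract control for frameshift induction.
#'
#' A CAA interruption pattern may be supplied because the frameshift
#' mechanism is CAG-specific: \code{caaEvery = k} replaces every k-th CAG
#' codon with CAA.
#'
#' @param kind one of \code{"polyq_gfp"}, \code{"polyq_minus1_gfp"},
#'   \code{"luc_minus1_gfp"}.
#' @param polyqCodons number of glutamine codons in the tract (default 36,
#'   a mildly pathogenic huntingtin exon-1 length).
#' @param caaEvery optional integer; every \code{caaEvery}-th tract codon
#'   becomes CAA (default NULL: pure CAG).
#' @return a [ReporterConstruct-class].
#' @export
buildReporter <- function(kind = c("polyq_gfp", "polyq_minus1_gfp",
                                   "luc_minus1_gfp"),
                          polyqCodons = 36L, caaEvery = NULL) {
  kind <- match.arg(kind)
  stopifnot(polyqCodons >= 1)
  seg <- reporterSegments(polyqCodons)
  tractCodons <- rep("CAG", polyqCodons)
  if (!is.null(caaEvery)) {
    stopifnot(caaEvery >= 2)
    tractCodons[seq_along(tractCodons) %% caaEvery == 0] <- "CAA"
  }
  tract <- paste(tractCodons, collapse = "")

  feat <- function(names, widths) {
    end <- cumsum(widths)
    data.frame(feature = names, start = end - widths + 1L, end = end,
               stringsAsFactors = FALSE)
  }
  if (kind == "luc_minus1_gfp") {
    insert <- seg$luc
    parentWidths <- c(3L, nchar(insert), nchar(REPORTER_LINKER),
                      nchar(seg$marker), 3L)
    parentNames <- c("start_codon", "luc_insert", "linker", "marker",
                     "stop_codon")
    parent <- paste0("ATG", insert, REPORTER_LINKER, seg$marker, "TAA")
  } else {
    parentWidths <- c(3L, nchar(seg$flank5), nchar(tract),
                      nchar(REPORTER_FLANK3), nchar(REPORTER_LINKER),
                      nchar(seg$marker), 3L)
    parentNames <- c("start_codon", "exon1_flank_5", "polyq_tract",
                     "exon1_flank_3", "linker", "marker", "stop_codon")
    parent <- paste0("ATG", seg$flank5, tract, REPORTER_FLANK3,
                     REPORTER_LINKER, seg$marker, "TAA")
  }
  features <- feat(parentNames, parentWidths)

  if (kind == "polyq_gfp") {
    return(new("ReporterConstruct", name = kind, sequence = parent,
               features = features, deletionSite = 0L))
  }
  # single-nucleotide deletion immediately upstream of the linker
  del <- features$start[features$feature == "linker"] - 1L
  sequence <- paste0(substr(parent, 1L, del - 1L),
                     substr(parent, del + 1L, nchar(parent)))
  features$end[features$end >= del] <- features$end[features$end >= del] - 1L
  features$start[features$start > del] <- features$start[features$start > del] - 1L
  new("ReporterConstruct", name = kind, sequence = sequence,
      features = features, deletionSite = del)
}

#' Analyze the reading-frame outcomes of a reporter construct
#'
#' Simulates translation from the start codon in frame 0 and with a single
#' -1 or +1 ribosomal shift applied at the 3' end of the tract region (the
#' insert region for tract-free constructs): a -1 shift re-reads the last
#' tract nucleotide, a +1 shift skips the following one. A frame yields
#' the marker when translation reaches the marker ORF's final codon
#' without encountering a stop. The tract-region peptide is reported for
#' each frame (a pure CAG tract reads as polyglutamine in frame 0 and as
#' polyalanine — the (GCA)^n frame — at -1).
#'
#' @param construct a [ReporterConstruct-class].
#' @return list with \code{frames_yielding_marker} (integer subset of
#'   \code{c(0, -1, 1)}), \code{tract_peptides} (named character,
#'   \code{"0"}, \code{"-1"}, \code{"+1"}) and \code{premature_stops}
#'   (named integer, first in-construct stop position per frame, NA when
#'   none before the marker end).
#' @export
analyzeReadingFrames <- function(construct) {
  f <- construct@features
  if (!"marker" %in% f$feature) stop("construct has no marker feature")
  region <- if ("polyq_tract" %in% f$feature) "polyq_tract" else "luc_insert"
  rs <- f$start[f$feature == region]
  re <- f$end[f$feature == region]
  markerEnd <- f$end[f$feature == "marker"]
  seq <- construct@sequence
  L <- nchar(seq)

  frames <- c(0L, -1L, 1L)
  reach <- logical(3)
  stops <- rep(NA_integer_, 3)
  peptides <- character(3)
  for (i in seq_along(frames)) {
    fr <- frames[i]
    mrna <- switch(as.character(fr),
      "0"  = seq,
      "-1" = paste0(substr(seq, 1L, re), substr(seq, re, L)),
      "1"  = paste0(substr(seq, 1L, re), substr(seq, re + 2L, L)))
    markerEndM <- markerEnd + switch(as.character(fr), "0" = 0L,
                                     "-1" = 1L, "1" = -1L)
    prot <- translateDna(mrna)
    stopIdx <- regexpr("*", prot, fixed = TRUE)
    firstStopStart <- if (stopIdx > 0) 3L * (as.integer(stopIdx) - 1L) + 1L
                      else NA_integer_
    reach[i] <- is.na(firstStopStart) || firstStopStart > markerEndM
    if (!reach[i]) {
      # map back to construct coordinates past the shift point
      pos <- firstStopStart
      if (pos > re) pos <- pos - switch(as.character(fr), "0" = 0L,
                                        "-1" = 1L, "1" = -1L)
      stops[i] <- pos
    }
    pepStart <- rs + switch(as.character(fr), "0" = 0L, "-1" = -1L, "1" = 1L)
    peptides[i] <- translateDna(substr(seq, pepStart, re))
  }
  list(frames_yielding_marker = frames[reach],
       tract_peptides = setNames(peptides, c("0", "-1", "+1")),
       premature_stops = setNames(stops, c("0", "-1", "+1")))
}

#' Write a reporter construct as FASTA plus a feature table
#'
#' @param construct a [ReporterConstruct-class].
#' @param dir output directory (created): \code{construct.fasta} and
#'   \code{features.tsv} (1-based, inclusive coordinates).
#' @return dir, invisibly.
#' @export
writeReporter <- function(construct, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(construct@sequence, construct@name)),
    file.path(dir, "construct.fasta"))
  utils::write.table(construct@features, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
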