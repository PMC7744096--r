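#' Parse a GtRNAdb-style tRNA gene FASTA
#'
#' Each record header must contain a \code{tRNA-<AA>-<Anticodon>} token
#' (e.g. \code{Mus_musculus_tRNA-Gln-CTG-1-1}) from which the amino-acid
#' class and anticodon are extracted. Initiator methionine (\code{iMet})
#' and selenocysteine (\code{SeC}) class labels are kept distinct from the
#' standard three-letter codes, so \code{tRNA-iMet-CAT} and
#' \code{tRNA-Met-CAT} genes end up in different isodecoder groups.
#'
#' Records with an undetermined (\code{NNN}) anticodon or an
#' \code{Und}/undetermined amino-acid label, and records flagged as
#' pseudogenes, are dropped with a warning. Records whose headers mark an
#' intron are rejected: inputs are assumed to be mature or intron-less gene
#' sequences. \code{U} is silently converted to \code{T}; any other
#' character outside \code{ACGT} is an error.
#'
#' @param fasta path to a FASTA file (plain or gzip) or a character vector
#'   of FASTA text.
#' @return data.frame with columns \code{gene_id}, \code{amino_acid},
#'   \code{anticodon}, \code{sequence}, \code{is_spike_in} (all FALSE),
#'   one row per retained record, input order preserved.
#' @examples
#' fa <- c(">Mus_musculus_tRNA-Gln-CTG-1-1",
#'         paste(rep("GGTTCCATGGTGTAATGGTTAGCACTCTGGACTCTGAATCCAGCGATCCGAGTTCAAATCTCGG", 1), collapse = ""))
#' parseTrnaFasta(fa)
#' @export
parseTrnaFasta <- function(fasta) {
  set <- readFastaInput(fasta, "DNA")
  empty <- data.frame(gene_id = character(), amino_acid = character(),
                      anticodon = character(), sequence = character(),
                      is_spike_in = logical(), stringsAsFactors = FALSE)
  if (!length(set)) return(empty)
  headers <- names(set)
  if (any(grepl("intron", headers, ignore.case = TRUE)))
    stop("intron-containing records are not supported; supply mature or ",
         "intron-less gene sequences (offending record: ",
         headers[grepl("intron", headers, ignore.case = TRUE)][1], ")")
  m <- regmatches(headers, regexec("tRNA-([A-Za-z]{3,4})-([A-Za-z]{3})", headers))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop("header lacks a tRNA-<AA>-<Anticodon> token: ", headers[bad][1])
  aa <- vapply(m, `[`, "", 2L)
  ac <- toupper(vapply(m, `[`, "", 3L))
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  alien <- grepl("[^ACGT]", seqs)
  if (any(alien))
    stop("sequence contains characters outside ACGTU: ", headers[alien][1])
  gene_id <- vapply(strsplit(headers, "\\s+"), `[`, "", 1L)

  drop <- ac == "NNN" | tolower(aa) %in% c("und", "undet") |
    grepl("pseudo", headers, ignore.case = TRUE)
  if (any(drop)) {
    warning(sum(drop), " record(s) with undetermined anticodon or pseudogene ",
            "flag dropped: ", paste(utils::head(gene_id[drop], 3), collapse = ", "))
  }
  keep <- !drop
  out <- data.frame(gene_id = gene_id[keep], amino_acid = aa[keep],
                    anticodon = ac[keep], sequence = seqs[keep],
                    is_spike_in = FALSE, stringsAsFactors = FALSE)
  badlen <- nchar(out$sequence) < 60L | nchar(out$sequence) > 120L
  if (any(badlen))
    stop("tRNA gene sequence length outside [60, 120] nt: ", out$gene_id[badlen][1])
  rownames(out) <- NULL
  out
}

#' Build a CCA-appended, deduplicated isodecoder reference
#'
#' Appends the 3' CCA that defines the mature ligatable end, collapses
#' identical mature sequences, groups genes into isodecoders by
#' (amino acid, anticodon), and attaches the spike-in record. The spike-in
#' must be distinguishable from every cellular sequence at more than
#' \code{maxMismatches} mismatches under the 3'-anchored comparison used by
#' the aligner, otherwise spike-normalization would be corrupted.
#'
#' @param genes data.frame as returned by [parseTrnaFasta()].
#' @param spikeIn one-row data.frame (same columns) or a FASTA path/text
#'   containing a single record, the foreign spike-in (yeast tRNA-Phe role).
#' @param assumeGenomic logical; when TRUE (default) sequences are treated
#'   as genomic and CCA is appended unconditionally, even if a sequence
#'   already happens to end in CCA. When FALSE, CCA is appended only to
#'   sequences not already ending in CCA (pre-processed mature sets).
#' @param maxMismatches mismatch allowance the downstream aligner will use;
#'   the spike-in must exceed this distance from every reference sequence.
#' @return a [ChargeRefIndex-class] object.
#' @export
buildReference <- function(genes, spikeIn, assumeGenomic = TRUE,
                           maxMismatches = 1L) {
  if (is.character(spikeIn)) spikeIn <- parseTrnaFasta(spikeIn)
  stopifnot(is.data.frame(genes), is.data.frame(spikeIn))
  if (nrow(spikeIn) != 1L) stop("exactly one spike-in record is required")
  if (nrow(genes) < 1L) stop("at least one non-spike gene is required")
  dup <- duplicated(genes$gene_id) |
    genes$gene_id %in% spikeIn$gene_id
  if (any(dup))
    stop("duplicate gene_id: ", paste(unique(genes$gene_id[dup]), collapse = ", "))

  appendCca <- function(s) {
    if (assumeGenomic) paste0(s, "CCA")
    else ifelse(endsWith(s, "CCA"), s, paste0(s, "CCA"))
  }
  genes$mature <- appendCca(genes$sequence)
  spikeIn$mature <- appendCca(spikeIn$sequence)
  spikeIn$is_spike_in <- TRUE
  genes$isodecoder <- paste(genes$amino_acid, genes$anticodon, sep = "-")
  spikeIn$isodecoder <- paste(spikeIn$amino_acid, spikeIn$anticodon, sep = "-")

  # deduplicate mature sequences; seq ids are <isodecoder>.<k> of first carrier
  uniq <- !duplicated(genes$mature)
  useq <- genes$mature[uniq]
  ukey <- genes$isodecoder[uniq]
  seq_id <- paste0(ukey, ".", ave(seq_along(ukey), ukey, FUN = seq_along))
  names(useq) <- seq_id
  genes$seq_id <- seq_id[match(genes$mature, useq)]
  seqToGenes <- split(genes$gene_id, genes$seq_id)[seq_id]
  spikeIn$seq_id <- "spike_in.1"

  # spike-in distinguishability under the aligner's 3'-anchored comparison
  for (i in seq_along(useq)) {
    o <- min(nchar(useq[i]), nchar(spikeIn$mature))
    mm <- hammingRaw(substr(useq[i], nchar(useq[i]) - o + 1L, nchar(useq[i])),
                     substr(spikeIn$mature, nchar(spikeIn$mature) - o + 1L,
                            nchar(spikeIn$mature)))
    if (mm <= maxMismatches)
      stop("spike-in sequence is within ", maxMismatches,
           " mismatch(es) of reference sequence ", names(useq)[i],
           "; it would be indistinguishable from cellular tRNA")
  }

  isoSplit <- split(genes, genes$isodecoder)
  isodecoders <- data.frame(
    key = names(isoSplit),
    amino_acid = vapply(isoSplit, function(g) g$amino_acid[1], ""),
    anticodon = vapply(isoSplit, function(g) g$anticodon[1], ""),
    n_genes = vapply(isoSplit, nrow, 1L),
    n_unique_sequences = vapply(isoSplit, function(g) length(unique(g$mature)), 1L),
    stringsAsFactors = FALSE)
  rownames(isodecoders) <- NULL

  new("ChargeRefIndex", genes = genes, matureSeqs = useq,
      seqToGenes = seqToGenes, isodecoders = isodecoders, spikeIn = spikeIn)
}

#' Convert an anticodon to the codon it decodes
#'
#' Returns the reverse complement read 5'->3'; wobble decoding is not
#' modeled. For example the two glutamine isodecoder anticodons CTG and TTG
#' map to codons CAG and CAA.
#'
#' @param anticodon character vector of 3-mers over ACGT.
#' @return character vector of codons.
#' @examples
#' anticodonToCodon(c("CTG", "TTG"))  # CAG, CAA
#' @export
anticodonToCodon <- function(anticodon) {
  if (any(nchar(anticodon) != 3L) || any(grepl("[^ACGT]", anticodon)))
    stop("anticodon must be a 3-mer over ACGT")
  revComp(anticodon)
}

#' @rdname ChargeRefIndex-accessors
#' @name ChargeRefIndex-accessors
#' @title Accessors for ChargeRefIndex
#' @param ref a [ChargeRefIndex-class] object.
#' @return \code{refGenes}: the per-gene table; \code{matureSequences}: the
#'   named vector of unique mature sequences; \code{isodecoderKeys}: the
#'   isodecoder group keys; \code{isodecoderGroups}: the group summary
#'   table; \code{spikeInGene}: the one-row spike-in record.
NULL

#' @rdname ChargeRefIndex-accessors
#' @export
refGenes <- function(ref) ref@genes

#' @rdname ChargeRefIndex-accessors
#' @export
matureSequences <- function(ref) ref@matureSeqs

#' @rdname ChargeRefIndex-accessors
#' @export
isodecoderKeys <- function(ref) ref@isodecoders$key

#' @rdname ChargeRefIndex-accessors
#' @export
isodecoderGroups <- function(ref) ref@isodecoders

#' @rdname ChargeRefIndex-accessors
#' @export
spikeInGene <- function(ref) ref@spikeIn

#' Write / read a reference bundle directory
#'
#' The bundle holds \code{reference.fasta} (unique mature sequences, names
#' are sequence ids), \code{genes.tsv} (gene table) and
#' \code{spikein.fasta}; [readReference()] reconstructs the index.
#'
#' @param ref a [ChargeRefIndex-class] object.
#' @param dir directory to create/read.
#' @return \code{writeReference}: \code{dir}, invisibly.
#'   \code{readReference}: a [ChargeRefIndex-class].
#' @export
writeReference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(ref@matureSeqs), file.path(dir, "reference.fasta"))
  utils::write.table(ref@genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sp <- Biostrings::DNAStringSet(setNames(ref@spikeIn$sequence, ref@spikeIn$gene_id))
  Biostrings::writeXStringSet(sp, file.path(dir, "spikein.fasta"))
  invisible(dir)
}

#' @rdname writeReference
#' @param assumeGenomic passed to [buildReference()] when rebuilding.
#' @export
readReference <- function(dir, assumeGenomic = TRUE) {
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  spike <- parseTrnaFasta(file.path(dir, "spikein.fasta"))
  buildReference(genes[, c("gene_id", "amino_acid", "anticodon",
                           "sequence", "is_spike_in")],
                 spike, assumeGenomic = assumeGenomic)
}
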