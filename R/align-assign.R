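#' Align a read against the reference, 3'-anchored, ungapped
#'
#' The adaptor ligation chemistry fixes the molecule's 3' CCA end, so each
#' read is anchored at the 3' end of every mature reference sequence and
#' compared ungapped over the overlap, permitting 5' truncation of the
#' read. Hits within the mismatch allowance (default one mismatch, which
#' absorbs reverse-transcriptase misincorporation at methylated adenines)
#' and overlapping by at least 20 nt are returned best-first (fewest
#' mismatches, then longest overlap). \code{N} bases count as mismatches.
#'
#' @param seq read sequence (>= 20 nt).
#' @param ref a [ChargeRefIndex-class].
#' @param maxMismatches mismatch allowance (default 1).
#' @param minOverlap minimum read/reference overlap (default 20).
#' @return data.frame of gene-level hits: gene_id, seq_id, isodecoder
#'   (\code{"spike_in"} for the spike), mismatches, overlap. Zero rows when
#'   nothing matches.
#' @export
alignRead <- function(seq, ref, maxMismatches = 1L, minOverlap = 20L) {
  if (nchar(seq) < minOverlap)
    stop("read shorter than the minimum overlap (", minOverlap, " nt)")
  targets <- c(ref@matureSeqs, setNames(ref@spikeIn$mature, ref@spikeIn$seq_id))
  n <- nchar(seq)
  sr <- charToRaw(seq)
  hits <- vector("list", length(targets))
  k <- 0L
  for (i in seq_along(targets)) {
    t <- targets[i]
    nt <- nchar(t)
    o <- min(n, nt)
    if (o < minOverlap) next
    mm <- sum(sr[(n - o + 1L):n] != charToRaw(substr(t, nt - o + 1L, nt)))
    if (mm <= maxMismatches) {
      k <- k + 1L
      hits[[k]] <- data.frame(seq_id = names(targets)[i],
                              mismatches = mm, overlap = o,
                              stringsAsFactors = FALSE)
    }
  }
  if (!k)
    return(data.frame(gene_id = character(), seq_id = character(),
                      isodecoder = character(), mismatches = integer(),
                      overlap = integer(), stringsAsFactors = FALSE))
  h <- do.call(rbind, hits[seq_len(k)])
  h <- h[order(h$mismatches, -h$overlap), , drop = FALSE]
  spikeId <- ref@spikeIn$seq_id
  expand <- lapply(seq_len(nrow(h)), function(i) {
    sid <- h$seq_id[i]
    if (sid == spikeId) {
      data.frame(gene_id = ref@spikeIn$gene_id, seq_id = sid,
                 isodecoder = "spike_in", mismatches = h$mismatches[i],
                 overlap = h$overlap[i], stringsAsFactors = FALSE)
    } else {
      gids <- ref@seqToGenes[[sid]]
      data.frame(gene_id = gids, seq_id = sid,
                 isodecoder = ref@genes$isodecoder[match(gids, ref@genes$gene_id)],
                 mismatches = h$mismatches[i], overlap = h$overlap[i],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, expand)
  rownames(out) <- NULL
  out
}

# Classify one read's hit table into an assignment status.
classifyHits <- function(hits) {
  if (!nrow(hits))
    return(list(status = "unassigned", isodecoder = NA_character_))
  best <- hits[hits$mismatches == hits$mismatches[1] &
               hits$overlap == hits$overlap[1], , drop = FALSE]
  isos <- unique(best$isodecoder)
  if (identical(isos, "spike_in"))
    return(list(status = "spike_in", isodecoder = NA_character_))
  if (length(isos) > 1L)
    return(list(status = "multi_across_isodecoders", isodecoder = NA_character_))
  if (length(unique(best$gene_id)) == 1L)
    list(status = "unique_gene", isodecoder = isos)
  else
    list(status = "multi_within_isodecoder", isodecoder = isos)
}

#' Assign processed reads to isodecoders and tally counts
#'
#' Applies the multimapping policy: a read whose best hits all fall on one
#' gene is \code{unique_gene}; tied best hits confined to several gene
#' copies of a single isodecoder are \code{multi_within_isodecoder} and
#' still count toward that isodecoder; ties spanning two or more
#' isodecoders are \code{multi_across_isodecoders} and are excluded from
#' isodecoder counts (tallied as ambiguous); spike-in best hits are
#' \code{spike_in}; reads without an acceptable hit are
#' \code{unassigned}. Identical sequences are aligned once.
#'
#' @param processed data.frame from [preprocessReads()] (rows with status
#'   \code{"too_short"} are ignored), or any data.frame with a
#'   \code{sequence} column.
#' @param ref a [ChargeRefIndex-class].
#' @param sampleId sample name recorded in the counts object.
#' @param maxMismatches,minOverlap passed to [alignRead()].
#' @return list with \code{assignments} (data.frame: read_id, status,
#'   isodecoder) and \code{counts} (an [AssignmentCounts-class] whose
#'   tallies sum to the number of assigned reads).
#' @export
assignAndCount <- function(processed, ref, sampleId = "sample",
                           maxMismatches = 1L, minOverlap = 20L) {
  keys <- isodecoderKeys(ref)
  if (!is.null(processed$status))
    processed <- processed[processed$status == "ok", , drop = FALSE]
  if (is.null(processed$read_id) && nrow(processed))
    processed$read_id <- sprintf("read%d", seq_len(nrow(processed)))
  n <- nrow(processed)
  if (!n) {
    counts <- new("AssignmentCounts", sampleId = sampleId,
                  counts = setNames(integer(length(keys)), keys),
                  spikeIn = 0L, unassigned = 0L, ambiguous = 0L,
                  librarySize = 0L)
    return(list(assignments = data.frame(read_id = character(),
                                         status = character(),
                                         isodecoder = character(),
                                         stringsAsFactors = FALSE),
                counts = counts))
  }
  useq <- unique(processed$sequence)
  cls <- lapply(useq, function(s) classifyHits(alignRead(s, ref,
                                                         maxMismatches,
                                                         minOverlap)))
  status <- vapply(cls, `[[`, "", "status")[match(processed$sequence, useq)]
  iso <- vapply(cls, `[[`, "", "isodecoder")[match(processed$sequence, useq)]
  assignments <- data.frame(read_id = processed$read_id, status = status,
                            isodecoder = iso, stringsAsFactors = FALSE)
  isoCounts <- table(factor(iso[status %in% c("unique_gene",
                                              "multi_within_isodecoder")],
                            levels = keys))
  counts <- new("AssignmentCounts", sampleId = sampleId,
                counts = setNames(as.integer(isoCounts), keys),
                spikeIn = sum(status == "spike_in"),
                unassigned = sum(status == "unassigned"),
                ambiguous = sum(status == "multi_across_isodecoders"),
                librarySize = n)
  list(assignments = assignments, counts = counts)
}

#' @rdname AssignmentCounts-accessors
#' @name AssignmentCounts-accessors
#' @title Accessors for AssignmentCounts
#' @param x an [AssignmentCounts-class].
#' @return numeric/integer components of the counts object.
NULL

#' @rdname AssignmentCounts-accessors
#' @export
isodecoderCounts <- function(x) x@counts

#' @rdname AssignmentCounts-accessors
#' @export
spikeInCount <- function(x) x@spikeIn

#' @rdname AssignmentCounts-accessors
#' @export
librarySize <- function(x) x@librarySize

#' Write / read an assignment counts table
#'
#' Long-format TSV: sample, isodecoder, count plus the spike_in,
#' unassigned, ambiguous and library_size bookkeeping rows.
#' @param counts an [AssignmentCounts-class].
#' @param path TSV path.
#' @return \code{writeCounts}: path invisibly; \code{readCounts}: an
#'   [AssignmentCounts-class].
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(sample = counts@sampleId,
                   isodecoder = c(names(counts@counts), "spike_in",
                                  "unassigned", "ambiguous", "library_size"),
                   count = c(counts@counts, counts@spikeIn, counts@unassigned,
                             counts@ambiguous, counts@librarySize),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCounts
#' @export
readCounts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  special <- c("spike_in", "unassigned", "ambiguous", "library_size")
  iso <- df[!df$isodecoder %in% special, ]
  get <- function(k) as.integer(df$count[df$isodecoder == k])
  new("AssignmentCounts", sampleId = as.character(df$sample[1]),
      counts = setNames(as.integer(iso$count), iso$isodecoder),
      spikeIn = get("spike_in"), unassigned = get("unassigned"),
      ambiguous = get("ambiguous"), librarySize = get("library_size"))
}

#' Export assignments as SAM
#'
#' Minimal single-end SAM against the mature reference sequences (1-based
#' positions; the 3'-anchored overlap is reported as a simple match
#' CIGAR). Only reads with a best hit are emitted.
#'
#' @param processed data.frame from [preprocessReads()].
#' @param ref a [ChargeRefIndex-class].
#' @param path output SAM path.
#' @param maxMismatches,minOverlap passed to [alignRead()].
#' @return path, invisibly.
#' @export
writeSam <- function(processed, ref, path, maxMismatches = 1L,
                     minOverlap = 20L) {
  targets <- c(ref@matureSeqs, setNames(ref@spikeIn$mature, ref@spikeIn$seq_id))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(targets), nchar(targets)))
  ok <- processed[processed$status == "ok", , drop = FALSE]
  recs <- character()
  for (i in seq_len(nrow(ok))) {
    h <- alignRead(ok$sequence[i], ref, maxMismatches, minOverlap)
    if (!nrow(h)) next
    tlen <- nchar(targets[[h$seq_id[1]]])
    recs <- c(recs, sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                            ok$read_id[i], h$seq_id[1], tlen - h$overlap[1] + 1L,
                            h$overlap[1], ok$sequence[i], h$mismatches[1]))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
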