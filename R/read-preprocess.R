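#' Trim a 3' adaptor from a read
#'
#' Scans 5'->3' for the earliest position where the adaptor prefix matches
#' with at most one mismatch over the matched length, requiring at least
#' \code{minMatch} matched nucleotides (the full adaptor when more of the
#' read remains). Everything from the match start onward is removed.
#'
#' @param seq read sequence.
#' @param adaptor adaptor sequence to look for.
#' @param minMatch minimum matched prefix length (default 8).
#' @param maxMismatch mismatches allowed in the matched prefix (default 1).
#' @return trimmed sequence (possibly unchanged, possibly empty).
#' @export
trimAdaptor <- function(seq, adaptor, minMatch = 8L, maxMismatch = 1L) {
  n <- nchar(seq)
  na <- nchar(adaptor)
  if (n < minMatch) return(seq)
  sr <- charToRaw(seq)
  ar <- charToRaw(adaptor)
  for (i in 1:(n - minMatch + 1L)) {
    len <- min(na, n - i + 1L)
    if (sum(sr[i:(i + len - 1L)] != ar[1:len]) <= maxMismatch)
      return(substr(seq, 1L, i - 1L))
  }
  seq
}

# Merge two adaptor-trimmed mates laid out as: mate 1 anchored at the
# insert 5' end, reverse-complemented mate 2 anchored at the insert 3'
# end. Negative offsets (mate 2rc starting before mate 1: short inserts
# whose residual adaptor read-through was below the trimmable length) are
# allowed; overhangs outside the overlap on the adaptor side are dropped.
# Returns NULL when no acceptable overlap exists.
mergeMates <- function(m1, q1, m2rc, q2rc, minOverlap = 15L, maxMismatch = 2L) {
  n1 <- nchar(m1); n2 <- nchar(m2rc)
  if (n1 < minOverlap || n2 < minOverlap) return(NULL)
  r1 <- charToRaw(m1); r2 <- charToRaw(m2rc)
  best <- NULL
  for (d in (minOverlap - n2):(n1 - minOverlap)) {
    a <- max(0L, d)          # overlap start offset in mate 1
    b <- max(0L, -d)         # overlap start offset in mate 2rc
    o <- min(n1 - a, n2 - b)
    if (o < minOverlap) next
    mm <- sum(r1[(a + 1L):(a + o)] != r2[(b + 1L):(b + o)])
    if (mm <= maxMismatch && (is.null(best) || mm < best$mm ||
                              (mm == best$mm && o > best$o)))
      best <- list(a = a, b = b, o = o, mm = mm)
  }
  if (is.null(best)) return(NULL)
  a <- best$a; b <- best$b; o <- best$o
  ov1 <- substring(m1, a + 1L, a + o)
  ov2 <- substring(m2rc, b + 1L, b + o)
  if (best$mm > 0L) {
    b1 <- strsplit(ov1, "")[[1]]; b2 <- strsplit(ov2, "")[[1]]
    p1 <- utf8ToInt(substring(q1, a + 1L, a + o))
    p2 <- utf8ToInt(substring(q2rc, b + 1L, b + o))
    pick <- b1 != b2 & p2 > p1       # disagreements go to the higher quality
    b1[pick] <- b2[pick]
    ov1 <- paste(b1, collapse = "")
  }
  # mate 1 prefix before the overlap is insert sequence; anything after
  # mate 2rc's end is 3'-adaptor read-through (and vice versa), so the
  # merged read is prefix + consensus + mate 2rc tail.
  paste0(substr(m1, 1L, a), ov1,
         if (b + o < n2) substring(m2rc, b + o + 1L, n2) else "")
}

#' Preprocess one read pair: trim adaptors, merge mates
#'
#' Mate 1 is trimmed of 3'-adaptor read-through and mate 2 of RT-adaptor
#' read-through (each allowing one mismatch over a matched prefix of at
#' least 8 nt). Mates are merged when, with mate 2 reverse-complemented
#' and anchored at the insert 3' end, they overlap by at least 15 nt with
#' at most 2 disagreements; disagreements are resolved toward the
#' higher-quality base. When no acceptable overlap exists, mate 1 alone
#' is used. Reads shorter than 20 nt after processing are discarded.
#'
#' @param mate1,mate2 read sequences.
#' @param qual1,qual2 phred quality strings (same lengths as the mates).
#' @param adaptor3p adaptor trimmed from mate 1 (default [ADAPTOR_3P]).
#' @param adaptorRt adaptor trimmed from mate 2 (default [ADAPTOR_RT]).
#' @param minLength minimum retained length (default 20).
#' @return list with \code{sequence}, \code{source} ("merged" or
#'   "mate1_only") and \code{status} ("ok" or "too_short"; sequence is NA
#'   for discarded reads).
#' @export
preprocessReadPair <- function(mate1, mate2, qual1 = strrep("I", nchar(mate1)),
                               qual2 = strrep("I", nchar(mate2)),
                               adaptor3p = ADAPTOR_3P, adaptorRt = ADAPTOR_RT,
                               minLength = 20L) {
  stopifnot(nzchar(adaptor3p), nzchar(adaptorRt))
  t1 <- trimAdaptor(mate1, adaptor3p)
  t2 <- trimAdaptor(mate2, adaptorRt)
  q1 <- substr(qual1, 1L, nchar(t1))
  q2 <- substr(qual2, 1L, nchar(t2))
  m2rc <- if (nchar(t2)) revComp(t2) else ""
  q2rc <- paste(rev(strsplit(q2, "")[[1]]), collapse = "")
  merged <- if (nchar(t1) && nchar(m2rc))
    mergeMates(t1, q1, m2rc, q2rc) else NULL
  if (!is.null(merged)) {
    seq <- merged; src <- "merged"
  } else {
    seq <- t1; src <- "mate1_only"
  }
  if (nchar(seq) < minLength)
    return(list(sequence = NA_character_, source = src, status = "too_short"))
  list(sequence = seq, source = src, status = "ok")
}

#' Preprocess a table of read pairs
#'
#' Vectorised wrapper around [preprocessReadPair()]. Identical
#' (mate1, mate2, qualities) tuples are processed once and the result
#' fanned back out, which makes deeply duplicated tRNA libraries cheap.
#'
#' @param reads data.frame with columns \code{read_id}, \code{mate1},
#'   \code{mate2} and optionally \code{qual1}, \code{qual2} (constant Q40
#'   assumed when absent).
#' @param ... passed to [preprocessReadPair()].
#' @return data.frame: read_id, sequence, source, status; discarded reads
#'   keep their row with status \code{"too_short"}.
#' @export
preprocessReads <- function(reads, ...) {
  if (!nrow(reads))
    return(data.frame(read_id = character(), sequence = character(),
                      source = character(), status = character(),
                      stringsAsFactors = FALSE))
  if (is.null(reads$qual1)) reads$qual1 <- strrep("I", nchar(reads$mate1))
  if (is.null(reads$qual2)) reads$qual2 <- strrep("I", nchar(reads$mate2))
  key <- paste(reads$mate1, reads$mate2, reads$qual1, reads$qual2, sep = "\r")
  uk <- !duplicated(key)
  res <- Map(preprocessReadPair, reads$mate1[uk], reads$mate2[uk],
             reads$qual1[uk], reads$qual2[uk], MoreArgs = list(...))
  names(res) <- key[uk]
  res <- res[key]
  data.frame(read_id = reads$read_id,
             sequence = vapply(res, `[[`, "", "sequence"),
             source = vapply(res, `[[`, "", "source"),
             status = vapply(res, `[[`, "", "status"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read paired FASTQ files into the preprocessing input table
#'
#' @param r1,r2 FASTQ paths (plain or gzip).
#' @return data.frame with read_id, mate1, mate2, qual1, qual2.
#' @export
readFastqPairs <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(s1) != length(s2)) stop("mate files differ in record count")
  data.frame(read_id = sub("\\s.*$", "", names(s1)),
             mate1 = as.character(s1), mate2 = as.character(s2),
             qual1 = as.character(S4Vectors::mcols(s1)$qualities),
             qual2 = as.character(S4Vectors::mcols(s2)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}
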