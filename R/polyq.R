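AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "*", "U")

#' Scan a protein for polyglutamine tracts
#'
#' Returns all maximal uninterrupted runs of glutamine (Q) of at least
#' \code{minLen} residues, with 1-based start positions, ordered by
#' position. \code{X} (and any non-Q residue) breaks a tract.
#'
#' @param sequence amino-acid string over the 20-letter alphabet plus X
#'   (and optionally U and \code{*}).
#' @param minLen minimum tract length (default 10, the census criterion).
#' @return data.frame with columns \code{start}, \code{length}.
#' @examples
#' scanPolyQ(paste0("M", strrep("Q", 10), "A"))   # one tract: start 2, length 10
#' scanPolyQ(paste0("M", strrep("Q", 9), "A"))    # none
#' @export
scanPolyQ <- function(sequence, minLen = 10L) {
  if (!nchar(sequence))
    return(data.frame(start = integer(), length = integer()))
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    stop("illegal amino-acid character(s): ", paste(bad, collapse = ", "))
  r <- rle(chars == "Q")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minLen
  data.frame(start = starts[keep], length = r$lengths[keep],
             row.names = NULL)
}

#' Polyglutamine census over a protein set
#'
#' Scans every protein for tracts of at least \code{minLen} glutamines and
#' summarises the set: how many proteins carry at least one tract (each
#' protein counted once) and the overall glutamine residue fraction
#' (total Q divided by total residues).
#'
#' @param proteins protein FASTA path (plain or gzip), a named character
#'   vector, or a \code{Biostrings::AAStringSet}.
#' @param minLen minimum tract length (default 10).
#' @return list with \code{tracts} (data.frame: protein_id, start, length)
#'   and \code{summary} (data.frame: n_proteins, n_with_tract,
#'   q_fraction; \code{q_fraction} is NA for an empty set).
#' @export
polyqCensus <- function(proteins, minLen = 10L) {
  if (methods::is(proteins, "AAStringSet")) {
    seqs <- setNames(as.character(proteins), names(proteins))
  } else if (is.character(proteins) && !is.null(names(proteins))) {
    seqs <- proteins
  } else {
    set <- readFastaInput(proteins, "AA")
    seqs <- setNames(as.character(set),
                     vapply(strsplit(names(set), "\\s+"), `[`, "", 1L))
  }
  if (length(seqs) && anyDuplicated(names(seqs)))
    warning("duplicate protein identifiers; all records scanned: ",
            paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  tracts <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    t <- scanPolyQ(seqs[[i]], minLen)
    if (!nrow(t)) return(NULL)
    cbind(data.frame(protein_id = names(seqs)[i], stringsAsFactors = FALSE), t)
  }))
  if (is.null(tracts))
    tracts <- data.frame(protein_id = character(), start = integer(),
                         length = integer(), stringsAsFactors = FALSE)
  totalRes <- sum(nchar(seqs))
  qRes <- sum(vapply(seqs, function(s)
    sum(strsplit(toupper(s), "")[[1]] == "Q"), 1L))
  summary <- data.frame(
    n_proteins = length(seqs),
    n_with_tract = length(unique(tracts$protein_id)),
    q_fraction = if (totalRes > 0) qRes / totalRes else NA_real_)
  list(tracts = tracts, summary = summary)
}
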