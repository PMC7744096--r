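DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse-complement DNA strings
#'
#' Vectorised over a character vector; delegates to Biostrings.
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @keywords internal
revComp <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a DNA string with the standard genetic code
#'
#' Trailing bases short of a full codon are dropped; stops appear as "*".
#' @param x single DNA string.
#' @return single amino-acid string.
#' @keywords internal
translateDna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, 1L, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

# Run code with a private RNG stream without disturbing the caller's seed.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Read a FASTA input that may be a file path or raw FASTA text.
readFastaInput <- function(input, type = c("DNA", "AA")) {
  type <- match.arg(type)
  reader <- switch(type,
    DNA = Biostrings::readBStringSet,  # tolerate U; converted downstream
    AA  = Biostrings::readAAStringSet)
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    set <- reader(input)
  } else {
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf), add = TRUE)
    writeLines(input, tf)
    set <- reader(tf)
  }
  set
}

# Hamming mismatches between two equal-length character strings (raw bytes).
hammingRaw <- function(a, b) sum(charToRaw(a) != charToRaw(b))
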