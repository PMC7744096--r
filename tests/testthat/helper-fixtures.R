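# Deterministic hand-built fixtures used across test files. Sequences are
# synthetic tRNA-length strings; only their combinatorial structure matters.

# Six genes over four anticodons: two identical Gln-CTG copies (dedup),
# two distinct Gln-TTG copies, one Val-AAC, one iMet-CAT.
fixtureGenes <- function() {
  base <- function(seed, len = 70) {
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }
  s1 <- base(101); s2 <- base(202); s3 <- base(303, 72); s4 <- base(404, 68)
  s2b <- s2
  substr(s2b, 10, 10) <- if (substr(s2, 10, 10) == "A") "C" else "A"
  data.frame(
    gene_id = c("Fix_tRNA-Gln-CTG-1-1", "Fix_tRNA-Gln-CTG-1-2",
                "Fix_tRNA-Gln-TTG-1-1", "Fix_tRNA-Gln-TTG-2-1",
                "Fix_tRNA-Val-AAC-1-1", "Fix_tRNA-iMet-CAT-1-1"),
    amino_acid = c("Gln", "Gln", "Gln", "Gln", "Val", "iMet"),
    anticodon = c("CTG", "CTG", "TTG", "TTG", "AAC", "CAT"),
    sequence = c(s1, s1, s2, s2b, s3, s4),
    is_spike_in = FALSE, stringsAsFactors = FALSE)
}

fixtureSpike <- function() {
  set.seed(909)
  data.frame(gene_id = "Fix_yeast_tRNA-Phe-GAA-1-1", amino_acid = "Phe",
             anticodon = "GAA",
             sequence = paste(sample(c("A", "C", "G", "T"), 73,
                                     replace = TRUE), collapse = ""),
             is_spike_in = TRUE, stringsAsFactors = FALSE)
}

fixtureRef <- function() buildReference(fixtureGenes(), fixtureSpike())

fastaText <- function(ids, seqs) as.vector(rbind(paste0(">", ids), seqs))

# Independent exhaustive 3'-anchored Hamming-scan oracle, written with
# different primitives (strsplit vectors) than the package matcher.
oracleAlign <- function(seq, targets, maxMismatches = 1, minOverlap = 20) {
  s <- strsplit(seq, "")[[1]]
  rows <- list()
  for (nm in names(targets)) {
    t <- strsplit(targets[[nm]], "")[[1]]
    o <- min(length(s), length(t))
    if (o < minOverlap) next
    mm <- sum(rev(s)[1:o] != rev(t)[1:o])
    if (mm <= maxMismatches)
      rows[[length(rows) + 1]] <- data.frame(seq_id = nm, mismatches = mm,
                                             overlap = o,
                                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(seq_id = character(), mismatches = integer(),
                      overlap = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$mismatches, -out$overlap, out$seq_id), , drop = FALSE]
}

# Simulate one oxidized/control pair and quantify it through the full
# pipeline; returns the charge-ratio table.
runPipeline <- function(ref, profile, nPairs, seedOx, seedCtl,
                        spikeInFraction = 0.05, misincorporationRate = 0.05) {
  lo <- simulateReadLibrary(ref, profile, libraryParams(
    nPairs, treatment = "oxidized", spikeInFraction = spikeInFraction,
    misincorporationRate = misincorporationRate, seed = seedOx))
  lc <- simulateReadLibrary(ref, profile, libraryParams(
    nPairs, treatment = "control", spikeInFraction = spikeInFraction,
    misincorporationRate = misincorporationRate, seed = seedCtl))
  ao <- assignAndCount(preprocessReads(lo$reads), ref, "ox")
  ac <- assignAndCount(preprocessReads(lc$reads), ref, "ctl")
  computeChargeRatios(ao$counts, ac$counts)
}
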