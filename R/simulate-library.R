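# Printed adaptor sequences from the assay chemistry: the pre-adenylated
# DNA adaptor ligated to intact (charged, periodate-protected) tRNA 3' ends,
# and the phosphorylated adaptor ligated to the cDNA 3' end.
#' Library adaptor constants
#'
#' \code{ADAPTOR_3P} is ligated to the tRNA 3' CCA end; \code{ADAPTOR_RT}
#' to the cDNA 3' end (it flanks the tRNA 5' end on the sense strand as its
#' reverse complement). Mate 1 reads the sense strand and runs into
#' \code{ADAPTOR_3P}; mate 2 reads the antisense strand and runs into
#' \code{ADAPTOR_RT}.
#' @export
ADAPTOR_3P <- "TGGAATTCTCGGGTGCCAAGG"

#' @rdname ADAPTOR_3P
#' @export
ADAPTOR_RT <- "AGATCGGAAGAGCGTCGTGTAGGGA"

#' Simulation parameters for a sequencing library
#'
#' @param nReadPairs number of read pairs to emit (= ligated molecules;
#'   each ligated molecule yields exactly one read pair).
#' @param readLength read length in nt (default 75).
#' @param spikeInFraction fraction of ligatable molecules that are
#'   spike-in, in [0, 0.5).
#' @param misincorporationRate probability of a reverse-transcriptase
#'   substitution at each designated methylated-adenine position, in
#'   [0, 0.25].
#' @param modifiedPositions named list, gene_id -> integer vector of
#'   1-based positions on the mature sequence. \code{NULL} (default)
#'   applies the m1A58-mimicking rule: the 3'-most A within positions
#'   55-60 of the mature sequence, when present.
#' @param treatment \code{"oxidized"} (periodate-treated: only charged
#'   molecules retain a ligatable 3' end) or \code{"control"} (all
#'   molecules ligatable).
#' @param seed integer RNG seed.
#' @return list of validated parameters.
#' @export
libraryParams <- function(nReadPairs, readLength = 75L, spikeInFraction = 0.05,
                          misincorporationRate = 0,
                          modifiedPositions = NULL,
                          treatment = c("oxidized", "control"), seed = 1L) {
  treatment <- match.arg(treatment)
  stopifnot(nReadPairs > 0, readLength > 0,
            spikeInFraction >= 0, spikeInFraction < 0.5,
            misincorporationRate >= 0, misincorporationRate <= 0.25)
  list(nReadPairs = as.integer(nReadPairs), readLength = as.integer(readLength),
       spikeInFraction = spikeInFraction,
       misincorporationRate = misincorporationRate,
       modifiedPositions = modifiedPositions, treatment = treatment,
       seed = as.integer(seed))
}

#' Default methylated-adenine positions for a reference
#'
#' For each gene, the 3'-most A within positions 55-60 (1-based) of the
#' mature sequence, mimicking the near-universal m1A58 modification; genes
#' with no A in the window get no modified position.
#'
#' @param ref a [ChargeRefIndex-class].
#' @return named list gene_id -> integer vector (possibly empty).
#' @export
defaultModifiedPositions <- function(ref) {
  all <- rbind(ref@genes[, c("gene_id", "mature")],
               ref@spikeIn[, c("gene_id", "mature")])
  out <- lapply(all$mature, function(s) {
    win <- 55:min(60, nchar(s))
    hits <- win[substring(s, win, win) == "A"]
    if (length(hits)) max(hits) else integer(0)
  })
  setNames(out, all$gene_id)
}

#' Simulate an oxidized or control sequencing library
#'
#' Emulates the periodate-protection assay collapsed to its operative
#' logic: in the oxidized library a cellular molecule is ligatable with
#' probability equal to its isodecoder's true charge fraction (uncharged 3'
#' ends are destroyed by oxidation), in the control library every molecule
#' is ligatable, and spike-in molecules (added after the oxidation step)
#' are always ligatable. Molecules are drawn spike-in with probability
#' \code{spikeInFraction}, otherwise from a gene sampled proportionally to
#' isodecoder abundance (uniform across the genes of a group); draws are
#' repeated until \code{nReadPairs} ligated molecules are obtained, so the
#' truth table total always equals the number of emitted read pairs.
#' Reverse-transcriptase misincorporation substitutes a random different
#' base at each designated modified position with the configured rate.
#' Each ligated molecule yields exactly one 75-bp read pair: mate 1 reads
#' the sense strand from the mature 5' end into the 3' adaptor; mate 2
#' reads the antisense strand from the 3' CCA end into the (reverse
#' complement of the) RT adaptor. Base qualities are constant Q40.
#'
#' @param ref a [ChargeRefIndex-class].
#' @param profile a [ChargeProfile-class] whose keys cover the reference.
#' @param params a [libraryParams()] list.
#' @return list with \code{reads} (data.frame: read_id, mate1, mate2,
#'   qual1, qual2, gene_id, isodecoder, is_spike_in) and \code{truth}
#'   (data.frame: isodecoder, treatment, ligated_count; spike-in keyed
#'   \code{"spike_in"}).
#' @export
simulateReadLibrary <- function(ref, profile, params) {
  keys <- isodecoderKeys(ref)
  cf <- chargeFractions(profile)
  ab <- abundances(profile)
  missing <- setdiff(keys, names(cf))
  if (length(missing))
    stop("profile is missing reference isodecoder(s): ",
         paste(missing, collapse = ", "))
  genes <- ref@genes
  # per-gene sampling weight: isodecoder abundance split uniformly in-group
  w <- ab[genes$isodecoder] / as.numeric(table(genes$isodecoder)[genes$isodecoder])
  mod <- params$modifiedPositions
  if (is.null(mod)) mod <- defaultModifiedPositions(ref)

  n <- params$nReadPairs
  rl <- params$readLength
  a5 <- revComp(ADAPTOR_RT)
  inserts <- c(genes$mature, ref@spikeIn$mature)
  ampliconLen <- nchar(a5) + nchar(inserts) + nchar(ADAPTOR_3P)
  if (any(rl > ampliconLen))
    stop("readLength (", rl, ") exceeds the shortest amplicon (",
         min(ampliconLen), " nt)")
  gid <- c(genes$gene_id, ref@spikeIn$gene_id)
  giso <- c(genes$isodecoder, "spike_in")
  ligp <- if (params$treatment == "oxidized") c(cf[genes$isodecoder], 1) else
    rep(1, length(gid))
  nGene <- nrow(genes)

  withSeed(params$seed, {
    idx <- integer(0)
    while (length(idx) < n) {
      draw <- max(1000L, ceiling((n - length(idx)) * 1.5))
      isSpike <- runif(draw) < params$spikeInFraction
      gi <- ifelse(isSpike, nGene + 1L,
                   sample.int(nGene, draw, replace = TRUE, prob = w))
      keep <- runif(draw) < ligp[gi]
      idx <- c(idx, gi[keep])
    }
    idx <- idx[seq_len(n)]

    ins <- inserts[idx]
    # RT misincorporation at each gene's modified positions
    for (g in unique(idx)) {
      pos <- mod[[gid[g]]]
      if (is.null(pos) || !length(pos)) next
      at <- which(idx == g)
      for (p in pos) {
        hit <- at[runif(length(at)) < params$misincorporationRate]
        if (!length(hit)) next
        alt <- sample(setdiff(DNA_BASES, substr(inserts[g], p, p)),
                      length(hit), replace = TRUE)
        s <- ins[hit]
        substr(s, p, p) <- alt
        ins[hit] <- s
      }
    }

    mate1 <- substr(paste0(ins, ADAPTOR_3P), 1L, rl)
    sense5 <- paste0(a5, ins)
    mate2 <- revComp(substr(sense5, nchar(sense5) - rl + 1L, nchar(sense5)))
  })

  qual <- strrep("I", rl)
  reads <- data.frame(
    read_id = sprintf("mol%07d", seq_len(n)),
    mate1 = mate1, mate2 = mate2, qual1 = qual, qual2 = qual,
    gene_id = gid[idx], isodecoder = giso[idx],
    is_spike_in = idx > nGene, stringsAsFactors = FALSE)
  tallies <- table(factor(giso[idx], levels = c(keys, "spike_in")))
  truth <- data.frame(isodecoder = names(tallies),
                      treatment = params$treatment,
                      ligated_count = as.integer(tallies),
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Write a simulated library as paired FASTQ files
#'
#' @param library result of [simulateReadLibrary()].
#' @param r1,r2 output paths (gzip applied for a \code{.gz} suffix).
#' @return invisible c(r1, r2).
#' @export
writeLibraryFastq <- function(library, r1, r2) {
  reads <- library$reads
  writeOne <- function(seqs, quals, path) {
    x <- Biostrings::DNAStringSet(setNames(seqs, reads$read_id))
    q <- Biostrings::BStringSet(quals)
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                                compress = endsWith(path, ".gz"))
  }
  writeOne(reads$mate1, reads$qual1, r1)
  writeOne(reads$mate2, reads$qual2, r2)
  invisible(c(r1, r2))
}

#' qPCR simulation parameters
#'
#' @param amplificationBase per-cycle fold change; 2 means 100% efficiency.
#' @param ctNoiseSd Gaussian noise SD added to every Ct, in cycles.
#' @param baselineCt Ct of one unit of template, in cycles.
#' @param ceilingCt reported Ct for zero template (no-amplification
#'   ceiling), never infinity.
#' @param seed integer RNG seed.
#' @return list of validated parameters.
#' @export
qpcrParams <- function(amplificationBase = 2, ctNoiseSd = 0, baselineCt = 20,
                       ceilingCt = 40, seed = 1L) {
  stopifnot(amplificationBase > 1, amplificationBase <= 2, ctNoiseSd >= 0,
            ceilingCt > baselineCt)
  list(amplificationBase = amplificationBase, ctNoiseSd = ctNoiseSd,
       baselineCt = baselineCt, ceilingCt = ceilingCt, seed = as.integer(seed))
}

#' Simulate periodate-assay qPCR Ct tables
#'
#' For each replicate, treatment arm and target isodecoder, the target Ct
#' reflects the available template: abundance times charge fraction in the
#' oxidized arm (only charged molecules survive with ligatable ends),
#' abundance alone in the non-oxidized arm. The spike-in Ct reflects the
#' fixed spike amount. Gaussian noise is added to every Ct. Zero template
#' is reported at the configured ceiling Ct with a flag.
#'
#' @param profile a [ChargeProfile-class].
#' @param targets character vector of isodecoder keys (subset of profile).
#' @param params a [qpcrParams()] list.
#' @param nReplicates replicates per treatment arm.
#' @return data.frame: replicate, treatment ("oxidized"/"non_oxidized"),
#'   target, ct_target, ct_spike, at_ceiling.
#' @export
simulateQpcr <- function(profile, targets, params = qpcrParams(),
                         nReplicates = 3L) {
  cf <- chargeFractions(profile)
  ab <- abundances(profile)
  bad <- setdiff(targets, names(cf))
  if (length(bad)) stop("targets not in profile: ", paste(bad, collapse = ", "))
  grid <- expand.grid(replicate = seq_len(nReplicates),
                      treatment = c("oxidized", "non_oxidized"),
                      target = targets, stringsAsFactors = FALSE)
  template <- ifelse(grid$treatment == "oxidized",
                     ab[grid$target] * cf[grid$target], ab[grid$target])
  lb <- log(params$amplificationBase)
  withSeed(params$seed, {
    ct_target <- ifelse(template > 0,
                        params$baselineCt - log(template) / lb, params$ceilingCt)
    at_ceiling <- template <= 0
    ct_target <- ct_target + rnorm(nrow(grid), 0, params$ctNoiseSd)
    ct_spike <- params$baselineCt + rnorm(nrow(grid), 0, params$ctNoiseSd)
  })
  ct_target <- pmin(ct_target, params$ceilingCt)
  ct_target[at_ceiling] <- params$ceilingCt
  data.frame(grid, ct_target = as.numeric(ct_target),
             ct_spike = as.numeric(ct_spike), at_ceiling = at_ceiling,
             stringsAsFactors = FALSE)
}
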