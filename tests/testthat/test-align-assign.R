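ref <- fixtureRef()
targets <- c(matureSequences(ref),
             setNames(spikeInGene(ref)$mature, spikeInGene(ref)$seq_id))

test_that("identity, one-mismatch and two-mismatch reads behave per contract", {
  full <- unname(targets[1])
  h <- alignRead(full, ref)
  expect_equal(unique(h$seq_id), names(targets)[1])
  expect_equal(h$mismatches[1], 0)
  expect_equal(h$overlap[1], nchar(full))

  one <- full
  substr(one, 40, 40) <- setdiff(c("A", "C", "G", "T"), substr(full, 40, 40))[1]
  h1 <- alignRead(one, ref)
  expect_true(names(targets)[1] %in% h1$seq_id)
  expect_equal(min(h1$mismatches), 1)

  two <- one
  substr(two, 20, 20) <- setdiff(c("A", "C", "G", "T"), substr(full, 20, 20))[1]
  h2 <- alignRead(two, ref)
  expect_false(names(targets)[1] %in% h2$seq_id)

  # 5' truncation is permitted: a 3'-anchored suffix still aligns fully
  suf <- substring(full, 30)
  hs <- alignRead(suf, ref)
  expect_true(names(targets)[1] %in% hs$seq_id)
  expect_equal(hs$overlap[hs$seq_id == names(targets)[1]][1], nchar(suf))

  # N counts as a mismatch
  nn <- full
  substr(nn, 10, 10) <- "N"
  expect_equal(min(alignRead(nn, ref)$mismatches), 1)
  expect_error(alignRead("ACGTACGT", ref), "minimum overlap")
})

test_that("matcher agrees exactly with the exhaustive Hamming-scan oracle", {
  set.seed(1234)
  synth <- simulateReference(15, genesPerIsodecoder = 2, seed = 99)
  bigRef <- buildReference(synth$genes, synth$spikeIn)
  tg <- c(matureSequences(bigRef),
          setNames(spikeInGene(bigRef)$mature, spikeInGene(bigRef)$seq_id))
  mats <- unname(tg)
  for (i in 1:400) {
    kind <- sample(3, 1)
    if (kind == 1) {          # clean or truncated reference read
      s <- sample(mats, 1)
      s <- substring(s, sample(1:(nchar(s) - 25), 1))
    } else if (kind == 2) {   # mutated reference read (0-3 substitutions)
      s <- sample(mats, 1)
      for (k in seq_len(sample(0:3, 1))) {
        p <- sample(nchar(s), 1)
        substr(s, p, p) <- sample(c("A", "C", "G", "T", "N"), 1)
      }
    } else {                  # random sequence
      s <- paste(sample(c("A", "C", "G", "T"), sample(20:100, 1),
                        replace = TRUE), collapse = "")
    }
    got <- alignRead(s, bigRef)
    want <- oracleAlign(s, tg)
    gotSeq <- unique(got[, c("seq_id", "mismatches", "overlap")])
    gotSeq <- gotSeq[order(gotSeq$mismatches, -gotSeq$overlap, gotSeq$seq_id), ]
    rownames(gotSeq) <- rownames(want) <- NULL
    expect_equal(gotSeq, want)
  }
})

test_that("multimapping policy: within-isodecoder kept, cross-isodecoder discarded", {
  genes <- refGenes(ref)
  # read from the shared Gln-CTG sequence: two gene copies, one isodecoder
  shared <- genes$mature[genes$gene_id == "Fix_tRNA-Gln-CTG-1-1"]
  res <- assignAndCount(data.frame(sequence = shared,
                                   stringsAsFactors = FALSE), ref)
  expect_equal(res$assignments$status, "multi_within_isodecoder")
  expect_equal(res$assignments$isodecoder, "Gln-CTG")
  expect_equal(unname(isodecoderCounts(res$counts)["Gln-CTG"]), 1L)

  # the two distinct Gln-TTG copies differ at one position: a read from
  # one copy hits it at 0 mm and its sibling at 1 mm -> strictly better
  # hit wins, unique assignment
  ttg <- genes$mature[genes$gene_id == "Fix_tRNA-Gln-TTG-1-1"]
  res2 <- assignAndCount(data.frame(sequence = ttg, stringsAsFactors = FALSE),
                         ref)
  expect_equal(res2$assignments$status, "unique_gene")
  expect_equal(res2$assignments$isodecoder, "Gln-TTG")

  # spike-derived read never contributes to any isodecoder
  res3 <- assignAndCount(data.frame(sequence = spikeInGene(ref)$mature,
                                    stringsAsFactors = FALSE), ref)
  expect_equal(res3$assignments$status, "spike_in")
  expect_equal(sum(isodecoderCounts(res3$counts)), 0L)
  expect_equal(spikeInCount(res3$counts), 1L)

  # a read tying two isodecoders is ambiguous and excluded from counts
  g <- fixtureGenes()[c(3, 5), ]
  g$sequence[2] <- g$sequence[1]          # same sequence, two isodecoders
  ref2 <- buildReference(g, fixtureSpike())
  amb <- assignAndCount(data.frame(sequence = paste0(g$sequence[1], "CCA"),
                                   stringsAsFactors = FALSE), ref2)
  expect_equal(amb$assignments$status, "multi_across_isodecoders")
  expect_equal(sum(isodecoderCounts(amb$counts)), 0L)
  expect_equal(amb$counts@ambiguous, 1L)
})

test_that("status tallies always sum to library size (conservation)", {
  keys <- isodecoderKeys(ref)
  prof <- chargeProfile(setNames(c(0.3, 0.6, 0.8, 1), keys))
  for (seed in c(2, 17)) {
    lib <- simulateReadLibrary(ref, prof, libraryParams(
      800, treatment = "oxidized", spikeInFraction = 0.08,
      misincorporationRate = 0.1, seed = seed))
    pp <- preprocessReads(lib$reads)
    res <- assignAndCount(pp, ref)
    ct <- res$counts
    expect_equal(sum(isodecoderCounts(ct)) + spikeInCount(ct) +
                 ct@unassigned + ct@ambiguous, librarySize(ct))
    expect_true(validObject(ct))
  }
  # empty input is an empty count table, not an error
  e <- assignAndCount(data.frame(sequence = character(),
                                 stringsAsFactors = FALSE), ref)
  expect_equal(librarySize(e$counts), 0L)
})

test_that("one misincorporation at a modified position does not change the assignment", {
  genes <- refGenes(ref)
  mod <- defaultModifiedPositions(ref)
  for (i in seq_len(nrow(genes))) {
    clean <- genes$mature[i]
    p <- mod[[genes$gene_id[i]]]
    if (!length(p)) next
    dirty <- clean
    substr(dirty, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(clean, p, p))[1]
    a1 <- assignAndCount(data.frame(sequence = clean,
                                    stringsAsFactors = FALSE), ref)
    a2 <- assignAndCount(data.frame(sequence = dirty,
                                    stringsAsFactors = FALSE), ref)
    expect_equal(a2$assignments$isodecoder, a1$assignments$isodecoder)
  }
})

test_that("noise-free simulator output is assigned perfectly end-to-end", {
  synth <- simulateReference(8, genesPerIsodecoder = 2, minSeparation = 3,
                             seed = 55)
  cleanRef <- buildReference(synth$genes, synth$spikeIn)
  keys <- isodecoderKeys(cleanRef)
  prof <- chargeProfile(setNames(rep(0.7, length(keys)), keys))
  lib <- simulateReadLibrary(cleanRef, prof, libraryParams(
    2000, treatment = "oxidized", spikeInFraction = 0.05,
    misincorporationRate = 0, seed = 6))
  pp <- preprocessReads(lib$reads)
  res <- assignAndCount(pp, cleanRef)
  expect_equal(res$counts@unassigned, 0L)
  expect_equal(res$counts@ambiguous, 0L)
  merged <- merge(res$assignments, lib$reads[, c("read_id", "isodecoder",
                                                 "is_spike_in")],
                  by = "read_id")
  nonSpike <- merged[!merged$is_spike_in, ]
  expect_equal(nonSpike$isodecoder.x, nonSpike$isodecoder.y)
  expect_equal(sum(merged$is_spike_in),
               sum(merged$status == "spike_in"))
})

test_that("counts tables round-trip through TSV and SAM export is well-formed", {
  keys <- isodecoderKeys(ref)
  prof <- chargeProfile(setNames(rep(0.5, 4), keys))
  lib <- simulateReadLibrary(ref, prof, libraryParams(60, seed = 9,
                                                      treatment = "control"))
  pp <- preprocessReads(lib$reads)
  res <- assignAndCount(pp, ref, sampleId = "s1")
  tf <- tempfile(fileext = ".tsv")
  writeCounts(res$counts, tf)
  back <- readCounts(tf)
  expect_equal(isodecoderCounts(back), isodecoderCounts(res$counts))
  expect_equal(librarySize(back), librarySize(res$counts))

  sam <- tempfile(fileext = ".sam")
  writeSam(pp, ref, sam)
  lines <- readLines(sam)
  expect_true(any(startsWith(lines, "@SQ")))
  recs <- lines[!startsWith(lines, "@")]
  expect_equal(length(recs), 60L)
  pos <- as.integer(vapply(strsplit(recs, "\t"), `[`, "", 4))
  expect_true(all(pos >= 1))
})
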