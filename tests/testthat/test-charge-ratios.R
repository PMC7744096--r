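mkCounts <- function(sample, counts, spike, librarySize = NULL,
                     unassigned = 0L, ambiguous = 0L) {
  counts <- setNames(as.integer(counts), names(counts))
  if (is.null(librarySize))
    librarySize <- sum(counts) + spike + unassigned + ambiguous
  new("AssignmentCounts", sampleId = sample, counts = counts,
      spikeIn = as.integer(spike), unassigned = as.integer(unassigned),
      ambiguous = as.integer(ambiguous), librarySize = as.integer(librarySize))
}

test_that("charge ratios recover hand-computed spike-normalized values", {
  ox <- mkCounts("ox", c(A = 500L, B = 0L, C = 300L), 10000L)
  ct <- mkCounts("ct", c(A = 500L, B = 1000L, C = 450L), 10000L)
  # identical normalized abundances -> ratio 1
  r <- computeChargeRatios(ox, ct)
  expect_equal(r$charge_ratio[r$isodecoder == "A"], 1.0)
  # zero oxidized reads -> fully uncharged
  expect_equal(r$charge_ratio[r$isodecoder == "B"], 0.0)

  # differing spike counts: (300/10000) / (450/15000) = 0.03/0.03 = 1
  ct2 <- mkCounts("ct", c(A = 500L, B = 1000L, C = 450L), 15000L)
  r2 <- suppressWarnings(computeChargeRatios(ox, ct2))
  expect_equal(r2$norm_oxidized[r2$isodecoder == "C"], 0.03)
  expect_equal(r2$norm_control[r2$isodecoder == "C"], 0.03)
  expect_equal(r2$charge_ratio[r2$isodecoder == "C"], 1.0)
})

test_that("ratios above 1 are clamped with a flag, raw value preserved", {
  ox <- mkCounts("ox", c(A = 1200L), 10000L)
  ct <- mkCounts("ct", c(A = 1000L), 10000L)
  r <- computeChargeRatios(ox, ct)
  expect_equal(r$charge_ratio, 1.0)
  expect_equal(r$raw_ratio, 1.2)
  expect_match(r$flags, "clamped")
})

test_that("low-coverage isodecoders are excluded like the low-read IleGAT case", {
  ox <- mkCounts("ox", c(A = 2000L, IleGAT = 3L), 10000L)
  ct <- mkCounts("ct", c(A = 2000L, IleGAT = 40L), 10000L)
  r <- computeChargeRatios(ox, ct, minControlReads = 100)
  expect_true(is.na(r$charge_ratio[r$isodecoder == "IleGAT"]))
  expect_match(r$flags[r$isodecoder == "IleGAT"], "low_coverage")
  expect_false(is.na(r$charge_ratio[r$isodecoder == "A"]))
  # configurable threshold
  r2 <- computeChargeRatios(ox, ct, minControlReads = 10)
  expect_false(is.na(r2$charge_ratio[r2$isodecoder == "IleGAT"]))
})

test_that("spike-in floor and scaling-concordance guards fire", {
  ox <- mkCounts("ox", c(A = 500L), 50L)
  ct <- mkCounts("ct", c(A = 500L), 10000L)
  expect_error(computeChargeRatios(ox, ct), "floor")
  # >3-fold disagreement between spike factor and library size factor warns
  oxBig <- mkCounts("ox", c(A = 500L), 10000L, librarySize = 100000L,
                    unassigned = 89500L)
  ctEq <- mkCounts("ct", c(A = 500L), 10000L)
  expect_warning(computeChargeRatios(oxBig, ctEq), "3-fold")
})

test_that("qPCR charged fractions follow the spike-referenced ddCt closed form", {
  rec <- data.frame(
    replicate = c(1, 1), treatment = c("oxidized", "non_oxidized"),
    target = "Gln-CTG",
    ct_target = c(26.1, 24.0), ct_spike = c(19.8, 20.1))
  out <- qpcrChargedFraction(rec)
  # dCt_ox = 6.3, dCt_nonox = 3.9 -> 2^(3.9 - 6.3) = 2^-2.4
  expect_equal(out$fraction, 2^-2.4, tolerance = 1e-12)

  eq <- data.frame(replicate = 1, treatment = c("oxidized", "non_oxidized"),
                   target = "t", ct_target = c(25, 25), ct_spike = c(20, 20))
  expect_equal(qpcrChargedFraction(eq)$fraction, 1.0)

  half <- data.frame(replicate = 1, treatment = c("oxidized", "non_oxidized"),
                     target = "t", ct_target = c(26, 25), ct_spike = c(20, 20))
  expect_equal(qpcrChargedFraction(half)$fraction, 0.5)

  # apparent fraction > 1 clamps with a flag
  over <- data.frame(replicate = 1, treatment = c("oxidized", "non_oxidized"),
                     target = "t", ct_target = c(24.5, 25), ct_spike = c(20, 20))
  o <- qpcrChargedFraction(over)
  expect_equal(o$fraction, 1.0)
  expect_match(o$flags, "clamped")

  # oxidized arm at the ceiling -> fraction 0 with a flag
  ceil <- data.frame(replicate = 1, treatment = c("oxidized", "non_oxidized"),
                     target = "t", ct_target = c(40, 25), ct_spike = c(20, 20))
  cc <- qpcrChargedFraction(ceil)
  expect_equal(cc$fraction, 0)
  expect_match(cc$flags, "ceiling")

  # unpaired record is named in the error
  unp <- rec[1, ]
  expect_error(qpcrChargedFraction(unp), "unpaired")
})

test_that("noise-free simulated Ct tables invert exactly to the true fractions", {
  keys <- paste0("iso", 1:5)
  cf <- setNames(c(0.05, 0.25, 0.5, 0.75, 0.95), keys)
  prof <- chargeProfile(cf)
  q <- simulateQpcr(prof, keys, qpcrParams(ctNoiseSd = 0), nReplicates = 3)
  out <- qpcrChargedFraction(q)
  expect_equal(out$fraction, unname(cf[out$target]), tolerance = 1e-9)
})

test_that("noisy qPCR estimates stay accurate with replication", {
  keys <- paste0("iso", 1:5)
  cf <- setNames(c(0.05, 0.25, 0.5, 0.75, 0.95), keys)
  prof <- chargeProfile(cf)
  q <- simulateQpcr(prof, keys, qpcrParams(ctNoiseSd = 0.2, seed = 14),
                    nReplicates = 4)
  out <- qpcrChargedFraction(q)
  # the per-target estimate is the mean over the four replicates; this is
  # where replication buys accuracy back from the Ct noise
  est <- tapply(out$fraction, out$target, mean)
  mae <- mean(abs(est[keys] - cf))
  expect_lt(mae, 0.08)
})

test_that("estimated charge ratio is monotone in the true fraction (in expectation)", {
  synth <- simulateReference(6, seed = 44)
  ref <- buildReference(synth$genes, synth$spikeIn)
  keys <- isodecoderKeys(ref)
  grid <- c(0.15, 0.45, 0.75)
  nSeeds <- 10
  est <- matrix(NA_real_, nSeeds, length(grid))
  cfBase <- setNames(rep(0.5, length(keys)), keys)
  for (s in seq_len(nSeeds)) {
    # the control library does not depend on charge fractions, so one per
    # seed is shared across the whole fraction grid
    lc <- simulateReadLibrary(ref, chargeProfile(cfBase), libraryParams(
      4000, treatment = "control", seed = 1000 + s))
    ac <- assignAndCount(preprocessReads(lc$reads), ref, "ctl")
    for (g in seq_along(grid)) {
      cf <- cfBase
      cf[keys[1]] <- grid[g]
      lo <- simulateReadLibrary(ref, chargeProfile(cf), libraryParams(
        4000, treatment = "oxidized", seed = 2000 + s * 10 + g))
      ao <- assignAndCount(preprocessReads(lo$reads), ref, "ox")
      r <- computeChargeRatios(ao$counts, ac$counts, minControlReads = 10,
                               spikeFloor = 50)
      est[s, g] <- r$charge_ratio[r$isodecoder == keys[1]]
    }
  }
  m <- colMeans(est)
  expect_true(all(diff(m) > 0))
})
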