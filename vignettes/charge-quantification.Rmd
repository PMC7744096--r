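---
title: "Quantifying tRNA charging from periodate-protection sequencing"
author: "ChargeSeq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tRNA charging from periodate-protection sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChargeSeq)
```

## The assay and its operative logic

A tRNA is "charged" when an amino acid is esterified to its 3'-terminal
CCA. Sodium periodate destroys the 2',3'-diol of a *free* 3' ribose, so
after periodate treatment only charged tRNAs retain a ligatable 3' end;
an untreated aliquot of the same sample retains all of them. Ligating a
DNA adaptor to the surviving 3' ends and quantifying the ligation
products therefore measures the charged pool (oxidized arm) against the
total pool (control arm). A fixed amount of foreign yeast
phenylalanine tRNA is added to every sample after the oxidation step and
before ligation; because it is always ligatable and is added at constant
mass, it serves as the internal standard that absorbs differences in
ligation efficiency and sequencing depth between libraries.

ChargeSeq collapses the wet chemistry between oxidation and ligation
(glucose quench, alkaline deacylation) into that operative rule: in the
oxidized library a cellular molecule is sampled into the sequencing pool
with probability equal to its isodecoder's true charged fraction; in the
control library with probability one; spike-in molecules always. This is
the assay's logic once every surviving 3' end ligates equally, and it is
what makes the estimator below consistent.

The unit of quantification is the **isodecoder**: the set of tRNA genes
sharing an anticodon (and an amino-acid class; initiator Met is kept
apart from elongator Met). Gene copies within an isodecoder are often
identical or one substitution apart, so reads cannot always be placed on
a single gene — but they can almost always be placed on a single
isodecoder, which is the resolution at which charging is biologically
read out (e.g. the two glutamine isodecoders decode CAG and CAA).

## The estimators

**Sequencing (charge ratio).** For one oxidized and one control library
quantified against the same reference,

$$\widehat{f}_i \;=\;
\frac{c^{\mathrm{ox}}_i / s^{\mathrm{ox}}}{c^{\mathrm{ctl}}_i / s^{\mathrm{ctl}}}$$

where $c_i$ is the isodecoder's read count and $s$ the spike-in count of
the same library. Because the spike is added at fixed amount per sample,
its expected share of the *control* pool is a constant, while the
oxidized pool is depleted of uncharged molecules; the two spike
normalizations cancel the library-specific ligation/depth factors and
the ratio converges to the true charged fraction $f_i$. Ratios are
clamped to [0, 1] (sampling noise can push them slightly above 1; the
raw value is kept alongside with a `clamped` flag). Isodecoders with
fewer than `minControlReads` (default 100) control reads are reported
absent with a `low_coverage` flag — the guard that keeps a low-read
isodecoder (an isoleucine isodecoder, in typical mouse libraries) from
being quantified off a handful of reads. Library size is kept
as a QC covariate: when the spike-in and library-size scaling factors
disagree more than 3-fold between the two libraries a warning is
emitted, since that pattern suggests a spike-in pipetting or depth
problem rather than biology.

**qPCR (ddCt charged fraction).** Within each sample the spike Ct is
subtracted from the target Ct ($\Delta Ct$); for a matched replicate the
charged fraction is $b^{\Delta Ct_{\mathrm{nonox}} - \Delta
Ct_{\mathrm{ox}}}$ with amplification base $b$ (default 2, i.e. 100%
efficiency; per-primer efficiencies can be supplied). One cycle of
difference corresponds to a fraction of one half. The spike subtraction
happens within-sample *before* the cross-treatment comparison. A Ct at
the no-amplification ceiling (default 40) in the oxidized arm yields
fraction 0 with a flag, never an infinity. Replicates are estimated
individually; the per-target estimate used downstream is their mean,
which is where replication buys accuracy back from Ct noise.

**Group comparisons.** Charged fractions across conditions are compared
with a paired Student's t test (two conditions measured on the same
biological replicates) or a one-way ANOVA followed by pairwise
pooled-variance t tests with Holm–Šidák step-down adjustment
($p^{adj}_{(i)} = \max_{j \le i}\, 1-(1-p_{(j)})^{m-j+1}$). The
step-down Šidák procedure is implemented in the package because base R's
`p.adjust` offers Holm–Bonferroni but not the Šidák variant. A paired
design with zero variance of differences is degenerate for the t
statistic: all-zero differences report $t = 0,\ p = 1$; a constant
non-zero difference is flagged `zero_variance` with p reported as the
smallest positive double rather than a fabricated statistic.

## Read model and assignment

Amplicons are the mature (CCA-appended) tRNA flanked by the two library
adaptors. Sequencing primers anneal inside the adaptors, so mate 1 reads
the sense strand from the mature 5' end and runs into the 3' adaptor
(`TGGAATTCTCGGGTGCCAAGG`), and mate 2 reads the antisense strand from
the CCA end and runs into the RT adaptor
(`AGATCGGAAGAGCGTCGTGTAGGGA`). With 75-nt reads and 63–123-nt inserts
the mates always overlap. Preprocessing trims adaptor read-through
(matched prefix of at least 8 nt, one mismatch allowed), merges mates
that overlap by at least 15 nt with at most two disagreements (resolved
toward the higher-quality base), and falls back to mate 1 alone
otherwise. When the residual read-through is shorter than the trimmable
8 nt, the reverse-complemented mate 2 starts a few bases *before* mate 1
— the merger searches these "outie" offsets too and drops the
adaptor-side overhangs. Reads shorter than 20 nt after processing are
discarded.

Alignment is a deterministic 3'-anchored ungapped comparison: the
ligation chemistry fixes the molecule's CCA end, so each read is
anchored at the 3' end of every mature reference sequence and compared
over the overlap (5' truncation permitted, minimum overlap 20 nt, `N`
counts as a mismatch). One mismatch is allowed by default — enough to
absorb the reverse-transcriptase misincorporation that methylated
adenines (m1A58 in particular) induce. Pipelines for this assay commonly
use a general-purpose aligner for this step; an exact matcher was chosen here
because tRNA amplicons are short and 3'-defined, and exactness lets the
matcher be verified against an exhaustive Hamming-scan oracle.
A SAM export (`writeSam()`) preserves interoperability with samtools.

Multimapping policy: best hits confined to one gene → unique; tied best
hits across several gene copies of one isodecoder → counted for that
isodecoder; ties spanning two or more isodecoders → excluded from counts
and tallied as ambiguous. Discarding cross-isodecoder ties (rather than
fractional splitting) keeps counts integral and is conservative; on
references whose isodecoders differ at three or more positions it
discards essentially nothing. Status tallies always sum to the library
size, and this conservation is enforced by the counts class itself.

## What the simulator emulates — and what it does not

`simulateReadLibrary()` draws molecules as: spike-in with probability
`spikeInFraction`, otherwise a gene sampled proportionally to isodecoder
abundance (uniform within a group); applies the treatment's ligation
rule; and repeats until the requested number of ligated molecules is
reached, so truth-table totals always equal emitted read pairs. Each
ligated molecule yields exactly one read pair (no PCR duplication model,
matching the absence of a duplicate-collapsing step in the analysis it
emulates). Misincorporation substitutes a random different base at each
designated modified position; by default each gene gets one such
position — the 3'-most A in the 55–60-nt window of the mature sequence
when present, mimicking m1A58. Base qualities are constant Q40.

Note one consequence of adding the spike *before* the treatment-dependent
loss: `spikeInFraction` is the spike's share of the control (total)
pool, and the oxidized library is correspondingly enriched for spike —
exactly as a fixed-mass spike behaves in the real assay, and the reason
the ratio estimator needs no correction factor.

Features of real libraries deliberately not modeled: sequencing errors
outside modification sites, quality-score variation, RT stops and
truncations (an optional truncation rate exists but defaults to 0), PCR
amplification bias, and intron-containing or compartment-specific gene
sets. Passing tests therefore demonstrate correctness of the estimator
chain under the assay's operative logic, not robustness to every
artifact of real data; the one-mismatch allowance and the spike floor
are the places where such artifacts would first bite.

The synthetic reference generator (`simulateReference()`) produces
tRNA-length (68–78 nt) sequences for a standard panel of cytosolic
isodecoder labels (always including Gln-CTG and Gln-TTG), keeps
different isodecoders at 3'-anchored distance ≥ 3, embeds the anticodon
at positions 35–37, and can emit near-identical within-isodecoder gene
copies to exercise the multimapping path. The spike-in stand-in is a
random sequence labelled for the yeast-Phe role — synthetic, not the
real yeast sequence.

## Numerical and design choices

* **Problem sizes.** The recovery analyses in the tests and the
  acceptance script use two libraries of 200,000 pairs over 20
  isodecoders at equal abundance (and a 50,000-pair run for the
  selective-uncharging ranking); the aligner/oracle comparison uses
  10,000 random reads against a 50-gene reference. At 200,000 pairs with
  a 5% spike, per-isodecoder counting noise puts a standard deviation of
  roughly 0.017 on a charge ratio near 0.95 — recovery to within ±0.03
  is therefore expected but not guaranteed for every isodecoder on every
  seed, a counting-statistics floor rather than an estimator defect
  (recomputing ratios directly from simulator truth tables reproduces
  the pipeline's errors bit-for-bit).
* **CCA appending** is unconditional for genomic inputs
  (`assumeGenomic = TRUE`); for pre-processed mature sets the flag
  appends only where CCA is absent. Intron-marked records are rejected
  rather than silently spliced, and undetermined-anticodon or pseudogene
  records are dropped with a warning.
* **Spike distinguishability** is checked at build time: a spike within
  the aligner's mismatch allowance of any cellular sequence would
  corrupt normalization and is a hard error.
* **Positions are 1-based** throughout (R convention), including
  modified positions and reporter feature tables.
* **Tie-breaks.** Hits order by (mismatches, then longer overlap); reads
  whose best hits tie across isodecoders are ambiguous. Merge offsets
  minimize disagreements, then maximize overlap.
* **Degenerate inputs.** Empty FASTA → empty gene table; empty read set
  → zero-size counts object; empty protein set → absent Q fraction; zero
  qPCR template → ceiling Ct with flag.

## The polyQ reporter logic

The polyglutamine census scans proteins for maximal uninterrupted Q runs
(≥ 10 by default) and reports the overall glutamine residue fraction.
The reporter constructs express the assay design as testable sequence
logic: `polyq_gfp` is start codon → exon-1-like flank →
(CAG)^36 tract → short flank → GGGGSGGGGS linker → ATG-codon-less
marker ORF, all in frame; `polyq_minus1_gfp` deletes one nucleotide
between tract and linker so the marker is reachable only via a −1
ribosomal frameshift within the CAG tract, which reads the tract in its
(GCA)^n alanine frame; `luc_minus1_gfp` replaces the tract-bearing
insert with an equal-length, tract-free, luciferase-like stand-in whose
−1 frame is kept stop-free, as the no-tract control. Frame
discrimination is engineered at the marker start (early stops in both
off frames) so that exactly one frame reaches the marker end stop-free
in each construct; `analyzeReadingFrames()` verifies this by simulating
translation with the shift applied at the tract's 3' end. The true HTT
exon-1, GFP and *Renilla* luciferase sequences are not reproduced; the
stand-ins are deterministic synthetic segments carrying only the
structural features the frame logic needs, because that logic — not
sequence identity — is the testable content. A CAA interruption pattern
is available (`caaEvery`) since the frameshift mechanism is
CAG-specific.

## Known limitations

* Cross-isodecoder multimappers are discarded, not fractionally
  assigned; on references with near-identical isodecoders (some
  leucine/serine families in real genomes) this undercounts both groups
  symmetrically, which cancels in the charge ratio but lowers effective
  depth.
* The qPCR model assumes a common amplification base across primers
  unless overridden, and Gaussian Ct noise.
* Wobble decoding, tRNA secondary structure, modification calling and
  mitochondrial/compartment filtering are out of scope; the reference
  builder indexes whatever gene set it is given.
* The human-proteome census figures (number of polyQ proteins, overall Q
  fraction) depend on the proteome release supplied by the user; the
  census reports its input set and makes no release assumption.

## A minimal worked session

```{r worked, eval = FALSE}
syn <- simulateReference(6, seed = 3)
ref <- buildReference(syn$genes, syn$spikeIn)
prof <- chargeProfile(setNames(c(0.05, 0.1, 0.9, 0.8, 0.95, 0.85),
                               isodecoderKeys(ref)))
ox  <- simulateReadLibrary(ref, prof, libraryParams(
  20000, treatment = "oxidized", seed = 1))
ctl <- simulateReadLibrary(ref, prof, libraryParams(
  20000, treatment = "control", seed = 2))
co <- assignAndCount(preprocessReads(ox$reads),  ref, "ox")$counts
cc <- assignAndCount(preprocessReads(ctl$reads), ref, "ctl")$counts
computeChargeRatios(co, cc)
```
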