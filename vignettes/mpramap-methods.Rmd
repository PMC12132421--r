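---
title: "mpramap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mpramap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The two assays

`mpramap` quantifies two flavours of massively parallel reporter assay
(MPRA) in which candidate regulatory DNA drives a reporter and activity is
read out by sequencing transcribed barcodes.

**Locus-scale MPRA.** A large genomic region (in real experiments a
BAC-sized insert of 100-250 kb) is randomly fragmented, size-selected, and
each fragment is cloned upstream of a minimal promoter together with a
degenerate 24-nt transcript barcode. Two libraries are sequenced: an
*association library* that pairs each barcode with its fragment (and
doubles as the input-abundance baseline) and a *cDNA library* of barcodes
recovered from transcripts. Per-base activity is the depth-normalised log2
ratio of cDNA barcode signal to input signal accumulated over fragment
intervals; active elements (CRMs, cis-regulatory modules) appear as peaks.

**Degenerate MPRA (d-MPRA).** A single CRM is randomly point-mutated by
error-prone PCR; a duplicated copy of the mutated CRM in the 3' UTR serves
as the transcript barcode. Comparing per-position mutation frequencies
between the expressed (experimental) library and the plasmid pool maps the
nucleotides that matter: mutations in activator-binding positions are
depleted in transcripts (troughs in the log2 profile), mutations in
repressor-binding positions are enriched (peaks).

Every stage consumes either standard files (FASTQ/FASTA/SAM/bedGraph/BED/
MTX/TSV) or in-memory objects, and every input can be produced by the
built-in simulator, so the full pipeline is testable against planted
ground truth without any external data.

# Barcode design and whitelist correction

Transcript barcodes are degenerate IUPAC patterns; the default is twelve
`SW` repeats - 24 nt alternating strong (G/C) and weak (A/T) bases, which
fixes GC content at 50% and caps homopolymer runs at two while retaining
$4^{12} \approx 1.7\times10^7$ distinct sequences. A `VHBD`-repeat
alternative is supported; note that four `VHBD` repeats give 16 nt, so the
24-nt default uses the `SW` form.

Multiplexing library tags are designed by rejection sampling under
explicit constraints: minimum pairwise Hamming distance (default 5), no
base run longer than 2 (excluding any triplet repeat), GC fraction within
[0.375, 0.625] (the four published 8-nt tags all sit at 0.50), and no tag
equal to its own reverse complement. `validate_tag_set()` is the oracle
for `design_tags()`: anything designed must validate.

Whitelist correction follows classical code theory. For canonicals with
minimum pairwise Hamming distance $d_{min}$, correction within radius
$r \le \lfloor (d_{min}-1)/2 \rfloor$ is provably unambiguous; strict mode
(default) enforces that bound, and `build_whitelist(radius = NULL)`
auto-selects the largest guaranteed radius. Variants reachable from two or
more canonicals are tagged `AMBIGUOUS` and dropped during counting rather
than assigned by frequency - conservative counting in the spirit of
whitelist filtering. At realistic library complexity (10^4 or more dense
24-nt barcodes) $d_{min}$ is typically 1-2, the guaranteed radius is 0 and
the whitelist degenerates to exact matching; error correction earns its
keep on sparser designed sets.

# The synthetic-data generator

The generator is first-class, tested code: its records are the ground
truth that downstream recovery is scored against.

* **Fragmentation** draws sizes uniformly in 400-600 nt (the size-selected
  band) and starts uniformly over positions where the fragment fits; each
  fragment receives a fresh degenerate barcode.
* **Association pairs** mirror the real read layout at 2x150 nt: read 1
  carries anchor + barcode + anchor followed by the reverse complement of
  the fragment's 3' end; read 2 is the fragment's 5' prefix. One mate maps
  the fragment start, the other the end, so error-free pairs recover the
  exact interval. Anchors are fixed synthetic 20-mers standing in for the
  vector context.
* **cDNA reads** sample fragments multinomially with weight
  `baseline + max(activity over the fragment)`. The max aggregation
  reflects that a CRM drives the whole reporter wherever it sits within
  the fragment.
* **Clone pools** mutate each position independently with probability
  `mu`; a mutation is a uniform different base, or a 1-nt deletion with
  probability `deletion_fraction` (default 0.1, the indel share typical of
  error-prone PCR). The default `mu` of 0.1% per nt sits inside the
  0.02-0.2% regime of the mutagenesis kits this emulates.
* **d-MPRA pairs** span the full mutated CRM as an overlapping pair (for
  the merge stage). Plasmid libraries sample clones uniformly;
  experimental libraries weight each clone by the product of effect-map
  factors over its mutated positions.

Sequencing errors are i.i.d. substitutions (no indel errors by default,
which isolates the homopolymer-deletion filter's behaviour; there is no
PCR-jackpot or GC-bias model). Raw LS-MPRA reads default to a 0.5%
per-base error. d-MPRA simulations (`dmpra_config()`) default to 1e-4:
the read pair covers the CRM twice and is overlap-merged, so the relevant
rate is the residual consensus error of merged amplicon sequencing, and it
must sit well below `mu` or the experimental/plasmid frequency ratio is
diluted toward 1.

**Why the activity landscape uses graded bumps.** CRMs are planted as
raised-cosine bumps (default span 6 kb, peak amplitude 3 over baseline 1,
i.e. 4x expression at the centre). Two reasons. Biologically, reporter
activity decays as fragments truncate an element, so weights should grade
with overlap. Statistically, rank-based recovery metrics are uninformative
under a binary landscape: if a fraction $p$ of fragments carries the
active weight and the rest are tied at baseline, the Spearman correlation
between planted weights and *any* recovered quantity is bounded by
$\sqrt{3p(1-p)} \le 0.87$, e.g. 0.50 at $p = 0.09$ - regardless of how
good the recovery is. Graded bumps spanning roughly a third of the demo
locus keep per-fragment weights continuous and the attainable correlation
near 0.88, so the end-to-end correlation check measures the pipeline, not
the tie structure. Observed end-to-end values sit around 0.80 at depth
100 with 0.5% errors, i.e. ~0.9 of the attainable bound.

Real libraries reach $7\times10^6$ to $9\times10^7$ fragments; the
simulator's validation default is $10^4$ fragments on a 50 kb locus. This
scaling is deliberate and visible, not hidden: coverage per base (~100
barcodes) is comparable, and nothing in the pipeline depends on absolute
locus size.

# Barcode-fragment association

The internal mapper is an exact 21-mer seed index plus mismatch-bounded
verification (default 5% of the read), adequate for loci up to a few
hundred kb; reads seeding in repeated k-mers fail as multi-mapping rather
than being randomly placed, so repeats cannot generate phantom peaks.
Real, genome-aligned data enters through `read_sam()` instead.

Association applies two rules:

* a barcode observed with interval starts spreading more than 5 nt is
  dropped as ambiguous (one barcode, one fragment);
* entries supported by fewer reads than one tenth of the read-mass
  weighted median support (minimum 2) are dropped. Sequencing errors
  inside true barcodes spawn a swarm of low-support satellite entries -
  at 0.5% error about one read in nine carries a barcode error - and the
  weighted median is robust to that swarm where the plain median is not.

Read accounting is conserved at every stage (parsed + unparsed + unmapped
+ ambiguous + low-support = input) and asserted at pipeline end.
Coordinates are 0-based half-open everywhere, matching bedGraph/BED.

# Activity tracks, AUC and peaks

Input and cDNA signal tracks accumulate per-barcode counts over their
intervals. `normalize_log2()` first scales both tracks to a common mass
(one count-equivalent per position on average), then takes
`log2((cdna + pc) / (input + pc))` with pseudocount `pc = 1`
count-equivalent; the depth normalisation makes the result exactly
invariant to rescaling either library. AUC over a region of interest uses
the trapezoidal rule at 1-nt spacing. Peak calling is threshold-based
(maximal runs above threshold, gap merging, minimum width), with the
run_pipeline default threshold at half the track maximum; candidate CRMs
on browser tracks are conventionally identified by eye, so the caller is
deliberately simple plumbing. Replicate tracks average arithmetically at
the log2 level; AUC values normalise to a designated reference condition.

# The d-MPRA profiler

* **Merging** reverse-complements read 2, scans overlaps of at least 20 nt
  with at most 10% mismatches, scores `matches - 4*mismatches` (ties to
  the longer overlap) and resolves disagreements to the higher-quality
  base (ties to read 1).
* **Alignment** is global with affine gaps (match +1, mismatch -2, gap
  open -4, extend -1). Reads whose length equals the reference take a
  gap-free fast path - under this scoring a gap pair can never beat
  substitutions for equal-length sequences, so position-wise comparison is
  the optimal alignment. Other reads go through
  `Biostrings::pairwiseAlignment`.
* **Full-span rule**: the aligned reference range must cover every
  reference position and no deletion run may exceed 3 nt; a truncated
  read otherwise masquerades as one long internal deletion. Reads above
  20% divergence also fail (foreign sequence guard).
* **Homopolymer filter**: a deletion inside a run of 3 or more identical
  bases has an ambiguous coordinate, so any read carrying one is dropped
  entirely (read-level exclusion). Substitutions inside runs are
  unaffected. The minimum run length of 3 is this package's choice: a
  deletion in a 2-run shifts by at most 1 nt, within the smoothing
  window, while 3-runs and longer genuinely delocalise the call.
* **Tallying** draws (default) 10 independent subsampling replicates of
  80% of the smallest library without replacement. The primary
  per-position frequency is `(substitutions + deletions) / wild-type
  reads` within the replicate - wild-type-normalised, with "wild type"
  meaning reads with zero retained mutations; the per-coverage rate
  (`count / subsampled reads`) is emitted alongside and is the unbiased
  estimator of `mu` (the wild-type-normalised ratio exceeds the raw rate
  by the factor `1/(1-mu)^L`, which cancels in the
  experimental-vs-plasmid ratio but not in rate recovery).
* **Effect profile**: per position, `log2(freq_exp / freq_plasmid)`;
  positions with zero frequency in either library are dropped (the
  retained-in-both rule) and recorded.
* **Finalisation** subtracts the median (so profiles are invariant to
  uniform offsets), applies a centred 5-nt moving average that shrinks at
  profile ends rather than padding (the ends are trimmed anyway), and
  removes the first 18 and last 14 reference positions, which carry
  construct-assembly sequence.
* **Replicate averaging** is the per-position mean over replicates where
  the position is present, with the between-replicate sd attached. For
  null-control checks the package pools that sd across positions
  (root mean square): a per-position sd from 3 replicates has 2 degrees
  of freedom and underestimates badly in its left tail, so pointwise
  3-sd bands would flag perfect null data; pooling is the standard
  variance-moderation remedy.

Insertion calling is out of scope (the assay quantifies substitutions and
deletions), as is per-alternate-allele decomposition.

# Co-expression statistics and PFM logos

Cells count as expressing a gene when the raw count exceeds zero - no
normalisation-aware thresholding. Percent co-expression is
`100 * both / gene1-positive` (asymmetric by design). Enrichment screens
build 2x2 tables against an anchor gene, apply Fisher's exact test
(two-sided by probability-mass ordering, the conventional definition;
other two-sided definitions exist) and a Haldane-Anscombe 0.5 correction
for zero cells in odds ratios, then Benjamini-Hochberg adjustment across
the screen. Position frequency matrices get Shannon information content
`IC = 2 - H` bits per position after adding a pseudocount (default 1e-6
per entry, exposed as an argument; the magnitude only matters for
deterministic columns) and renormalising; letter heights are
`frequency * IC` and sum exactly to the IC.

# Determinism, seeds and numerics

All randomness flows through R's RNG; generator configs carry an optional
seed, and `run_config(seed)` fans out per-stage seeds by fixed small
offsets so each stage is independently reproducible. Pipeline outputs are
byte-reproducible from config + inputs + seed; numeric columns print at 6
significant digits to make that meaningful across platforms. The C++
error-injection kernel draws from R's RNG, so simulations are reproducible
across the R/C++ boundary.

Degenerate inputs fail loudly: all-zero input tracks, zero wild-type reads
in a subsample, references shorter than trims + window, infeasible tag
designs, and radius violations in strict mode are all errors with
guidance, not silent results.

# Validation problem sizes

The shipped test-suite and acceptance studies use: a 50 kb locus with
10^4 fragments at depth 100 and 0.5% error for LS-MPRA recovery (three
planted CRMs recovered with precision and recall 1 and centre error well
under 100 nt); a 200-nt CRM with `mu` = 0.1%, 5x10^3 clones and 5x10^4
reads per library across 3 replicates for d-MPRA sign recovery plus a
matched null; mutation-rate recovery at `mu` of 0.02% and 0.2% from
5x10^4 clean reads (relative error a few percent); and a 2,000-cell
synthetic co-expression matrix (true odds ratio 13.5). Unit tests run the
same machinery at tenth scale.

# Known limitations

The mapper is exact-seeded and unspliced - real genome-scale alignment
belongs to external aligners, consumed via SAM. The error model omits
quality-score profiles, PCR duplication structure and GC bias; passing
tests demonstrate pipeline correctness under the stated model, not
robustness to every artefact of real libraries (the known AscI-site
dropout artefact, for example, surfaces only as low input coverage in QC,
and restriction-site dropout is not modelled). Peak calling is a simple
threshold device, and statistical significance of AUC differences across
conditions is left to standard statistics environments.
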