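---
title: "Inferring tasiRNA biogenesis under the two-hit trigger model"
author: "tasiphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tasiRNA biogenesis under the two-hit trigger model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tasiphase)
```

## The biology being modelled

Trans-acting siRNAs (tasiRNAs) are plant secondary small RNAs produced in a
fixed 21-nt register from a non-coding *TAS* precursor. For the conserved
*TAS3* family the trigger is miR390, under the *two-hit* model: the
transcript carries **two** miR390-complementary sites. One of them — in the
classical configuration the 3′ site — is sliced by the miR390–AGO complex;
the other, carrying a mismatch at the center of the pairing region, is
bound but not cut. The slicing position sets the phase: DCL4 then dices
the RDR6-converted fragment into consecutive 21-nt duplexes, counted from
the cleavage point. Registers are conventionally named 5′D1(+), 5′D2(+), …
on the transcript strand, with minus-strand duplex partners 5′Dk(−). A
subset of these registers — the tasiR-ARFs — silence the auxin response
factors ARF3/ARF4.

`tasiphase` turns the inference usually done by hand around such loci into
a tested pipeline with five stages:

1. **Target scanning** (`find_target_sites`, `detect_two_hit`): score every
   guide-length window of a transcript, keep windows below a penalty
   cutoff, classify their cleavability, and recognise the two-hit
   configuration.
2. **Phasing** (`enumerate_registers`, `minus_strand_registers`,
   `assign_reads`, `phasing_pvalue`): derive the register grid from the
   scissile bond, and tally small-RNA reads per register.
3. **Target prediction** (`predict_targets`, `multiplicity_report`): the
   same duplex machinery applied from the tasiRNA side.
4. **Cleavage validation** (`map_tags`): map 5′-end tags (RLM-RACE clones
   or degradome reads) onto a predicted duplex and read off the observed
   bond.
5. **Simulation** (`make_tas_locus`, `simulate_phased_reads`,
   `simulate_degradome_tags`, `simulate_target_mrna`): generate loci,
   reads and tags with complete ground truth, so stages 1–4 are testable
   without any external download.

## The duplex model and its penalty score

Duplexes are **ungapped and antiparallel**: guide position $i$ (counted
from the guide's 5′ end) faces target-window position $L - i + 1$. Each
position is classified as Watson–Crick (`WC`: A:U or G:C), wobble (`GU`:
G:U in either orientation) or `MISMATCH`. The penalty is

$$\mathrm{penalty} \;=\; \sum_{i=1}^{L} w(\mathrm{state}_i)\, m(i),
\qquad
w = \{\mathrm{WC}{:}\,0,\ \mathrm{GU}{:}\,0.5,\ \mathrm{MISMATCH}{:}\,1\},$$

with $m(i) = 2$ for guide positions 2–13 (the seed/core region) and
$m(i) = 1$ elsewhere. These are the standard plant target-recognition
weights used by the common prediction servers; they are pinned explicitly
(`duplex_weights()`) so that scores are deterministic and reproducible
rather than tied to a web service version. Gapped duplexes (bulges) are
deliberately out of scope: published tasiR-ARF duplexes are ungapped, and
a gap model would add degrees of freedom that nothing in scope can
validate.

```{r duplex}
d <- build_duplex("UCUUGACCUUGUAAGAUCCC", "AGGGUCUUGCAAGGUCAAGA")
which(d$states == "GU")        # wobbles at guide positions 12 and 17
which(d$states == "MISMATCH")  # single mismatch at 20
score_duplex(d)                # 0.5*2 + 0.5 + 1 = 2.5
```

**Cleavability** requires strict Watson–Crick pairing at guide positions
9–11. Slicing is blocked by central duplex distortion, and a G:U pair —
although tolerated elsewhere — is treated as a distortion here, so wobble
at 9–11 counts as non-cleavable. This is the strictest reading consistent
with the "central mismatch blocks the 5′ site" behaviour of TAS3 loci; it
is exposed as its own predicate (`assess_cleavability`) so looser policies
can be layered on top if a use case demands it.

For a cleavable site bound at $[s, e]$, the scissile bond lies between the
transcript nucleotides opposite guide positions 11 and 10, i.e. between
positions $e - 10$ and $e - 9$ (`cleavage_coordinate`).

### Default penalty cutoff

`max_penalty = 4.0` is the default everywhere. The choice balances two
requirements checked in the test-suite: a two-hit locus whose 5′ site
carries one central mismatch (penalty 2 under the weights above, since the
mismatch falls in the doubled core) must qualify with margin, while random
21-mer windows on an unrelated backbone must essentially never qualify
(seeded shuffle tests assert zero spurious predictions at this cutoff).
The cutoff is an argument, not a constant, and tasiRNA target prediction
takes an independent override because tasiRNA–target pairing rules may
legitimately be looser than miRNA–*TAS* pairing.

### Overlap resolution

All qualifying windows are found first; groups of transitively overlapping
windows are then collapsed to the lowest-penalty window per group,
leftmost on ties. The pre-resolution window set is monotone in the cutoff
(raising `max_penalty` can only add windows), a property tested against a
brute-force enumerator.

## Phase registers

Registers are anchored at the cleavage site and tiled 5′-ward: the
highest-index register ends exactly at the last transcript position 5′ of
the scissile bond, and each earlier register abuts the next. Windows that
would extend past the start of the available region are **dropped, not
clipped** — a partial 21-mer is not a tasiRNA. Consequently the register
count is $\lfloor(\text{region length})/21\rfloor$. Names run 5′→3′
(5′D1+ farthest from the cleavage site), matching the convention in which
the ARF-targeting registers of dual-site loci sit near the 3′ end of the
array.

```{r registers}
# the archetypal dual-site geometry: 5' site ends at 312, 3' site bound
# at [472, 491] and sliced opposite guide positions 10/11
bond <- cleavage_coordinate(list(end = 491L, cleavable = TRUE))
regs <- enumerate_registers(cleavage_5p_end = bond[1], region_start = 313L)
nrow(regs)          # 8 complete registers
regs[c(1, 8), c("name", "start", "end")]
```

Minus-strand partners are the reverse complements of the plus-strand
windows shifted 3′-ward by the duplex overhang (2 nt by default, the
Dicer-family duplex geometry; configurable since it is a convention, not
an observable of this pipeline). Partners whose shifted window runs off
the transcript are dropped.

**Read assignment is exact**: a read is in-phase for a register iff its
sequence (with T≡U) is identical to the register 21-mer, mirroring how
phased species are searched against sRNA libraries by exact match. Reads
matching the phasing region at any other offset (either strand) are
off-phase; anything else is ignored as foreign. Both raw (multiplicity-
weighted) and collapsed (distinct-sequence) tallies are reported, because
public tables of phased-read abundance do not always state which tally
they print.

### The phasing statistic

The workflow this package automates reports plain per-register read
counts; `phasing_pvalue` adds an optional enrichment statistic and all
written output flags it as an addition. With $K = \lfloor N/21 \rfloor$
in-phase start positions among the $N$ positions of the region, the
statistic is the binomial upper tail
$P(X \ge x)$, $X \sim \mathrm{Bin}(n, K/N)$, for $x$ in-phase reads out of
$n$ region-mapped reads. A draw-without-replacement (hypergeometric) form
was considered and rejected: read counts routinely exceed the number of
distinct start positions, and several reads can share a 5′ end, so
position-sampling without replacement does not describe the data. The
binomial tail is exact under the uniform-start null, is monotone
non-increasing in the in-phase count at fixed totals, and is calibrated in
simulation (≥ 90 % of seeded null data sets give $p > 0.05$; both
properties are asserted in the test-suite).

## Degradome / RLM-RACE cleavage mapping

A 5′-end tag at transcript position $t$ marks a bond between $t-1$ and
$t$. `map_tags` collects tags within the duplex window ± 5 nt (the flank
is configurable; RACE clones map within or immediately around the
complementary region), takes the **modal** position, and converts it to
guide-relative numbering $(i, i+1)$ with $i = e - t + 1$; $(10, 11)$ is
the canonical slicer signature. Ties prefer the canonical bond, then the
3′-most position — a deterministic rule chosen because validated loci are
reported as a single position with a clone fraction, e.g. a target cut
between guide positions 9 and 10 rather than 10 and 11. The supporting
fraction is modal count over total in-window count and is invariant under
uniform scaling of counts.

## What the simulators emulate — and what they do not

`make_tas_locus` builds a uniform-random backbone and implants the two-hit
architecture: a perfect-complement 3′ site (penalty 0, cleavable) and a 5′
site whose single mismatch faces guide position 10 (implemented by placing
the guide's own base there — a self-pair can never be WC or G:U, so the
mismatch is guaranteed without further case analysis). Site placement
guarantees that exactly `n_registers` complete registers fit between the
5′ site's end and the scissile bond; with 21-nt guides the register region
always overlaps the 5′ half of the 3′ site, as at real loci.

`simulate_phased_reads` draws, per read, in-phase vs off-phase with
probability `in_phase_fraction` (default 0.9); in-phase reads pick a
register from geometric weights $\mathrm{decay}^{|k - \mathrm{peak}|}$
(decay 0.5, peak defaulting to register $m-2$, reproducing the skew of
real phased loci where a couple of mid-3′ registers dominate and several
registers are near zero) and emit the exact 21-mer, from the minus strand
with probability `minus_strand_fraction` (default 0.3). Off-phase reads
are 21-mer substrings of the region at uniformly drawn non-register
offsets; offsets whose substring would coincide with a register sequence
are excluded so that simulation truth and exact-match assignment agree to
the read. Defaults (depth 1000 for routine checks, 10⁴ for the
distributional check) keep the whole suite fast while leaving multinomial
fluctuations measurable.

`simulate_degradome_tags` places `(1 - noise) * depth` tags at the true
bond (optionally offset from canonical) and the rest uniformly in the
flanked window; depth 50 with 10 % noise is the reference condition under
which the bond must be recovered in at least 95 of 100 seeded runs.

What the simulators deliberately **do not** model: sequencing error,
quality scores, adapter artefacts, GC bias, multi-locus read ambiguity,
and 24-nt phasiRNA classes. Passing tests therefore demonstrate that the
*logic* — scoring, geometry, counting, statistics — is correct under
clean, known-truth conditions; they do not certify performance on noisy
biological libraries, where trimming and filtering upstream of this
package remain the user's responsibility.

## Numerical and degenerate-input choices

* Coordinates are 1-based, inclusive, on the plus strand throughout.
* T and U are interconvertible in every comparison; the canonical internal
  alphabet is RNA, and sequences containing neither T nor U are treated as
  RNA.
* All penalties are small rationals (multiples of 0.5); comparisons are
  plain `<=` with no tolerance needed.
* A region shorter than one phase length yields zero registers (not an
  error); zero mapped reads yield $p = 1$; an empty tag window yields an
  explicit "unsupported" report with fraction 0 rather than an error.
* Every simulator consumes an explicit integer seed, restores the caller's
  RNG state, and is byte-deterministic for fixed inputs.

## Known limitations

* Only the two-site (dual-hit) configuration is detected; loci with more
  than two qualifying sites are resolved to the two best with a warning.
* The 5′-anchored processing mode (`phase_anchor = "5p"`) implements the
  alternative geometry reported for some dicot TAS loci but has no
  ground-truth generator in the simulation module.
* Exact-match read assignment will undercount on real libraries with
  untrimmed or 5′-jittered reads; a mismatch-tolerant mode is intentionally
  not provided because it would change what the reported counts mean.
* Target prediction multiplicity depends on the supplied mRNA set; no
  transcriptome library ships with the package.

## Problem sizes used in the checks

The routine test-suite works on 600-nt synthetic loci with 8 registers,
read depths of 500–1500, and 100-seed recovery studies; the scanning
oracle comparison uses 10⁴ random transcript/guide instances of ≤ 60 nt /
≤ 12 nt, where exhaustive enumeration is itself trivially correct. These
sizes were chosen so the full suite exercises every code path in a few
minutes on a single core while keeping all stochastic acceptance margins
wide.
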