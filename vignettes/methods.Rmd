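---
title: "Models and methods behind teunmask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind teunmask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teunmask)
```

`teunmask` studies one biological event from every computational angle: a
DNA transposon inserted into the coding sequence of one allele of a
voltage-gated sodium channel (VGSC)-like gene, silencing that allele
through nonsense-mediated decay (NMD) and thereby unmasking recessive
pyrethroid-resistance mutations (kdr/super-kdr analogues) carried on the
homologous allele. This vignette describes the models, the defaults and
the reasoning behind the choices that were genuinely open.

## The simulated locus

`build_locus()` constructs an 8,000-nt single-gene locus with two exons
(0-based half-open intervals [599, 1699) and [2199, 4805)) and a 3,306-nt
CDS (1,102 codons) split 1,000/2,306 between them. The CDS is sampled
from sense codons only, with ATG and TAA planted at its ends, so the
reference ORF is clean by construction. The geometry mirrors the
biological case: the insertion breakpoint sits at CDS nt 2,360 (so the
first disrupted codon is ⌈2360/3⌉ = 787) and the two variant sites lie
346 and 634 nt downstream of it (CDS nt 2,706 and 2,994), inside the same
exon. Both site offsets land on third codon positions, so the exact
amino-acid exchanges of the housefly-numbered mutations cannot both be
reproduced at those distances; the kdr analogue is TTA→TTT (Leu→Phe, the
canonical exchange) and the super-kdr analogue ATG→ATA (a Met-losing
substitution). All downstream logic keys on the site labels, not the
codon chemistry.

Three haplotypes are defined: S (reference alleles, no insertion), R
(both alternate alleles), and M (reference alleles plus the element).
Clone archetypes map to pairs: 1X = S/S, 4H = S/R, 62H2 = 88H2 = M/R,
92H6 = R/R. The resistance SNPs and the insertion never share a
haplotype, matching the configuration the archetypes represent.

The default element is the 2,076-nt 5′-truncated suffix of a 2,476-nt
full-length parent built by `make_te()` with 109-nt imperfect terminal
inverted repeats (TIRs; 5 mismatches). Because the truncation (400 nt)
exceeds the TIR length, the inserted copy retains only its 3′ TIR — the
TIR pair is a property of the full-length parent, which is what
`compare_to_library()` is given as library. This has a second, welcome
consequence: the simulated locus contains a single TIR copy, so targeted
assembly never has to disambiguate a pair of inverted near-repeats
(multi-copy repeat resolution is explicitly outside the assembler's
scope).

## Read simulation and truth alignments

`simulate_reads()` draws fragments (normal length, mean 400 nt, sd 50 nt,
150-nt paired ends — a routine modern short-read configuration) uniformly
from each haplotype. Fragment counts per haplotype are proportional to
haplotype *length*, which is what uniform sequencing of a diploid does:
every haplotype base, inserted sequence included, is covered at half the
requested diploid coverage, and allele fractions at heterozygous
positions are unbiased. The default DNA coverage of 40× matches a
typical resequencing depth for this kind of experiment.

In RNA mode, fragments are drawn from spliced transcripts. Any transcript
whose in-frame translation stops before its final codon is an NMD target
and is down-weighted to a residual relative abundance `nmd_retention`
(default 0.05, the middle of the 3–10% residual band such alleles show in
practice). No exon-junction rule is applied — NMD is modelled purely as
PTC-triggered degradation. Because what the downstream counter measures
is *depth at a site*, pair counts scale with abundance × transcript
length, making the expected alternate-allele fraction at a heterozygous
site exactly `1/(1 + nmd_retention)` (≈ 0.952 at the default).

Truth alignments are computed analytically from a per-base map of
template coordinates to reference coordinates: bases absent from the
reference (inside the insertion) become soft clips, intron gaps become N
ops, and when anchored blocks flank an insertion the longer block is
kept, as a local aligner would report it. Reads without a ≥ 20-nt anchor
are emitted unmapped. The error model is uniform substitution only
(default 0 for unit-level work, 0.005 for error-tolerance checks);
quality strings are constant. No PCR duplicates, GC bias or indel errors
are simulated — results on real data will be noisier than these tests
can show, which is why the thresholds below are deliberately
conservative.

## Breakpoint detection

`collect_clips()` keeps primary mapped records, demands position-sorted
input, and clusters terminal soft clips of ≥ 20 nt (shorter tails are
indistinguishable from alignment noise) by clip point and side, merging
positions within 5 nt. Tail consensus is per-column majority with
columns under 70% agreement masked as N; exact ties are never guessed.
`call_insertions()` pairs a tail-clip cluster with a head-clip cluster
within the merge window and requires ≥ 3 supporting reads.

The insertion allele fraction needs care: a long insertion exposes *two*
clip junctions that map to the same reference breakpoint, while the
insertion-free allele presents one spanning window. The estimator
therefore uses the per-side mean of clipped support against unclipped
fragments that anchor ≥ 20 nt on each side of the breakpoint — equal
capture windows on both alleles — which makes its expectation 0.5 for a
heterozygote. Zygosity is het inside (0.2, 0.8), hom above, ambiguous
below.

## Targeted assembly

`assemble_insertion()` is the in-silico counterpart of repeatedly mapping
raw reads at highest stringency to a growing contig. The right-cluster
tail consensus (which by construction starts at the insert's first base)
is extended rightward; the left-cluster consensus (ending at the insert's
last base) leftward, via the reverse complement. Each round recruits
reads — in either orientation — containing the contig's terminal 31-mer
with ≤ 1 mismatch and extends by the strict-majority consensus of the
recruited overhangs; a tied column aborts extension (truncation is
preferred to chimerism), and columns with fewer than 3 reads stop the
round. After every round the two contigs are tested for a co-linear
overlap of ≥ 40 nt with ≤ 1 mismatch, in both possible placements (for
inserts shorter than a read, the 3′ contig legitimately starts left of
the 5′ contig's start). Because the seeds anchor the insert termini
exactly, the reported sequence is simply the span between them; any
target-site duplication would survive inside the span and remain visible.
Consensus columns masked N are trimmed from the unanchored seed ends, as
exact k-mer recruitment cannot cross them. A 100-round cap flags
still-growing contigs as incomplete rather than erroring.

## TIR and truncation annotation

`find_tirs()` anchors candidate repeats at the element's termini (where
DNA-transposon TIRs sit) and compares the prefix with the reverse
complement of the suffix position-wise — substitutions only, which keeps
the naive oracle exact. The reported hit is the longest length within a
300-nt search window that (i) ends on a matching pair, (ii) keeps the
overall mismatch fraction ≤ 0.1, and (iii) has ≤ 2 mismatches among its
innermost 12 pairs. The local condition (iii) matters: with only a
global budget, a long repeat's spare mismatch allowance lets the
reported length drift into random flanking sequence. A chance complement
immediately adjacent to a true repeat is information-theoretically
indistinguishable from a one-longer repeat, so test fixtures guard the
boundary pairs when asserting exact recovery.

`compare_to_library()` runs an ends-free (overlap) pairwise alignment
against each library entry (match 2, mismatch −3, gap open 5, extend 2)
and classifies the element 5′-truncated when it aligns essentially fully
(5-nt end slack) as a suffix of a longer entry at ≥ 90% identity, with
`bases_missing` the unaligned library prefix.

## Frame impact and NMD

`annotate_impact()` takes the modified CDS, validates that the original
CDS (insert excised) is a clean ORF, translates in frame from codon 1
(ambiguity codes → X, never a stop), and reports: first disrupted codon
= ⌈position/3⌉ with `position` the 1-based index of the first displaced
base (the convention under which an insertion at CDS nt 2,360 disrupts
codon 787); the first stop before the final complete codon as the PTC;
frame restoration iff the insert length is divisible by 3; and the NMD
flag iff a PTC exists — the same rule the simulator uses, keeping the two
modules consistent.

## Allele-specific expression

`count_alleles()` walks each alignment's CIGAR to the site, honouring
splices, skipping deletions/clips and bases under Q20, and counting each
read name once per site. The exact two-sided binomial p-value against
0.5 comes from `binom.test`. `classify_expression()` calls a site
monoallelic when the allele fraction passes 0.85 *and* the test rejects
at α = 0.01 with ≥ 20 informative reads; 0.85 sits below the ~0.90 floor
observed for genuinely silenced alleles but far above anything a
balanced heterozygote produces at these depths. The formal test is this
package's own operationalisation — the descriptive practice it
formalises reported percentages without one. The pipeline additionally
genotypes each site from the DNA alignments and reports fixed sites as
such instead of letting a homozygous site masquerade as monoallelic
expression; no mapping-bias correction is applied (simulated reads are
symmetric by construction — a caveat for real data).

## Genetics and diagnostics

`cross()` enumerates the four equiprobable gamete pairs. The phenotype
rule is: nonviable iff no haplotype is expressed; resistant iff viable
and every expressed haplotype confers resistance; susceptible otherwise.
This single rule reproduces recessive resistance (S/R susceptible),
unmasking (M/R resistant), and homozygous lethality of the silenced
allele (M/M). The alphabet is extensible; a predefined `R_L` haplotype
(the alternative super-kdr form) is flagged "inferred" because its
resistance is deduced from monoallelic expression, not bioassayed.
Clonal propagation is the identity cross; reproductive-mode dynamics and
temperature-dependent fitness costs of M carriers are out of scope.

`amplify()` matches primers purely by sequence (mismatch budget outside
an exact 3-nt 3′ anchor; no melting-temperature or dimer model) and
measures products from the forward site's 5′ end to the distal end of
the reverse site. `call_genotype()` declares the insertion present when
any insertion-specific reaction bands at its expected size (± 5 nt),
absent when only wild-type-specific reactions do, invalid when nothing
does. Published diagnostics of this design give 326/276-nt
insertion-specific and 327-nt wild-type products; the bundled fixtures
embed exactly those sizes into synthetic templates, since the real
primer sequences live in supplementary material not shipped here.

## Dose–response statistics

`fit_probit()` is maximum-likelihood binomial probit on log10 dose via
`glm`, following the field's standard analysis; no natural-mortality
correction is applied (none is simulated). LC50 confidence limits use
Fieller's theorem on −α/β, falling back (flagged) to the delta method
when the Fieller discriminant is non-positive. Degenerate all-dead or
all-alive data yield a flagged fit with no estimate. Resistance ratios
are reported to 3 significant figures. `lrt_equality()` compares the sum
of separate log-likelihoods against a pooled fit, χ² on 2(k−1) df.
`ddct_fold_change()` normalises target Ct against the arithmetic mean of
housekeeping Cts — identical to the log of the geometric mean of their
linear quantities — and reports 2^−ΔΔCt against the calibrator.

## Problem sizes used in the checks

The test suite runs everything on simulations sized to exercise the
statistics without waste: insert reconstruction is checked for exact
recovery at lengths 80/300/1,000/2,076 nt over 20 seeds each at 40×;
breakpoint recall and false-call rates over 50 positive and 50 negative
loci; ASE calibration over 200 transcriptome replicates at 100×
(pooled n ≈ 45,000 site reads); probit recovery and the likelihood-ratio
test's type-I error over 300 replicates each at 7 doses × 50 insects.
These sizes give three-standard-error resolution well inside the bands
being asserted.

## Known limitations

- The assembler resolves a single targeted insertion; multi-copy or
  internally repetitive elements (including an element retaining both
  TIRs, which form inverted near-copies) can stall extension at
  ambiguous columns — by design, since ties abort rather than guess.
- TIR search is substitution-only; indel-divergent TIRs are not found.
- The NMD model is PTC-presence only; exon-junction geometry, partial
  degradation kinetics and nuclear transcript pools are not modelled.
- PCR prediction ignores thermodynamics entirely.
- The read simulator omits quality-score structure, indels, duplicates
  and coverage biases; passing tests demonstrate algorithmic
  correctness under the stated model, not robustness to every artefact
  of real libraries.
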