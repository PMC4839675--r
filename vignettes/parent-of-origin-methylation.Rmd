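---
title: "Determining the parental origin of trisomy 21 from DNA methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining the parental origin of trisomy 21 from DNA methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methorigin)
```

# The scientific problem

Free trisomy 21 arises when a chromosome 21 fails to separate during
meiosis; the supernumerary copy can come from either parent. The
classical way to tell which is linkage analysis of trio STR genotypes.
`methorigin` implements that route together with an epigenetic
alternative: if a CpG island near the nondisjoined region carries a
maternal germline methylation imprint, the bulk methylation level of a
trisomic sample encodes the origin directly — two of three alleles are
methylated when the extra copy is maternal (expectation 200/3 ≈ 66.7%),
one of three when paternal (100/3 ≈ 33.3%), against the disomic 50%.
The package also provides the supporting analyses such a study needs:
allele-specific methylation calling with two complementary restriction
enzymes, an allelic-expression screen over raw read sets, and a
degenerate-motif scanner for the tandem repeat array that marks the DMR.

# MSRE-PCR quantification

## Model

A triplex PCR amplifies, from undigested and HhaI-digested aliquots of
the same genomic DNA, (1) the query CpG island, (2) a fully
digestion-susceptible positive control, and (3) a reference region with
no HhaI sites. HhaI cuts only unmethylated GCGC sites, so the fraction
of query template surviving digestion estimates the fraction of
methylated (enzyme-resistant) alleles. Because amplimers amplify with
different efficiencies, the digested query:reference ratio `C/D` is
normalized by the undigested ratio `A/B`, expressed through the
imbalance correction factor:

$$f_{AB} = \left[\frac{100\,A}{A+B} - 50\right]\times 0.02
         = \frac{A-B}{A+B}, \qquad
\%\mathrm{Meth} = 100\,\frac{C\,(1-f_{AB})}{D\,(1+f_{AB})}
               = 100\,\frac{C}{D}\cdot\frac{B}{A}.$$

The second equality follows from $(1-f_{AB})/(1+f_{AB}) = B/A$ and is
what makes the estimator invariant to each amplimer's amplification
efficiency: multiplying both $A$ and $C$ by any $k>0$ leaves the result
unchanged. Both forms are implemented and tested for agreement to
$10^{-9}$; the identity itself is verified to $10^{-12}$ relative error
over peak areas in the realistic electropherogram range (50–50,000
fluorescence units, ratios up to ~1000 — beyond that, double-precision
cancellation in $1-f_{AB}$ dominates, which is a property of the
reconstruction, not the assay).

## Numerical choices

* Raw ratios slightly outside $[0, 100]$ are measurement noise and are
  clamped, with the `clamped` flag set; clamping beyond 10 points
  (configurable `slack`) additionally raises a warning, since that
  indicates assay failure rather than noise.
* Division requires $A, B, D > 0$; $C = 0$ is valid and yields exactly
  0%.

## Classification thresholds

Three methylation states are reported: hypomethylated at ≤ 20%,
hypermethylated at ≥ 80%, hemimethylated in between (boundaries
inclusive toward the extremes, configurable). The defaults are chosen so
the biological anchors classify correctly: a fully unmethylated
androgenetic mole (~0%), hemimethylated disomic blood (~47–51%), and
hypermethylated embryonic stem cells (~82%). No sharper boundary is
biologically motivated, so the values are deliberately round.

Digestion QC normalizes the surviving positive-control fraction the same
way and passes at a residual ≤ 0.05 (the control is fully
digestion-susceptible; 5% residual allows for integration noise).

# STR trio origin inference

## Dosage from peak areas

Fluorescence peak areas are roughly proportional to template copies. A
trisomic biallelic genotype is called 2:1 when the larger:smaller area
ratio lies in [1.5, 3.0]; a triallelic genotype is called 1:1:1 when the
max:min ratio is ≤ 1.6. These windows are design choices: the assay
literature describes the patterns only as "approximately 1:1:1" and "a
consistent 2:1", so the windows are midway between the nominal ratios
(1, 2, and the impossible 3:0), wide enough for ~10% area noise and
narrow enough that the nominal patterns cannot be confused. Both are
configurable and uncallable loci are simply uninformative — with
multiple loci per family, discarding a borderline locus is cheaper than
miscalling it.

## Segregation enumeration

For a trisomic child the dosage-resolved genotype (a multiset of three
alleles) is split every possible way into a two-allele contribution from
one parent plus a single allele from the other. Nondisjunction is
modeled as two independent gametes from the origin parent, so a
heterozygous mother can contribute $\{a,a\}$, $\{a,b\}$ or $\{b,b\}$ —
this covers both meiosis-I and meiosis-II errors without attempting to
distinguish them (stage inference would need pericentromeric marker
reduction, which this analysis does not perform). A locus is informative
when every Mendelian-consistent split places the doubled contribution on
the same parent; if both parents could explain it the locus is
uninformative, and if neither can it is flagged inconsistent. The
implementation is verified against a brute-force enumeration of all
gamete pairs on exhaustive small allele configurations.

## Aggregation policy

A family verdict (MT21/PT21) requires at least three informative loci,
all agreeing; any maternal/paternal conflict yields `inconsistent`
rather than a majority vote. Unanimity is the conservative choice for a
diagnostic question — a single conflicting informative locus indicates
either genotyping error or a non-standard inheritance event, both of
which invalidate the simple trisomy model rather than merely outvoting
it.

## Androgenetic verification

A complete hydatidiform mole of androgenetic origin carries no maternal
genome. Verification compares the mole's genotypes with the donor's over
at least 10 shared loci: the mole must be homozygous everywhere
(monospermic origin), and at loci where its allele is absent from the
donor genotype, maternal transmission is positively excluded. Three or
more excluding loci are required, mirroring the three-locus rule above;
a mole matching the donor everywhere is *not* called androgenetic, since
a maternal contribution cannot be excluded.

# Allele-specific methylation

HhaI (cuts unmethylated DNA) and McrBC (cuts methylated DNA) are
complementary: on a truly hemimethylated heterozygote with complete
digestion, the HhaI-surviving and McrBC-surviving alleles are disjoint
and together reconstruct the untreated genotype. The caller reports the
HhaI-surviving allele as methylated, uses McrBC for cross-validation
(discordance downgrades the call to `ambiguous`), and assigns the
parental origin of the methylated allele through the trio when only one
parent carries it. An allele is "detected" in a SNuPE electropherogram
at ≥ 10% of the strongest peak — an instrument noise floor, configurable.

The bulk classifier `epigenetic_origin` uses thresholds 175/3 ≈ 58.3 and
125/3 ≈ 41.7 — the midpoints between the disomic expectation (50%) and
the two trisomic expectations. The indeterminate band deliberately
covers the disomic value, so a mislabeled disomic sample is not forced
into a parental call. On simulated trisomies with Gaussian noise of 6
percentage points, essentially all samples crossing a threshold are
called for the correct parent (a wrong-parent call requires a > 4-sigma
excursion), while ~8% fall in the indeterminate band; accuracy is
therefore reported among samples reaching a verdict, matching how the
STR caller is scored among trios reaching a verdict.

# The allelic-expression screen

Each SNP is queried with a 29-character substring of its flanking
sequence carrying exactly one biallelic IUPAC code at the SNP position.
The two concrete expansions are searched as exact substrings in each
read and its reverse complement; reads matching both expansions (possible
when the read spans a second, error-induced copy) are excluded as
ambiguous. Exact matching is deliberate: with 28 fixed positions, a
single mismatch tolerance would mostly admit sequencing errors at the
SNP position itself, exactly where errors must not be forgiven.

Gates and categories follow the standard screen design: a read passes
quality filtering when ≥ 90% of its bases have Phred ≥ 25 (both
boundaries inclusive); a SNP is classified only at depth ≥ 80
informative reads. The allele-a fraction (allele a = the alphabetically
first base of the ambiguity code, a deterministic orientation) maps to
monoallelic (< 0.15 or > 0.85), biallelic ([0.35, 0.65] inclusive) or
biallelic imbalance in between; the fractions 0.15 and 0.85 themselves
fall in the imbalance band, since the monoallelic bounds are strict
inequalities. The chi-square test against 50/50 is the 1-df goodness of
fit without continuity correction, which reduces to
$(n_a - n_b)^2 / (n_a + n_b)$; at depth 100 its type-I error is ~0.057
(the discreteness of the binomial makes it slightly anticonservative at
the 0.05 level), which the calibration tests verify.

# Motif scanning

The scanner slides the IUPAC consensus over both strands, counting
mismatches per window (`N` in the subject never matches; minus-strand
hits are found by matching the reverse-complemented consensus in forward
coordinates). The default mismatch tolerance is 0 because the degeneracy
is already encoded in the consensus. Same-strand hits whose
start-to-start distance is at most motif length + 60 bp chain into
arrays of ≥ 2 units; 60 bp accommodates the ~62 bp start-to-start
spacing observed for the seven-unit repeat array at the candidate DMR,
whose constructed analogue (7 units, spacing 62, unit length 15) spans
$6 \times 62 + 15 = 387$ bp. Coordinates are 0-based half-open
internally and 1-based inclusive in report tables, following BED-like
conventions.

# The synthetic-data generators

The generators emulate the statistical structure each stage assumes, not
the instruments:

* **Trios** (`sim_trios`): parents drawn from equifrequent allele pools
  (default 8 alleles at 5 loci — typical heterozygosity for the
  tetranucleotide STRs such studies use); trisomic children get two
  independent gametes from the origin parent; peak areas are
  copy-number × 1000 fluorescence units with 5% lognormal noise. The
  default origin mix is equal thirds so the caller's symmetry is
  exercised; the cohort script instead weights origins to the clinically
  observed maternal excess.
* **MSRE quartets** (`sim_msre`): peak-area noise has two components — a
  run-level lognormal scale factor (CV `meth_noise_cv`, default 3%)
  shared by the peaks of one capillary injection, and an independent
  per-peak integration residual (CV `meth_noise_cv/3`). Injection
  amount and detector gain dominate area variation and are common to
  all peaks of a run, which is precisely why the assay is designed
  around within-run ratios; only the smaller per-peak residual
  propagates into the estimate. Under these defaults the estimator's
  mean absolute error stays below 2 percentage points across the whole
  0–100% range, with exact recovery in the noise-free limit.
* **Reads** (`sim_reads`): each read embeds one allele's 29-mer at a
  random offset in random flanking sequence on a random strand
  (binomial allele sampling), with per-base substitution errors
  (default 0.001) and Gaussian-ish quality strings centered at Q36.
* **Motif sequences** (`sim_motif_seq`): concrete consensus instances
  (degenerate positions resolved randomly per unit) at constant spacing
  inside 200 bp random flanks, with truth coordinates returned.

All generators are deterministic given a seeded `sim_config`, down to
byte-identical FASTQ output.

What the generators do *not* model bounds what passing tests show about
real data: no electrophoresis stutter or pull-up peaks, no STR mutation,
no population structure or linkage disequilibrium, no sequencing error
profiles beyond uniform substitution, no alignment ambiguity (reads are
queried by containment, not mapped), and no meiotic recombination — so
the trio caller's perfect accuracy on simulation is an internal
consistency result, not a clinical error rate.

# Problem sizes and verification

The test suite checks, among others: the correction-factor identity on
10^4 random peak-area pairs; equivalence of the two %Meth forms to
10^-9; estimator recovery (100 replicates per true value in
{0, 10, …, 100}); segregation calls against a brute-force gamete
enumeration on all 4-allele configurations; 500 simulated trios with
zero tolerated wrong-parent verdicts; the expression category map on the
full fraction grid with symmetry about 0.5; the chi-square statistic
against `chisq.test` for all depths ≤ 60 and its type-I calibration over
10^4 simulations; and the scanner against both a naive matcher and
`Biostrings::matchPattern`. These sizes keep the full suite under a
couple of minutes while leaving Monte-Carlo margins far from the
acceptance thresholds.

# Known limitations

* The MT21/PT21 epigenetic classifier presumes the sample is known
  trisomic and the DMR retains its germline imprint in the sampled
  tissue; tissues or stages that erase or gain methylation (e.g.
  hypermethylated embryonic stem cells) break the dosage arithmetic.
* The trio caller does not model STR mutation or stutter; a de novo
  repeat-length change at an informative locus would surface as an
  inconsistent family rather than being absorbed.
* The expression screen's exact-substring counting requires reads ≥ 29
  bases that span the SNP with no error inside the window; its depth is
  therefore conservative relative to alignment-based counting.
* Meiotic stage (MI vs MII) is out of scope throughout.
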