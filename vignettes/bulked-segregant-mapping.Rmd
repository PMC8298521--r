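---
title: "Mapping a causal mutation in a haploid cross: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a causal mutation in a haploid cross: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkmapr)
```

## The problem

In moss and other organisms with a dominant haploid phase, a mutant isolated
in one genetic background (here called Gd, the mutagenised parent) can be
crossed to a polymorphic wild type (Vx), and every spore of the hybrid
sporophyte germinates into a scoreable haploid segregant. For a monogenic,
fully penetrant trait the phenotype then reads out the parental origin at
the causal locus directly -- there is no dominance, no phase ambiguity, and
the progeny segregate 1:1.

`bulkmapr` implements the two complementary mapping computations this design
enables, plus the downstream candidate-variant filter:

1. **Bulked-segregant analysis (BSA)**: pool progeny selected for the mutant
   phenotype ("downward-growing" in the motivating protonema screens),
   sequence the pool, and scan for the genomic region where the pooled reads
   are dominated by the mutant parent's alleles.
2. **Two-point linkage refinement**: genotype segregants individually at a
   local marker panel and shrink the interval to the nearest flanking
   markers that show recombinants.
3. **Variant-effect classification and filtering**: within the mapped
   interval, retain only nonsynonymous (missense) and nonsense (stop-gained)
   changes in genes.

Because real screens of this kind rest on undeposited genotyping details and
raw reads, the package ships a first-class synthetic-data generator (the
cross simulator) that reproduces the study conditions; every stage is tested
against it and against closed-form expectations.

## The mapping statistic

For marker $i$ with pooled read depths $a_i$ (Gd allele) and $b_i$ (Vx
allele), the per-SNP statistic is the Gd depth fraction

$$ f_i = \frac{a_i}{a_i + b_i}. $$

In a bulk of $n$ haploid segregants selected for the Gd-linked phenotype,
the expected fraction at a marker with recombination fraction $r$ to the
causal locus, sequenced with per-read error $e$, is

$$ E[f] = (1 - r)(1 - e) + r e, $$

so $f \to 1 - e$ at the causal locus and $f \to 1/2$ at unlinked markers.
This is why the statistic is implemented as a *fraction* (baseline 0.5,
ceiling 1.0) rather than the literal quotient $a/b$: the detection criterion
"the ratio approaches 1.0" is only meaningful on the fraction scale -- the
raw quotient is already $\approx 1$ at unlinked loci and diverges at the
causal locus. Markers with zero total depth are undefined and are dropped
rather than imputed.

Smoothing averages $f_i$ in sliding windows of `window` bp advanced by
`step` bp (defaults 0.5 Mb and 0.25 Mb). Windows are bp-anchored and
half-open, $[kS, kS + W)$ -- the one departure from the package's otherwise
1-based, both-ends-inclusive coordinate convention. Windows with fewer than
`min_markers` (default 5) defined ratios are masked and reported as missing,
never as zero: a sparse window carries no evidence, and a zero would
masquerade as a strong Vx signal. Peaks are maximal runs of at least
`min_run` contiguous unmasked windows with mean at or above `threshold`
(default 0.9); ties for the run maximum resolve to the leftmost window so
that results are deterministic.

The defaults `threshold = 0.9`, `min_run = 1`, `min_markers = 5` are
package choices (no published values exist for them): 0.9 sits several
bulk-composition standard deviations above the unlinked baseline for a
48-member bulk, while staying below the causal-region plateau $1 - e$ even
after window averaging; all three are arguments the user can change.

## The cross simulator

`simulate_cross()` draws each chromosome of each meiotic product under the
no-interference model: a Poisson number of crossovers with mean equal to the
genetic length in Morgans, crossover positions uniform in genetic
coordinates, mapped to bp by piecewise-linear interpolation through the
marker $(cM, bp)$ pairs (constant extrapolation beyond terminal markers),
and a Bernoulli(1/2) starting origin. No interference was chosen
deliberately: under it, two-locus discordance follows the Haldane map
function $r = \tfrac12(1 - e^{-d/50})$, the same function the linkage stage
uses, so the simulator and the estimator are mutually consistent and the
meiosis model is testable against a closed form. The map-function choice in
analysis code is an argument of the science, not of the simulator: with real
data from an organism with strong interference one would substitute Kosambi
distances downstream, and the two-point counting logic would be unchanged.

Phenotype assignment: Gd carriers at the causal locus score "down" with
probability `penetrance` (default 1), otherwise "up"; non-carriers score
"up"; each progeny is independently relabelled "undetermined" with
probability `undetermined_rate` (default 0). Undetermined progeny never
enter a bulk -- the corresponding real-world tables list them as a separate
class, without stating how they were handled, so the simulator exposes the
rate as a knob and defaults it to zero.

Pooled sequencing (`simulate_pool_depths()`): per marker the total depth is
Poisson(`coverage`, default 50); each read comes from a uniformly chosen
bulk member's origin allele and flips to the other parental allele with
probability `error_rate` (default 0.01). The implementation uses the
marginally equivalent binomial thinning (Gd templates ~
Binomial(total, bulk Gd fraction), then error flips in each direction)
rather than a per-read loop; the distribution of `(gd_depth, vx_depth)` is
identical.

Defaults mirror the study conditions: a 48-member downward bulk and ~50x
coverage. `n_progeny` defaults to 150, a value of the package's choosing
(the source screens do not state the total progeny behind their bulk): under
1:1 segregation it makes a 48-member mutant bulk available with probability
$1 - 4\times10^{-6}$, i.e. essentially always, without being wasteful.
`error_rate = 0.01` stands in for the combined sequencing plus
alignment/genotyping error after filtering; 1% is typical of modern
short-read pipelines at this depth.

Reproducibility: a single integer seed in `cross_config()` seeds the R
random number stream once; all downstream draws consume that stream in a
fixed order, so `(config, seed)` determines every output byte.

## Linkage refinement

`recombination_fraction()` counts a segregant as recombinant when its marker
origin disagrees with the phenotype-implied origin at the causal locus
(down => Gd, up => Vx); $\hat r$ is the recombinant count over the
informative count. Using the phenotype as a perfect surrogate for the causal
genotype is exactly the logic that makes haploid bulk mapping valid;
simulations with `penetrance < 1` let tests probe what happens when it is
not. SSR-type length markers contribute nothing computationally distinct
from SNPs and are treated as ordinary codominant biallelic markers.

`refine_interval()` takes the per-marker counts, requires at least one fully
cosegregating marker (otherwise the locus is not in the genotyped region --
an error, not an empty interval), and returns the span from the nearest
flanking recombinant-bearing marker on each side. A missing flank extends
the interval to the chromosome end with a warning. The refined interval
always contains every zero-recombinant marker by construction.

Two practical notes on panels. First, with $n$ segregants a marker $d$ cM
from the locus cosegregates fully with probability $(1 - r(d))^n$; at
$n = 282$ even a 0.25 cM marker shows a recombinant about half the time, so
a panel whose markers are all strictly offset from the locus frequently has
*no* cosegregating marker and refinement correctly refuses. The package's
simulated refinement studies therefore include one panel marker at the
locus itself, reflecting the real workflow in which the candidate region's
own polymorphisms are genotyped. Second, interval width shrinks with
population size: the replicated tests verify that 282 segregants give a
narrower median interval than 48 on the same panel.

The two historical interval widths quoted for the motivating screen's
second mapping round disagree between the figure (283 kb) and the methods
text (238 kb); the discrepancy is in the source itself and is merely noted
here, not resolved.

## Variant effects

`classify_codon_change()` translates ref and alt codons with the standard
nuclear code: same residue => synonymous, residue to stop => stop_gained,
stop to residue => stop_lost, otherwise missense. The test suite checks all
4,096 codon pairs against an independent translate-and-compare oracle,
including the canonical lesions CAG>TAG and CAG>TAA (Gln to stop, written
`Q598X` at protein position 598) and the synonymous CAG>CAA and AGT>TCA.

`classify_variant()` places an SNV against single-isoform gene models:
intergenic outside every gene; UTR within transcript bounds but outside the
CDS span; inside an intron, splice_site within 2 bp of an exon boundary
(the canonical GT/AG dinucleotides) and intronic deeper in; inside the CDS,
the affected codon is located strand-aware (codon index
$\lceil \text{CDS offset} / 3 \rceil$), minus-strand genes being handled by
complementing the alternate base in CDS space. A non-synonymous change in
codon 1 is reported as start_lost. The 2 bp splice window is a package
choice: it captures the invariant donor/acceptor dinucleotides without
claiming to model branch points or exonic splice enhancers.

`filter_candidates()` implements the candidate rule -- keep missense and
stop_gained variants inside the mapped interval -- with an opt-in flag for
splice_site variants, off by default to match the stated rule. stop_lost
and start_lost are classified but not retained by default, since the rule
names only the two retained classes. Indels are out of scope; none of the
motivating alleles required them.

## Bending-angle summaries

`circular_summary()` bins angles over $[k b, (k+1) b)$, and reports the
circular mean $\operatorname{atan2}(\overline{\sin}, \overline{\cos})$
mapped to $[0, 360)$ together with the mean resultant length $\bar R$; for
$\bar R$ numerically zero (e.g. an antipodal pair) the mean is undefined and
reported as NA. Angles are reduced modulo 360 on entry; the sign convention
(which rotation direction is positive) is the caller's, since the summaries
are equivariant under rotation. `kinetic_summary()` uses the plain
arithmetic mean and sample SD per timepoint, matching how kinetic bending
curves are conventionally reported; this is defensible only while angles
stay well within one cycle, which gravitropic bending curves do.

## Numerical and degenerate-input choices

* Coordinates are 1-based and inclusive throughout; BED I/O converts at the
  boundary; sliding windows are half-open as described above.
* kb reporting divides by 1000 and rounds half-up to two decimals
  (4,642 bp prints as "4.64").
* Crossovers that round to the same bp cancel pairwise (an even number of
  exchanges at one point is no exchange), preserving recombination parity.
* A chromosome with fewer than two markers has genetic length 0 and
  segregates as a single block.
* `fragment_lengths()` on an empty site list returns the whole molecule;
  a site at the last position produces a zero-length end fragment rather
  than an error.
* Variants on an N reference base are rejected; N is otherwise allowed in
  genomes.
* Peak `peak_value` ties and window-mean ties resolve leftmost.

## What the simulations do and do not show

The generator reproduces the *sampling structure* of the study conditions:
haploid meiosis with a realistic crossover process, phenotype-driven bulk
selection, finite pool composition, Poisson depth and read error. It does
not emulate alignment artefacts, variant-calling bias, duplicated or
repetitive regions, segregation distortion, or marker ascertainment -- so a
passing suite shows the *computation* is correct under the stated model,
not that any particular real dataset would map as cleanly.

Replicated checks run at the study scale: a 20 Mb / 100 cM chromosome with
2,000 markers (plus a physically unlinked 10 Mb chromosome for the
baseline), 20 replicate crosses, 150 progeny each. One detail of geometry:
with the causal locus at the midpoint of a 100 cM chromosome no marker on
that chromosome is more than 50 cM away, so the "distant marker" baseline is
measured on the second, unlinked chromosome, where $r = 1/2$ exactly. The
end-to-end pipeline tests use a scaled-down 2 Mb chromosome with 300
markers and proportionally smaller windows (0.2 / 0.1 Mb), keeping the
marker density per window comparable.

## Limitations

* Single isoform per gene; overlapping genes resolve to the first model.
* One bulk, one phenotype contrast; no G' or SNP-index confidence envelopes.
* No statistical significance for peaks -- the threshold rule matches the
  original "approaches 1.0" criterion rather than a formal test.
* SNVs only in variant classification.
* The simulator's error model is symmetric per read; reference-bias
  asymmetries are not modelled.
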