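---
title: "Models and methods behind admixbreed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind admixbreed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

admixbreed characterizes the genome of a recently founded hybrid breed — the
motivating case is a wolfdog breed descending from German Shepherd dogs and
Carpathian wolves — from diploid SNP-array-style genotypes of the breed and
of reference samples of its two parental populations. Because real chip
genotypes for such breeds are rarely redistributable, the package pairs every
estimator with a forward simulator that produces genotypes, phased
haplotypes, a complete pedigree and exact per-haplotype ancestry tracks, so
each method can be checked against known truth. This vignette records the
models, the defaults and why they were chosen, the numerical decisions, and
the limits of what the simulation-based validation shows.

## The synthetic study

### Founder gene pools

Parental allele frequencies follow the Balding–Nichols divergence model: an
ancestral frequency $p \sim \mathrm{Beta}(1.5, 1.5)$ per site, then each
parental population's frequency drawn from
$\mathrm{Beta}\!\left(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\right)$ with
$F$ = `divergence_fst`. Under this model the Weir–Cockerham estimator applied
to samples of the two populations recovers $F$ itself, so the default
`divergence_fst = 0.35` puts the realized parental $F_{ST}$ in the
0.30–0.40 band — the divergence regime of a managed dog breed against a wild
wolf population. The mildly concave Beta(1.5, 1.5) keeps most sites at
intermediate frequency, as SNP-array ascertainment does.

Sites are evenly spaced; founders are drawn independently per site, so the
references carry no background LD. All LD in the breed therefore arises from
admixture and drift — exactly the signal the dating methods exploit, and the
main idealization to keep in mind (below).

Parental *reference samples* additionally receive within-population
inbreeding (allele-copying probability 0.10 for wolves, 0.15 for dogs,
giving heterozygosity $2pq(1-F)$). Real reference panels are an inbred breed
and a small wild population, and without this the panmictic references would
out-diversify the admixed breed.

### Breeding schedule

The default `cwd_schedule()` mirrors a wolfdog-like history on a 3-year
generation clock: F1 litters at generation 0 (1958); single new wolf sires
mated into 10% of litters at generations 1, 3, 5 and 8 (≈1960, 1968, 1974,
1983); heavy backcross waves into new dog dams (70% of litters) at
generations 2 and 4; closed breeding to generation 18 (≈2010). Census
declines linearly 40 → 20 and sires are drawn with Dirichlet weights at
concentration 1, a strong popular-sire effect. The backcross waves are what
keep the expected wolf fraction near 0.3 — with only wolf additions after an
F1 founding it would stay at or above one half, which is not how breeds of
this kind were actually built (hybrid litters were absorbed into the dog
population). Census sizes per year are not historically documented; the
40 → 20 decline is a free desk-scale choice, not an estimate.

Meiosis draws crossover counts as Poisson with mean equal to the chromosome's
genetic length (no interference), positions uniform on the genetic map, which
defaults to linear at 1 Morgan per 100 Mb. Ancestry segments are spliced
exactly at crossover breakpoints, so per-haplotype tracks, per-individual
wolf fractions, and junction counts are exact by construction.

Two founding modes exist. `founding = "f1"` (the historical default) makes
every founding litter a wolf × dog cross. `founding = "mixture"` draws the
founding generation from a randomly mating pool containing a fraction
`mixture_wolf_fraction` of wolves — the canonical single-pulse admixture
model. The distinction matters for dating: under mixture founding junctions
accrue at $2q(1-q)$ per Morgan per haplotype per generation from the first
generation on, which is the assumption behind the junction-dating formula,
whereas F1 founding makes the very first meiosis fully ancestry-heterozygous
and adds roughly $1/(2q(1-q)) - 1$ generations of upward bias to
switch-based dates. Calibration tests therefore use mixture founding; the
default pipeline keeps the historical F1 founding and inherits the same mild
bias the real analyses have.

Missingness is injected independently per call. The pipeline default is
0.04: that keeps every *sample's* call rate comfortably above the 95%
threshold (as in the motivating study, where all samples passed quality
control) while a realistic quarter to a third of *sites* fail, exercising
the call-rate filter. At 0.05 the sample call-rate distribution would sit
exactly on the threshold and survival would be a coin flip per sample.

### The default problem size

Tests and the acceptance script run on a 5-chromosome × 50-Mb genome with
2,000 sites per chromosome (10,000 sites, 2.5 Morgans), 20 breed individuals
in the final generation and 12 + 12 parental references; seed-loop tests use
a 2 × 600-site version. These sizes keep a full study under half a minute on
one core while leaving every estimator enough signal; a `preset = "full"`
founder model (38 autosomes, 2.2 Gb) is available for demonstrations.

## Filtering

The cascade reproduces standard chip practice: drop sex chromosomes (alias
list configurable — dog data sometimes labels X as "39"); drop samples, then
sites, with call rate ≤ 0.95 (the inequality is strict survival, read
literally from the usual "call rates ≤ 95% discarded" phrasing; sample-first
order is fixed and documented); LD-prune greedily in 50-SNP windows stepping
by 5, removing from each offending pair (`r^2 > 0.2`, genotypic dosage
correlation) the site with the lower call rate, ties removing the later
site. Window sweeps repeat until a pass removes nothing, which makes pruning
idempotent. Complete-case selection then keeps sites without any missing
call.

One practical finding is worth recording: *local-ancestry deconvolution must
not run on the LD-pruned set.* Admixture LD is exactly what pruning removes,
and doing so biases block ancestry toward 0.5 and halves the switch counts.
The pipeline deconvolves the complete-case subset of the quality-pruned
data, matching the practice of phasing the quality-pruned set.

## Statistics

* **Heterozygosity** is the fraction of called sites heterozygous; group
  values are means over members.
* **Inbreeding $F$** is method-of-moments:
  $(O_{hom} - E_{hom}) / (n - E_{hom})$ with $E_{hom}$ from per-site $2pq$
  under Hardy–Weinberg (no finite-sample correction), reference frequencies
  from the sample's own group unless supplied. Values are not clipped.
* **$F_{ST}$** uses the Weir–Cockerham (1984) per-site components $a, b, c$
  with site-specific sample sizes; the genome-wide value is
  $\sum a / \sum (a+b+c)$ (ratio of sums, the standard recommendation), and
  per-site values — which may be negative — are kept for marker selection.
  The test suite checks every per-site value against an independent
  three-level nested ANOVA (populations / individuals / gametes) computed
  with base `aov()` mean squares.
* **PCA** mean-imputes missing calls per site and centers dosages; frequency
  standardization ($\sqrt{p(1-p)}$) is available behind a flag but off by
  default, since plain centering is the more conservative reading of an
  "additive model" PCA.
* **IBD** is the PLINK-style method of moments from IBS counts and reference
  allele frequencies, without PLINK's finite-sample bias-correction factors;
  state probabilities are clamped to $[0,1]$ and renormalized, and pairs
  sharing under 100 called sites are flagged low-confidence.

Pedigree kinship is the classic recursion (founders $f = 1/2$ with
themselves); `COI` is parental kinship; `COR` is Wright's
inbreeding-normalized relationship, with the raw numerator relationship
$2f$ reported alongside because pedigree software differs in which it
prints.

## Runs of homozygosity

Detection is a greedy leftmost-maximal scan per sample and chromosome: a run
extends while it holds at most `max_het` heterozygotes and `max_missing`
missing calls and no adjacent-SNP gap exceeds `max_gap_kb`; the next run
starts after the previous ends, so runs never overlap. Raw runs are filtered
by `min_snps` and `min_kb`; coordinates are first-to-last SNP positions.
The defaults (25 SNPs, 500 kb, 1 het, 2 missing, 1 Mb gap) resolve the
1–7 Mb ROH regime of SNP-array breed data; the scanning parameters of the
commercial tools used in chip studies are generally unpublished, so these
are declared package conventions, all exposed in `roh_params()`.
$F_{ROH}$ divides summed run length by the SNP-covered genome span.
Shared-ROH regions are the interval intersection, across the chosen samples,
of each sample's run union (via IRanges), reported half-open 0-based as all
interval output is.

## Local ancestry

`build_reference()` cuts the site index into non-overlapping blocks of 10
consecutive SNPs within chromosomes (trailing partial blocks dropped), runs
a PCA of the pooled parental haplotype vectors per block, and stores the
class means and SDs of the parental scores on the top component. Blocks
whose class means differ by less than half a pooled SD are flagged
uninformative (SDs are floored at 5% of the overall score SD to handle
fixed blocks). `deconvolve()` projects each query haplotype, forms Gaussian
class likelihoods and equal-prior posteriors, and optionally smooths along
each chromosome with a two-state HMM whose switch probability between
adjacent blocks is $1 - e^{-g d}$ for block-midpoint gap $d$ Morgans and
prior $g = 10$ generations. Hard calls need posterior ≥ 0.8 (a common
deconvolution convention); everything else is uncalled. One principal
component suffices at these divergences; the Gaussian block model is the
simplest mechanism faithful to the block-PCA idea, and its accuracy is gated
by tests (block accuracy > 95% and mean $|\hat q - q_{truth}| < 0.03$ on the
default study, where it reaches ≈ 97–99%).

Genome-wide $q$ is the wolf share of called blocks (a length-weighted
variant is also reported). `supervised_q()` is the model-based-clustering
stand-in: it maximizes the binomial likelihood of dosages under per-site
mixture frequencies $q\,p_{wolf} + (1-q)\,p_{dog}$ by 1-D bounded
optimization (tolerance $10^{-6}$), with parental frequencies clipped away
from 0/1 by $1/(2n+1)$. With estimated (rather than true) parental
frequencies it shows the expected errors-in-variables attenuation toward
0.5 — the same reason cluster-based and block-based estimates disagree in
real studies — so the pipeline reports both.

Switch counts compare adjacent *called* blocks (uncalled blocks are skipped,
their flanking called blocks compared directly), summed over both haplotypes
and chromosomes; the count is invariant to chromosome processing order.
Ancestry-fixed blocks require unanimous hard calls across every haplotype of
the cohort; a single uncalled haplotype removes the block.

## Dating

**$N_E$ trajectory.** Within-chromosome pairs are binned by genetic distance
with edges $1/(2(t \pm \tfrac12))$ so bin $t$ represents $t = 1/(2c)$
generations of look-back (the Sved/Hayes convention); the bin mean $\bar r^2$
of genotypic $r^2$ is inverted through
$E(r^2) = 1/(1+4N_Ec) + 1/n$, where $n$ counts sampled chromosomes
(2 × individuals). Bins with no pairs or $\bar r^2 \le 1/n$ are flagged, not
extrapolated. The inversion round-trips exactly by construction, and a
constant-size Wright–Fisher simulation (N = 100, 40 generations, 20 sampled
individuals) is recovered within a factor of two in geometric mean over the
$t \in [4, 20]$ bins. With 50-Mb chromosomes the $t = 1$ bin is nearly
empty — a stated limitation of the desk-scale genome, not of the method.

**Weighted-LD decay.** For pairs $(i,j)$ within a chromosome the statistic
is $\mathrm{cov}(g_i, g_j)\,w_i w_j$ with weights $w = p_{wolf} - p_{dog}$;
drift LD is sign-incoherent under this weighting and averages out, while
admixture LD decays as $e^{-gd}$. Binned curves (default bin 0.005 M,
distances 0.001–0.3 M; the shortest pairs are excluded as founder/array
artefacts) are fitted with Levenberg–Marquardt least squares to
$a e^{-gd} + k$, with documented starts ($g_0 = 10$, $k_0$ = tail mean,
$a_0$ = first bin minus tail) and a chromosome bootstrap CI. A fitted
amplitude indistinguishable from zero flags $g$ unidentifiable. On
single-pulse simulations the estimate lands within ±30% of truth; on the
default multi-pulse breed history it lands between the founding and the last
introgression, as a single-pulse summary of a multi-pulse history must.

**Switch dating** uses the junction-count form
$g = 1 + S/(4Lq(1-q))$ — an F1 ($S = 0$) dates to $g = 1$, and junctions
accrue at $2q(1-q)$ per Morgan per haplotype per generation under
single-pulse random mating. The exact "modified" variants used with
commercial deconvolution output are not published, so the form is declared,
kept in one function for substitution, and calibrated against the simulator:
pooled over replicate mixture-founded simulations the median estimate is
within 25% of truth for $g^\ast \in [3, 15]$. Two known biases partially
offset in pipeline use: F1 founding inflates junction counts (above), while
block-resolution switch counting undercounts them.

Calendar conversion multiplies by a 3-year generation time from an explicit
reference year (no default — sampling year is study metadata the package
cannot guess).

**Drift accumulation** $p = \mu \times g \times N_E$ is provided as the
standard back-of-envelope check that mutation during a ~20-generation breed
history is negligible ($10^{-8} \times 20 \times 20000 = 0.004$).

## Outlier panels

Fixed-difference sites require per-site parental $F_{ST} = 1$ — opposite
fixation on called chromosomes. Among them, `aim_select()` keeps the lowest
1% quantile of per-site $F_{ST}$(breed, wolf) as "wolf-like" and of
$F_{ST}$(breed, dog) as "dog-like" (the quantile is taken *within the
fixed-difference set*; boundary ties are all kept and counts reported; a
site appearing in both panels is flagged). The block variant scores 10-SNP
blocks by the mean per-site $F_{ST}$ over their fixed-difference sites.
Panels expand to ±50 kb intervals (half-open 0-based, clipped at chromosome
ends, optional merging), and `consolidate_panels()` groups intervals from
all panels by transitive overlap, recording contributing methods and
direction, with direction conflicts kept as separate flagged records.

With minority wolf ancestry the dog-fixed blocks vastly outnumber wolf-fixed
ones across seeds, reproducing the qualitative asymmetry such breeds show.

## What the simulation does and does not establish

The simulator omits background LD in the parental populations, mutation
during the breed era, sex chromosomes, selection, genotyping error beyond
random missingness, and phasing error (deconvolution consumes truth-phased
haplotypes; statistically phased input is accepted via the haplotype TSV
interface but its switch errors are the user's to account for). Passing
tests therefore demonstrate estimator correctness under a neutral,
admixture-and-drift-only model at desk scale — they do not certify behaviour
under ascertainment bias, reference misspecification or phasing error. Two
further desk-scale effects are documented in the tests themselves: the
census (40 → 20) drifts harder than the real breed's effective sizes, so the
breed-above-parental-mean heterozygosity margin is small and holds on
average across seeds rather than in every replicate; and absolute $N_E$
levels track the simulated census, not the hundreds of the real breed's
early years.

## Determinism

Every stochastic entry point takes a seed; `run_pipeline()` fans a single
global seed out to fixed per-stage seeds so stages can be re-run in
isolation, and identical configs produce bit-identical reports and output
files.
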