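---
title: "Methods: microsatellite population genetics and ABC for a highly selfing weed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsatellite population genetics and ABC for a highly selfing weed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrabc)
```

# The problem

Glyphosate-resistant *Conyza canadensis* (horseweed) spread across
California's Central Valley within a few decades of intensive glyphosate
use.  Because the species self-fertilizes almost completely, a resistant
plant founds a near-clonal lineage whose multilocus microsatellite genotype
(MLG) travels with its wind-dispersed seed.  Two questions drive the
analysis this package implements: did resistance arise once and spread, or
arise independently in several lineages; and when did resistant lineages
start expanding relative to the onset of glyphosate use?

The package covers the full chain: genotype IO and quality control,
descriptive diversity and differentiation statistics, MLG identification
and lineage classification, survival-assay summaries and their correlation
with a regulatory covariate (groundwater protection areas, GWPA), and
coalescent-based approximate Bayesian computation (ABC) over competing
demographic scenarios.

# Genotype data and quality control

Genotypes are diploid microsatellite calls stored as allele *repeat counts*
(not fragment lengths): the generalized stepwise mutation model and the
"single repeat unit" lineage logic both operate in repeat units.  GenePop
and delimited-table dialects are supported with code `000` for missing;
a call with a single recorded state is scored as a homozygote (the standard
microsatellite convention — whether partially amplified calls occurred in
the original scoring is not knowable, so this is a convention, not a claim).
Individuals whose profile shows three or more allele states at a locus
(putative hybrids with a co-occurring hexaploid congener) are flagged and,
under the default policy, dropped before analysis.

# Descriptive statistics

* **F-statistics** follow Weir & Cockerham's (1984) variance components.
  Multi-locus values are ratios of summed components, never averages of
  per-locus ratios, matching FSTAT.  A brute-force transcription of the
  published formulas serves as the oracle in the test suite (agreement to
  1e-12).  One consequence worth knowing: on a 4-individual sample in exact
  Hardy-Weinberg proportions (1 AA, 2 Aa, 1 aa) the small-sample estimator
  gives F_IS = 1/7, not 0 — the finite-sample correction is not a bias.
* **F_ST significance** permutes whole multilocus diploid genotypes among
  populations (random mating is not assumed in a selfer); **F_IS
  significance** permutes alleles among individuals within populations.
  Pairwise tests across many population pairs use Bonferroni division of
  the significance level by the number of pairs tested.
* **Allelic richness** uses hypergeometric rarefaction to twice the
  smallest per-population complete-genotype count (FSTAT's behavior),
  averaged over loci.
* **Selfing rate** is the inbreeding-equilibrium transform
  s = 2F_IS/(1+F_IS); populations monomorphic after missing-data handling
  report missing F_IS and s rather than a number.
* **Nei (1972) distance** is computed from gene identities summed over
  loci, with locus bootstrap support and a PHYLIP lower-triangular export
  for external tree programs (tree search itself is out of scope).  A pair
  sharing no allele anywhere has infinite distance and is reported as an
  `Inf` sentinel (999.9999 in the PHYLIP export).
* **Garza-Williamson M** is k/(r+1) per population and locus.  The +1
  convention keeps M in (0, 1] and gives monomorphic loci M = 1; the
  alternative k/r convention diverges there, which is why we fixed this
  one.
* **Assignment likelihoods** (Rannala-Mountain) use Dirichlet(1/k)
  posterior-mean allele frequencies with leave-one-out for an individual's
  own population, so alleles absent from a reference population keep the
  likelihood finite.

# MLG identification and lineage classification

Individuals sharing a canonical genotype string (sorted allele pair per
locus) share an MLG.  Under the default `strict` policy individuals with
any missing call are excluded from matching, because exact sharing counts
over complete profiles are the quantity of interest.

Within a highly resistant population (R >= 0.95 by default), each MLG is
compared with the *more abundant* MLGs present there:

* **single_step_variant** — exactly one locus differs, by exactly one novel
  allele one repeat unit away from a parental state, and that allele occurs
  nowhere else in the population.  This is the signature of a single
  microsatellite mutation within the same selfing lineage, whether still
  heterozygous or already fixed by selfing.
* **recombinant** — every differing locus matches some more abundant MLG
  and no single parent explains all loci, so at least two parents are
  required: the signature of an outcross between resident lineages followed
  by selfing.  A fresh F1 (heterozygous at the differing loci) matches
  neither parent locus-wise and is deliberately *not* called recombinant;
  the rule targets selfed descendants, which is what a survey of
  established lineages observes.
* **nonrecombinant** otherwise; ambiguous configurations fall to
  `unclassified`.

The published source for this classification describes it only verbally;
the rule above is this package's documented interpretation, and ties break
toward `unclassified`.

# Resistance phenotypes

Population-level resistance R is the mean over assay replications of the
per-replication survivor proportion.  Where only pooled totals are
available the pooled ratio is used; the two differ when replication sizes
differ (30/15 + 20/12 gives R = 0.55, not 27/50 = 0.54), which is why the
bundled survey table carries the published per-population R alongside the
totals.  The GWPA association is a plain Pearson correlation with the
two-sided t test, via `cor.test`.

# The demographic model

All scenarios share a skeleton: two ancestral gene pools of effective size
N_e diverge from a single root at `ta`.  Every sampled deme attaches to its
pool at its own divergence time.  Susceptible populations are sampled as
two closely related lineages from the same pool (equal halves of the
sample), each with its own bottleneck start time, and *remain* at the
bottleneck size N_b until the present.  Resistant demes drop from N_e to
N_b at `t_i` and expand to N_r at `t_i - b_i` (the onset of resistance
spread), with `t_i > b_i` enforced.  Scenario families differ in how
resistant demes originate:

* independent origins (no admixture);
* historical admixture — the deme is created by admixture between the two
  pools at a time older than 40 generations (before glyphosate);
* recent admixture — the deme is created 1-40 generations ago from two
  other resistant demes, and is expanded (N_r) from creation, since in
  these scenarios admixture immediately precedes the expansion.

Set A has 2 susceptible + 2 resistant populations and seven scenarios
(independent; historical into P3 / P4 / both; recent into P4 / P3 / both),
sets B and C have five each (B: 2 susceptible + 3 resistant, recent
admixture into P5 from P3+P4 or into P4 from P3+P5; C: 1 susceptible + 4
resistant, analogous).  The published figure defining these graphs shows
topologies only; donor/target assignments here are the package's
reconstruction from the accompanying text, and the scenario builder is
config-free precisely so the reconstruction is explicit and testable.

**Priors.**  N_e ~ U(10, 10^4); N_b ~ U(2, 100); N_r ~ U(10, 10^5);
bottleneck starts U(1, 150) generations (agriculture intensified roughly
120 years before sampling; one generation per year for this annual);
divergence times uniform between each deme's bottleneck start and 10^4,
with the root above them all (and above 160, so the pools predate the
management era); recent admixture times U(1, 40) (glyphosate era);
historical admixture U(41, 10^4) truncated below the root; admixture rates
U(0.001, 0.999); locus mutation rate log-uniform on (10^-5, 10^-4) — one
tenth of the conventional microsatellite mean-rate band, reflecting the
reduced effective rate under near-complete selfing; GSM geometric
coefficient P ~ U(0.10, 0.70).  Draws are rejection-sampled until the
order constraints hold.  Selfing is not modeled genealogically; the
two-lineage susceptible structure and the scaled mutation rate are the
standard workaround, reproduced here deliberately.

**Simulator.**  Per locus, a structured coalescent runs backward through
the event list (size changes, merges, admixture moves), then mutations are
Poisson on branches with geometric step sizes, equiprobable direction, and
reflection into a 40-state window with the root allele at state 20 (the
usual bounded-ladder convention).  Diploids pair two independent gene
copies.  Closed-form checks in the suite: E[T2] = 2N for a constant deme,
and Ohta-Kimura homozygosity 1/sqrt(1+2\theta) in the single-step limit.

# The ABC engine

The selection/estimation statistic vector is: per-population mean allele
number and mean M; pairwise Weir-Cockerham F_ST; and ordered-pair mean
assignment log-likelihoods.  Undefined pairwise F_ST on a monomorphic pair
is imputed as 0 to keep vectors finite.  Genic diversity, allele-size
variance and shared-allele distance are *never* in this vector: they are
reserved for the posterior predictive check, so goodness-of-fit is not
assessed with the statistics that drove the fit.

* **Scenario choice.**  Rows are ranked by Euclidean distance on z-scored
  statistics (ties by row index); the closest fraction (10% by default for
  five-scenario sets, 7% for seven — the same fractions as the study's
  70 000 / 50 000 of one million) enters a weighted multinomial logistic
  regression with Epanechnikov weights, evaluated at the observed point.
  Confidence intervals come from the delta method on the fitted intercepts.
* **Numerical choice: slope ridge.**  With ~40 statistics and desk-scale
  retained sets (hundreds to thousands of rows, not tens of thousands) an
  unpenalized local logistic fit quasi-separates and an unpenalized local
  linear adjustment overfits.  Both local regressions therefore carry a
  ridge on the z-scored slope coefficients only — intercepts are never
  penalized, so fitted class odds and posterior locations stay unbiased.
  Defaults (2 for the logistic, 25 for the linear adjustment) were set so
  that exchangeable scenarios split evenly on average and 90% credible
  intervals cover prior-drawn truths at nominal rate in the suite's
  calibration tests; `ridge = 0` recovers the unpenalized fits.
* **Confidence in choice.**  For each true scenario, pseudo-observed
  datasets are simulated from the prior and classified by max posterior;
  Type I for a scenario is 1 minus its self-selection frequency, Type II
  the mean rate at which it is selected when false, with optional grouped
  rates (no-recent-admixture vs recent-admixture).  How exactly the
  original analysis combined grouped rates is not published; the grouped
  definitions here are documented and tested on their own terms.
* **Parameter estimation.**  Beaumont-style local-linear adjustment on
  transformed parameters (log for sizes, times and mutation rates; logit
  within prior bounds for admixture rates and P), with the weighted sample
  summarized by mean, median, weighted-KDE mode and credible bounds.
  A singular design falls back to the unadjusted rejection sample with a
  warning.  Adjusted draws may fall outside the prior box; the model check
  redraws when an adjusted vector is not simulable.
* **Model check.**  Datasets are simulated with parameters drawn from the
  weighted posterior; each held-out statistic's two-tail rank probability
  is adjusted across statistics with Benjamini-Hochberg (`p.adjust`).

# The synthetic-data generator

The generator exists so every stage has ground truth without any download.
It emulates the study conditions: 42 populations x 30 diploids x 12 loci;
selfing probability 0.96; founders drawn per population from a shared
regional pool of homozygous lineages (drawn from a two-pool coalescent, one
gene copy doubled), so MLGs are shared across populations; forward
propagation for 20 generations with single-step mutation at 1e-4 per copy;
a log-normal county covariate tied to the resistance frequency through a
logistic link.  Where the study fixes no value we chose once: 3 founders
per population and a 60-lineage pool give the observed "few MLGs per
population, many shared" texture; 20 generations is enough to approach
inbreeding equilibrium at s = 0.96 (F = s/(2-s) = 0.923) so the
selfing-rate recovery test is meaningful.

What it does **not** emulate: locus-specific mutation-rate scatter, allele
frequency spectra of the real survey, linkage, null alleles, or scoring
error.  A green suite therefore shows the estimators and the inference
machinery are correct on data satisfying the model's assumptions — not that
the model captures every feature of field data.

# Problem sizes and numerical conventions

The suite and the acceptance script run everything from scratch on one
CPU: reference tables of 10^4 rows per scenario with 100 pseudo-observed
datasets per true scenario for the confidence analysis; 3 x 10^3-row
tables with 50 repetitions for coverage; 8 x 10^3 replicate loci for the
mutation-model checks; 200 replicate datasets for permutation calibration.
These sizes were chosen so each check's Monte-Carlo error is several times
smaller than the tolerance it asserts.  Other conventions: permutation
p-values are (1 + exceedances)/(n + 1); rarefaction uses `lchoose` to
avoid overflow; distances use ties-by-row-index so reruns are
deterministic; all randomness flows through R's RNG (including inside the
compiled simulator), so a single `set.seed` reproduces any result
bit-for-bit.

# Known limitations

* Scenario topologies are a reconstruction (figure-only source); anyone
  comparing against the original software should expect agreement in kind,
  not row-for-row posterior probabilities.
* One shared N_e stands in for per-deme ancestral sizes, and all loci share
  one mutation rate; both are deliberate simplifications of the original
  tool's defaults.
* The recombinant/variant classification is a heuristic pattern match; on
  shallow pedigrees it is conservative (fresh F1s are nonrecombinant by
  design).
* Printed survey tables carry replication-mean resistance values that
  pooled totals cannot always reconstruct; analyses consume the published
  R column for that reason.

# A minimal run

```{r example, eval = FALSE}
set.seed(1)
cfg <- synth_config(n_populations = 6, n_individuals = 20, n_loci = 12,
                    n_generations = 8)
g <- generate_genotypes(cfg)
ph <- generate_phenotypes(cfg, g$truth)
run_descriptive(g$genotypes, run_config(out_dir = "out", seed = 1,
                                        n_perm = 100, n_boot = 100),
                phenotypes = ph$table)

scens <- setNames(lapply(paste0("B", 1:5), build_scenario), paste0("B", 1:5))
obs <- simulate_dataset(scens$B4, draw_params(scens$B4), 12)
res <- run_abc(obs, scens,
               run_config(out_dir = "out", seed = 1, n_per_scenario = 2000,
                          n_pods = 20))
res$posterior
```
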