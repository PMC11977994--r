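---
title: "Methods: genetic evidence enrichment for labeled side effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic evidence enrichment for labeled side effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetse)
```

## The question and the unit of analysis

Drugs inhibit or activate protein targets, and human genetic variation in
the genes encoding those targets causes or predisposes to phenotypes. If a
target gene is genetically associated to a trait, engaging that target
pharmacologically may reproduce the trait as an on-target side effect
(SE). `targetse` quantifies this: across the universe of all
(drug, SE-term) pairs — the cross product of drugs with at least one human
target and approved indication against the distinct SE terms appearing on
any label — it asks whether a pair is more likely to be *observed* (the SE
appears on that drug's label) when the drug carries *genetic evidence* for
the SE, meaning some target gene is genetically associated to a trait
highly similar to the SE term.

Everything downstream is computed on this pair universe: the base rate is
the fraction of pairs observed, and the primary statistic is the exact
Fisher odds ratio of the observed-by-evidence 2×2 table.

## Ontology similarity

SEs, indications and genetically associated traits are all terms of one
disease ontology (MeSH-like: a DAG with multiple parents, a set of
designated top-level headings serving as disease areas). Similarity
between terms combines two information-content measures. With an
annotation corpus giving each term a usage count, a term's probability is
its cumulative (self plus descendants) count over the corpus total, and
its information content is IC = −log p (natural log; the base cancels in
Lin and is absorbed by the rescaling multiplier in Resnik). Then for a
pair (a, b):

* **Resnik** = IC of the most informative common ancestor (MICA), where a
  term is its own ancestor;
* **Lin** = 2·IC(MICA) / (IC(a) + IC(b)), in [0, 1].

Because Resnik is on the (unbounded) IC scale, it is rescaled before
averaging: both scores are floored at 0 and a zero-intercept
least-squares regression of Lin on Resnik over all unordered term pairs
(including the diagonal) gives a multiplier m = Σ(lin·resnik)/Σ(resnik²);
the combined score is (Lin + min(1, m·Resnik)) / 2. The direction of the
regression and the zero intercept are a design choice — the requirement
is only that the two scores share a 0–1 range with unit slope — and the
diagonal is included so that self-similarity anchors the top of the
scale.

Degenerate cases are fixed by convention: pairs with no common ancestor
score 0; a root compared with itself scores Lin 1 despite the 0/0 ratio;
any other pair with IC(a)+IC(b)=0 scores 0. By default every term's
direct count receives add-one (Laplace) smoothing so that IC — and hence
similarity — is defined for all ontology terms; disabling smoothing
leaves zero-count terms flagged `NA` and excluded.

## Confounder filters

Two filters guard the headline odds ratio, both with inclusive (≥)
thresholds:

* **Genetic insight** (`insight_config()`): an SE only enters the
  analysis if it has plausibly *been studied* genetically — otherwise the
  absence of evidence is uninformative and SEs similar to well-studied
  traits would be over-represented among evidence pairs. A trait
  qualifies if it has ≥ 1 Mendelian/somatic-driver gene (OMIM ∪ IntOGen)
  or ≥ 3 GWAS hits at distinct loci (chromosome plus position rounded to
  the nearest megabase, `mb_bin()`); an SE has insight if it, or any
  trait with similarity ≥ 0.8 to it, qualifies. Gene-burden evidence
  (Genebass) has no locus and counts toward neither rule by default; that
  attribution is configurable because the convention is not settled.
  GWAS-type sources for locus counting are OTG and PICCOLO.
* **Similar indication** (`theta_indic`, default 0.9): SEs can co-occur
  with the disease being treated rather than being caused by the drug. A
  pair is excluded when any approved indication of the drug has
  similarity ≥ 0.9 to the SE; independently, an association whose trait
  has similarity ≥ 0.9 to an indication is disqualified *per association,
  before the drug-level maximum* when flagging evidence — a literal
  reading of the rule that evidence requires SE-trait similarity ≥ 0.9
  while trait-indication similarity stays < 0.9.

Both filters are monotone (raising `theta_indic` removes fewer pairs;
raising `theta_assoc` flags fewer evidence pairs), they commute, and the
sweeps in `sweep_assoc_threshold()` / `sweep_indic_threshold()` expose
the sensitivity of the OR to each threshold with the other held fixed.

## Statistics

* `fisher_or()` implements conditional exact inference for the 2×2 odds
  ratio: the conditional MLE under the noncentral hypergeometric model,
  the exact two-sided p (summing outcomes no more likely than the one
  observed), and the CI from inverting the one-sided tails at α/2. Root
  finding is bisection on log odds to below 1e-9 relative error; the
  crude sample OR is reported alongside. Zero-cell tables give 0 or
  infinite estimates with one-sided CIs; empty margins are an error.
* `cmh_across_areas()` stratifies the 2×2 by the SE's top-level heading.
  "A heterogeneity test across the stratified tables" conflates two
  things, so both are reported: the Mantel-Haenszel common OR with its
  chi-square test of common association, and the Breslow-Day test (with
  Tarone correction, hand-implemented) for heterogeneity of ORs.
* Binomial logits use `stats::glm` (IRLS, tolerance 1e-8, max 100
  iterations). For per-pair covariates the model is
  `observed ~ evidence * covariate`; for attributes defined only on
  observed pairs (numeric frequency, frequency words, placebo basis) the
  conditional model is `evidence ~ covariate` over observed carriers.
  Frequency words are either ordered factors (polynomial contrasts:
  linear plus higher-order terms) or numeric ranks; the vocabulary and
  its order are configuration (`default_freq_words()` is a placeholder
  ordering, since empirical orderings come from external surveys).
  Complete separation aborts with an error rather than reporting an
  unidentifiable unpenalized fit.
* `target_se_enrichment()` screens every (target gene, SE) combination by
  a Fisher test over drugs, with Benjamini-Hochberg adjustment across all
  tested combinations and an enrichment call at OR ≥ 2 and FDR < 0.05.
  Targets carried by a single drug are flagged untestable.
* Predictive values are plain count ratios: PPV = observed-with-evidence
  / evidence pairs; NPV = unobserved-without-evidence / non-evidence
  pairs. No odds-ratio identity is assumed; the fields are recomputed by
  direct counting.

Binned breakdowns (`specificity_bins()`, `severity_bins()`,
`area_bins()`, `modifier_bins()`) share one summary shape: per-bin pair
counts, base rate, PPV/NPV and the exact OR. Default specificity edges
are 1, 2–9, 10–99, 100+ and default numeric-frequency cuts are ≤ 1%,
1–10%, > 10%; both are configurable, as published analyses differ in
exactly where these cuts sit. Severity quartiles come from the empirical
rank distribution of ranked SEs, with unranked SEs kept as an explicit
"unassigned" bin rather than dropped. An SE under several top-level
headings counts in every area (the ontology is a DAG; choosing one parent
would be arbitrary), and `area_bins(remove_same_area_indication = TRUE)`
additionally drops, within each area, every drug indicated in that area.

## The synthetic study

`simulate_dataset()` generates the complete input set with known ground
truth, at a desk scale that runs in about a second:

* a layered random DAG (300 terms, depth 5, 8 top-level headings; deeper
  terms attach to 1–2 parents in the previous layer) with a long-tailed
  (log-normal) annotation corpus;
* 200 genes and 150 drugs with 1–3 targets and 1–3 approved indications
  each; Poisson(3) gene-trait associations per gene with source labels
  drawn from a fixed mix and random loci for GWAS-type sources;
* SE observation per pair from
  `logit(P) = alpha + beta_evidence·E + gamma_indic·I`, where E indicates
  a target association with similarity ≥ 0.9 to the SE and I an
  indication with similarity ≥ 0.9 — the confounder the indication filter
  is designed to remove. Crucially, the generator's notion of "similar"
  is the package's own combined similarity, so planted effects are
  defined in the same metric the pipeline tests. Defaults plant
  `beta_evidence = log 2` (the conditional OR of 2 the analysis should
  recover), `gamma_indic = log 3` (strong confounding), and
  `alpha = qlogis(0.05)`, which with the two planted effects yields a
  marginal base rate near the 5% regime the analysis operates in;
* modifiers on observed records only: per-SE severity ranks coupled to
  drug specificity with slope −0.5 on the log scale plus unit noise (so
  more severe SEs are observed for fewer drugs, weakly), Beta(1.2, 8)
  numeric frequencies, frequency words cut from the same latent
  frequency, Bernoulli placebo flags, each present at realistic
  missingness rates (25% of SEs unranked; 40%/30%/50% of records carrying
  a numeric frequency / word / placebo flag).

The truth record keeps all planted parameters and per-pair latent flags,
and `truth_eval()` reports estimate bias, CI coverage and the confusion
of flagged versus latent evidence.

What the generator does *not* emulate: real MeSH topology (depth,
fan-out, the disease/non-disease split), empirical label frequency
spectra, drug-class structure (shared chemistry between drugs sharing a
target), direction-of-effect annotations, or name-mapping noise between
source databases. Passing tests therefore demonstrate that the machinery
is correct and calibrated under the stated generative model, not that the
real-data effect sizes are reproduced — the published joined dataset is
partly commercial and is out of scope here.

## Verification strategy and problem sizes

The test suite checks the two numerical workhorses against independent
brute-force oracles: exact Fisher OR/p/CI against direct fixed-margin
enumeration on every 2×2 table with total ≤ 60 (p to 1e-10, CI endpoints
to 1e-6 relative; table symmetries are verified across the full set and
the oracle is run on one representative per symmetry orbit), and
Lin/Resnik against common-ancestor enumeration on random ontologies of up
to 50 terms. Calibration is checked by simulation: 200 replicates of the
default study at ~50,000 pairs must recover `beta_evidence = log 2` with
absolute log-OR bias below 0.1 and 95%-CI coverage between 90% and 98%,
and a global-null screen (both planted effects zero; 30 replicates of a
smaller 60-drug configuration) must keep the BH-controlled target-SE
discovery proportion at or below 7%. These sizes keep the whole suite in
the minutes range on one CPU.

## Known limitations

* The conditional-MLE OR differs from the sample OR in small or extreme
  tables; both are reported, and published sample ORs will not match the
  conditional MLE exactly.
* Insight propagation uses a single similarity threshold (0.8); graded
  propagation is not modeled.
* The per-association indication disqualification and the pair-level
  exclusion share one threshold by default; they are conceptually
  distinct and can be decoupled only by editing `flag_evidence()`.
* Multi-parent terms contribute to every disease area, so per-area counts
  do not sum to the universe size by design.
* The generator plants evidence through exact-similarity thresholds, so
  threshold-sweep inflections in synthetic data are sharper than real
  ones.
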