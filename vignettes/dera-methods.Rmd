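---
title: "Sample-specific regulation networks and core regulations with dera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-specific regulation networks and core regulations with dera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dera)
```

## The method

Bulk differential-expression analysis averages over a cohort and blurs
exactly the heterogeneity that distinguishes individual tumors. `dera`
takes the opposite route: it characterizes **each sample** by the set of
prior regulatory relationships that its own expression profile supports,
and only then aggregates across a phenotype group.

The procedure has four steps.

1. **Prior network.** A signed directed network of regulations
   (source gene, effect in {activation, inhibition}, target gene) is read
   from a SIF-style edge list. A regulation is identified by the full
   triple, so a curated pair carrying both an activation and an inhibition
   contributes two regulations, each evaluated independently.

2. **Gene-activity indicator.** For gene $i$ in tumor $j$, the log2 fold
   change is
   $$f_{ij} = x_{ij} - \frac{1}{n}\sum_{k=1}^{n} y_{ik},$$
   the tumor's log2 expression minus the gene's mean log2 expression over
   the $n$ reference (control) samples. The ternary indicator is
   $$I_{ij} = \begin{cases} +1 & f_{ij} \ge \log_2 K \\
   -1 & f_{ij} \le -\log_2 K \\ 0 & \text{otherwise,} \end{cases}$$
   with fold-change cutoff $K = 2$ by default (the conventional two-fold
   difference). Over-expression is $+1$; the subtraction is oriented so
   that a tumor above the reference mean gets a positive fold change.

3. **Sample-specific regulation networks.** A regulation $A \to B$ is
   included in sample $j$'s network iff both genes are differentially
   expressed ($I_{Aj} \neq 0$, $I_{Bj} \neq 0$) and their signs are
   consistent with the effect: equal signs for an activation, opposite
   signs for an inhibition. The retained unit is a **regulation
   instance** — the edge plus its concrete sign pattern — so an edge seen
   as (+1, +1) in one sample and (−1, −1) in another yields two distinct
   instances.

4. **Core regulations.** Within a phenotype group of $m$ samples, an
   instance present identically in at least $T\,m$ sample networks
   (inclusively; default $T = 0.5$) is a core regulation. The core set is
   decomposed into subnetworks — connected components of the undirected
   graph on the core genes — and can be compared between groups (set
   difference of instances) or validated in an independent cohort
   (recompute the core there, typically at a slightly lower $T = 0.4$ for
   small or heterogeneous cohorts, and intersect). The expression of a
   regulation in a sample is the sum of its two genes' fold changes.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `K` | 2 | fold-change cutoff on the linear scale; the indicator thresholds at $\pm\log_2 K$, inclusively |
| `T` | 0.5 | fraction of a group's samples (all of them, including samples with empty networks) an instance must reach |
| `reference_label` | `"REFERENCE"` | phenotype token marking control samples |
| `T_validation` | 0.4 (convention) | threshold used when recomputing the core in a validation cohort |

Raising `K` can only delete or keep indicator calls, never flip them, so
each sample's instance set shrinks monotonically in `K`; likewise the core
set shrinks monotonically in `T` (`t_sweep()` reports the whole curve).

## Numerical and design choices

* **Fold-change orientation.** Over-expression must come out as $+1$, so
  the subtraction is tumor minus reference mean. This is fixed, not
  configurable.
* **Inclusive boundaries.** Both the indicator ($|f| \ge \log_2 K$) and the
  core threshold (frequency $\ge T$) are inclusive, reading "at least a
  two-fold difference" and "at least $T\%$ of samples" literally.
* **Missing values.** A missing tumor measurement yields a missing fold
  change and an indicator of 0: a gene that was not measured cannot
  support a regulation. Reference means and row means ignore missing
  entries.
* **Mean-centering.** `preprocess()` centers each gene across all samples
  passed in (tumors and references jointly). Because `fold_change()`
  subtracts the per-gene reference mean, centering cannot change any
  indicator value; it is provided as the conventional preparation of
  log-intensity data and for visualisation.
* **Multi-probe genes.** The probe filter removes probes mapping to zero
  or to several genes. Several surviving probes for one gene are collapsed
  by the mean (configurable via the `collapse` argument); the filter rule
  itself concerns multi-*gene* probes, so the collapse policy is a
  separate, documented default.
* **Contradictory prior edges** (both effects between the same pair) are
  both kept; each is a distinct regulation and at most one of the two can
  be consistent in any given sample.
* **Self-loops** are permitted: a self-activation fires whenever the gene
  is differentially expressed at all, while a self-inhibition can never be
  sign-consistent and is structurally dead — it is kept in the network and
  reported, never silently dropped.
* **Genes in the network but absent from the expression matrix** get state
  0 (with a one-time warning), so an incomplete expression platform
  deflates, but never inflates, sample networks.
* **Specificity level.** Group comparison subtracts at the instance level
  by default: the same edge carried with opposite sign patterns in two
  subtypes *is* a subtype-specific finding. An edge-level mode
  (`level = "edge"`) is available where the coarser question is wanted.
  The same flag exists for cross-cohort validation.
* **Component numbering.** Subnetworks are numbered by decreasing gene
  count, ties broken by the lexicographically smallest member gene, so
  output ordering is deterministic and diff-stable.
* **Undirected protein–protein edges** have no defined consistency rule
  here and are out of scope; no rule was invented.

## The synthetic cohort generator

`synthetic_spec()` / `generate_cohort()` emulate the data regime the
method assumes: log2-scale intensities, a reference set defining per-gene
baseline, and regulations whose two genes shift together. Per sample,
each planted regulation assigned to the sample's group (or shared by all
groups) is activated with probability equal to its prevalence — a
per-sample, per-instance independent Bernoulli draw, which matches the
frequency semantics of $T$ directly — and, when active, shifts its source
by `source_state * effect_size_log2` and its target by
`target_state * effect_size_log2`. Independent Gaussian noise
(`noise_sd_log2`, default 0.3) is added to every value.

The defaults are chosen to be realistic for log-intensity array data and
analytically transparent: with an effect size of 2.0 log2 units against
the $\log_2 2 = 1$ cutoff, an active gene's fold change fails the
threshold only when the combined noise (SD
$\sigma\sqrt{1 + 1/n}\approx 0.31$) pushes it more than one unit down — a
$\approx 3.2$-SD event, probability well under $10^{-3}$ — so
instance-level presence tracks the nominal prevalence almost exactly, and
an inactive gene false-fires with similarly negligible probability.

Two structural guarantees make exact-recovery tests meaningful:

* planted regulations occupy pairwise-disjoint gene pairs, so shifts never
  overlap; and
* background network edges avoid pairs lying entirely within the planted
  gene set. Without this exclusion, a stray prior edge between two planted
  genes would inherit their differential expression and appear as a core
  regulation at a prevalence the spec never asked for.

Randomness is split into a `structure_seed` (network topology and the
concrete planted instances) and a `seed` (activations and noise), so
cross-cohort experiments can share structure while drawing independent
cohorts. Regeneration with the same spec and seeds is bit-for-bit
identical.

What the generator does **not** emulate: dye/batch artifacts, count-based
RNA-seq noise, correlated co-expression beyond the planted edges, and
overlapping regulatory programs (planted gene sets are disjoint by
construction). Passing recovery tests therefore demonstrates the
correctness of the discretization–overlay–thresholding machinery under
its stated assumptions, not robustness to real-array pathology.

## Problem sizes used in the test suite

The suite exercises randomized instances of up to 50 genes, 80 edges and
25 samples against naive loop-based reference implementations (100
replicates), planted-recovery cohorts of 30 genes / 50 edges / 40 samples
over 20 seeds, four-group specificity designs of 80 genes / 120 edges /
100 samples over 10 seeds, and paired discovery–validation cohorts over
10 seeds. These sizes give every stage multiple independent random
draws while keeping the whole suite comfortably interactive.

## Worked example

```{r example}
spec <- synthetic_spec(
  groups = c(case = 40L),
  planted = data.frame(group = c("case", "case"), n = c(5, 5),
                       prevalence = c(0.7, 0.2)))
cohort <- generate_cohort(spec, seed = 1)
fit <- dera(cohort$network, cohort$expression, cohort$phenotype,
            group = "case", K = 2, T = 0.5)
fit
```

The five instances planted at prevalence 0.7 are recovered; the five
decoys at 0.2 are rejected:

```{r check}
core_keys <- with(fit$core, paste(source, effect, target, source_state))
truth <- cohort$truth[cohort$truth$prevalence > 0.5, ]
setequal(core_keys,
         with(truth, paste(source, effect, target, source_state)))
```

```{r sweep, fig.width = 5, fig.height = 4}
plot(fit, which = "sweep")
```

## Limitations

* The method detects only what the prior network contains; it cannot
  propose novel edges, and its output quality is bounded by the prior's.
* No significance measure is attached to a core regulation; $T$ is a
  prevalence cutoff, not a test. Frequencies near $T$ are unstable in
  small cohorts — hence the convention of lowering $T$ for validation
  rather than demanding the discovery threshold again.
* A two-fold cutoff on log2 intensities is a platform convention, not a
  calibrated quantity; `K` should be reconsidered for other data types.
* Samples are treated as exchangeable within a group; no covariates,
  batch structure or within-patient correlation are modeled.
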