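---
title: "Decision-tree case quizzes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-tree case quizzes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephroquiz)
```

## The problem

Renal-biopsy diagnosis is taught by pattern: a nephropathologist weighs a
set of categorical findings — histology, immunofluorescence,
immunohistochemistry, clinical data — and arrives at one of a few dozen
nosological entities. When expert-labelled case reports are tabulated as a
categorical case table (one row per report, one column per finding, one
diagnosis column), a decision tree induced from that table makes the
expert's implicit question ordering explicit: each internal node is the next
most informative question, and each root-to-leaf path is a minimal line of
questioning that ends in a diagnosis. `nephroquiz` turns that observation
into a teaching loop: induce the tree, validate it, convert every path into
a quiz, grade learners against the tree's flow, and rank a cohort.

Nothing in the machinery is specific to nephropathology: any case table of
nominal attributes with a single class column works.

## Tree induction

The inducer is the classical C4.5 recipe for nominal attributes. At a node
holding class counts $n_1,\dots,n_K$, the impurity is the Shannon entropy

$$H = -\sum_{i\,:\,n_i>0} \frac{n_i}{n}\log_2\frac{n_i}{n},$$

and a candidate attribute $A$ with observed values $v$ partitioning the node
into subsets of size $n_v$ is scored by its information gain
$\mathrm{IG}(A) = H - \sum_v \frac{n_v}{n} H_v$, its split information
$\mathrm{SI}(A) = -\sum_v \frac{n_v}{n}\log_2\frac{n_v}{n}$, and the gain
ratio $\mathrm{IG}/\mathrm{SI}$, which penalises many-valued attributes.
Splits are multiway — one branch per value observed at the node — and an
attribute is used at most once per path.

Choices a reader should know about:

* **Candidate filter.** Only attributes with strictly positive information
  gain enter the gain-ratio argmax. This is a simplification of C4.5's
  average-gain heuristic with the same purpose: it keeps near-zero-gain
  attributes with tiny split information from winning on a pathological
  ratio. `gain_ratio` is defined as 0 when `split_information` is 0.
* **Stopping.** A node becomes a leaf when its majority-class fraction
  reaches `purity_threshold` (default 1: grow until pure), when it holds
  fewer than `min_instances` cases (default 2), or when no candidate has
  positive gain. The purity threshold is the user-facing "how similar must
  the cases be before we stop asking" dial; 1.0 is the conservative default
  because the quiz layer wants faithful paths, and pruning — not early
  stopping — is the instrument for noise control.
* **Tie-breaks.** Everywhere, ties go to declaration order: the
  earlier-declared attribute wins equal gain ratios, and a leaf's diagnosis
  is the earliest-declared class among the most frequent. This makes
  induction fully deterministic — the same table always serializes to the
  same bytes — at the price of a mild bias toward early columns, which is
  irrelevant when scores differ and harmless (but arbitrary) when they tie.
  Floating-point equality is handled with a $10^{-12}$ tolerance.
* **Missing values.** In training, a missing cell is treated as its own
  category `"unknown"` and can carry a branch. At prediction time a missing
  value (or a value the node never branched on) stops the walk and returns
  the node's locally trained majority class, flagged `fallback_used`. The
  asymmetry is deliberate: a student-facing system must answer for any
  input, and the majority fallback is the standard closed-world answer.
  C4.5's fractional-instance weighting is intentionally not implemented.

### Pruning

Pessimistic-error pruning replaces a subtree by a leaf when doing so does
not worsen a deliberately pessimistic estimate of its error. For a node
with $n$ cases and $e$ training errors, the estimate is $n \cdot
U_{CF}(e, n)$, where $U_{CF}$ is the exact binomial (Clopper–Pearson) upper
confidence limit at confidence `confidence` — computed as
`qbeta(1 - CF, e + 1, n - e)`, which for $e = 0$ reduces to
$1 - CF^{1/n}$. Children's estimates are summed bottom-up and a subtree
collapses when the would-be leaf's estimate is no larger (a $10^{-9}$
slack favours collapsing on exact ties, the cheaper model). The default
`confidence = 0.25` is the long-standing J48 default; smaller values prune
harder. Subtree raising is not implemented. Pruning can only shrink the
tree and can only lower resubstitution accuracy — both are asserted as
invariants in the test suite.

## Validation

`cross_validate()` runs stratified k-fold cross-validation (default
`k = 10`): per class, instances are shuffled under the caller's seed and
dealt round-robin across folds, so even singleton classes land somewhere
and no fold is systematically class-starved. With ~30 diagnoses in ~100
cases, plain random folds routinely lose whole classes from a training
complement; stratification is therefore the default, and when a class is
still lost (it had only one case) the run proceeds and records a warning —
that class simply cannot be predicted correctly in that fold.

Accuracy is reported per fold and pooled; Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$ is computed once on the pooled confusion
matrix rather than averaged per fold, matching how a single kappa is
conventionally reported for a cross-validated model. The degenerate case
$p_e = 1$ (a one-class matrix) is defined as 1 when agreement is perfect
and 0 otherwise. An 80/20 stratified holdout (`holdout_evaluate()`) is
provided alongside k-fold CV because both protocols are in common use for
small case collections; they answer slightly different questions and the
package deliberately offers both rather than blessing one.

## From tree to quiz

`enumerate_paths()` lists one path per leaf (depth-first, branch order =
domain order), and `build_quizzes()` turns each into an ordered
questionnaire: the questions follow the tree top-down, and an attempt is
correct only if it reproduces the branch labels exactly and completely.
Two design points were genuinely open:

* **Options shown per question** are the attribute's *full* domain, not
  just the branches the tree grew. Pedagogically the learner must weigh
  every possible finding; mechanically this keeps every answer gradeable
  (off-path answers are simply wrong).
* **Difficulty levels** are path-length quantiles (default `n_levels = 3`):
  path depth is the only intrinsic difficulty measure the tree offers — a
  one-question path is a pathognomonic finding, a six-question path is a
  differential worked through. Quizzes are ranked by length and cut into
  near-equal groups (sizes differ by at most one), so equal-length quizzes
  may straddle a boundary when arithmetic demands it.

Quiz ids are 32-bit FNV-1a hashes of the canonical path string, so the same
tree always yields the same ids and a retrained tree invalidates stale
pools by construction. Drawing (`draw_quiz()`) is uniform over the level's
unanswered quizzes, without replacement within a session.

## Sessions, advancement, ranking

Session state is a pure fold over graded attempts: per-level tallies
(attempted = correct + wrong, summed seconds), an answered set per level,
and an append-only history. Advancement from a level requires **at least
70% correct among the quizzes attempted at that level** — the denominator
is attempts, not pool size, because a learner who restarts a small level
would otherwise face an unpassable ratchet. The threshold is applied
uniformly between consecutive levels. `restart_level()` zeroes one level's
tallies and makes its quizzes drawable again, leaving an audit record.

Cohort ranking is lexicographic: total corrects (descending), then total
errors (ascending), then total time (ascending), then student id. The
three factors are ordered by importance; a weighted composite score would
need a weight nobody can justify, whereas the lexicographic order is
parameter-free and deterministic. `first_error_index` in grading is
1-based, as is idiomatic in R.

## The synthetic generator

Real expert-labelled biopsy tables of this kind are not publicly
deposited, so the package carries its own study-condition generator.
`sample_ground_truth()` draws a random decision tree over a schema shaped
like the motivating data: 30 diagnoses, 20 attributes, 80% of them binary
present/absent and the rest 3-valued patterns, maximum path depth 6.
Growth splits random leaves on random unused attributes until every
diagnosis can be placed on at least one leaf; attributes the tree never
uses are irrelevant by construction. `generate_cases()` samples leaves
uniformly, fixes on-path attribute values, fills everything else uniformly
at random, and then applies three independent noise channels: label flips
(to a *different* diagnosis), attribute-cell corruption (uniform
resampling), and missingness (blanking). With all rates zero, the table is
class-consistent by construction.

What the generator emulates: the dimensions, domain shapes, and
tree-structured label logic of a small expert case collection, with
tunable noise. What it does not emulate: correlated findings beyond the
tree structure, class priors driven by disease prevalence (leaves are
sampled uniformly, not diagnoses), attribute cost or acquisition order,
and anything about images. Green recovery tests therefore show that the
inducer recovers tree-structured signal under these idealised conditions —
they do not certify accuracy on real biopsy data, whose noise is neither
independent nor uniform.

## Problem sizes and what the tests compute

The test suite and the acceptance script work at sizes chosen to make the
statistics stable while keeping a full run in well under a minute of
compute per file: 500 random tiny tables (≤ 4 attributes, ≤ 12 instances)
for exact agreement between `select_split()` and an independently coded
brute-force gain-ratio argmax; 50 seeds × 80 noise-free cases for exact
100% resubstitution; 20 seeds × 400 noise-free cases from the default
30-diagnosis generator, with 200 fresh probes each, for label-function
recovery (median agreement is the reported statistic); 500 shuffled-label
instances under 10-fold CV for the permutation-null kappa; and an
11-point sweep of k/10 correct sessions for the 70% advancement boundary.
The worked fibronectin example — an immunohistochemistry finding that alone
settles the diagnosis, so the tree asks exactly one question — is both a
unit test and the package's smallest end-to-end demonstration.

## Known limitations

* Numeric attributes, C4.5's fractional missing-value weights, subtree
  raising, and rule-set post-processing are out of scope.
* With ~30 classes in ~100 cases, cross-validation estimates carry large
  fold-to-fold variance and singleton classes are unlearnable in their own
  fold; the per-fold table and recorded warnings make this visible rather
  than hiding it.
* The `"unknown"` training category collides with a genuine domain label
  spelled "unknown", should a table declare one.
* Quiz difficulty equates to path length; it ignores how confusable the
  distractor options are.
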