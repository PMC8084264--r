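# nephroquiz

Decision-tree case quizzes for categorical diagnosis training.

`nephroquiz` is built for the teaching workflow around expert-labelled
categorical case tables — the motivating example being renal-biopsy
reports, where each case is a row of nominal findings (histology,
immunofluorescence, immunohistochemistry, clinical data) and the label is
one of a few dozen glomerulopathy diagnoses. The package:

1. **induces a C4.5-style decision tree** over the table — multiway nominal
   splits chosen by gain ratio $\mathrm{IG}(A)/\mathrm{SI}(A)$, where
   $\mathrm{IG}(A) = H - \sum_v \frac{n_v}{n} H_v$ is the information gain
   of attribute $A$ and $H = -\sum_i p_i \log_2 p_i$ is class entropy, with
   a user-set purity stopping threshold and pessimistic-error pruning from
   the exact binomial upper confidence limit;
2. **validates it** by stratified k-fold cross-validation: per-fold and
   pooled accuracy, pooled confusion matrix, and Cohen's kappa
   $\kappa = (p_o - p_e)/(1 - p_e)$;
3. **turns every root-to-leaf path into a quiz**: the questions follow the
   tree top-down, an attempt is correct only if it reproduces the tree's
   flow exactly, quizzes are levelled by path length, drawn at random
   without replacement, and graded sessions feed a 70%-correct advancement
   rule and a lexicographic cohort ranking (corrects, then errors, then
   time);
4. **simulates study conditions**: a seeded ground-truth-tree generator
   emits case tables (default: 30 diagnoses, 20 mostly-binary attributes)
   with controllable label/attribute/missingness noise, for recovery and
   robustness experiments.

Input is CSV or ARFF (nominal attributes); models, quiz pools, sessions and
reports persist as JSON. A thin CLI lives at `inst/cli/nephroquiz.R`.

## Worked example

A nine-case teaching table in which the immunohistochemistry finding
"positive for fibronectin" is pathognomonic:

```r
library(nephroquiz)

cases <- data.frame(
  immunohistochemistry = c(rep("positive for fibronectin", 3), rep("negative", 6)),
  mesangial_hypercellularity = c("present", "absent", "present",
                                 rep("present", 3), rep("absent", 3)),
  diagnosis = c(rep("fibronectin glomerulopathy", 3),
                rep("iga nephropathy", 3), rep("minimal change disease", 3)))

fit <- c45(diagnosis ~ ., data = cases, control = c45_control(prune = FALSE))
print(fit)
#> C4.5-style decision tree
#>   training instances: 9  leaves: 3  depth: 2
#>
#> immunohistochemistry = negative
#> |   mesangial_hypercellularity = absent: minimal change disease (3)
#> |   mesangial_hypercellularity = present: iga nephropathy (3)
#> immunohistochemistry = positive for fibronectin: fibronectin glomerulopathy (3)
```

The tree asks about immunohistochemistry first because it has the best
gain ratio; the positive-fibronectin branch is already pure, so that
diagnosis needs no second question (the `(3)` after each leaf is its
training support):

```r
classify(fit, list(immunohistochemistry = "positive for fibronectin"))
#> Diagnosis: fibronectin glomerulopathy
#>   immunohistochemistry = positive for fibronectin
```

Each of the three leaves becomes a quiz; the negative-branch quizzes have
two questions, the fibronectin quiz one:

```r
quizzes <- assign_levels(build_quizzes(fit), 2)
print(quizzes[[1]])
#> Quiz 06c99f3b (level 1)
#>   Q1. immunohistochemistry? [negative | positive for fibronectin]
#>   Q2. mesangial_hypercellularity? [absent | present]
#>   Diagnosis: minimal change disease
```

At realistic scale, with a synthetic 100-case, 30-diagnosis table:

```r
gt  <- sample_ground_truth(seed = 1)
tab <- generate_cases(gt, 100, seed = 2)
rep <- cross_validate(tab, c45_control(prune = FALSE), k = 10, seed = 3)
#> accuracy 91.00%, kappa 0.906
```

Accuracy here is the pooled fraction of held-out cases classified
correctly across the 10 folds; kappa corrects that agreement for chance
given the 30-class confusion matrix. Both vary with the seed — with 30
classes in 100 cases several diagnoses have so few examples that each fold
assignment matters.

## Package tour

| Area | Functions |
| --- | --- |
| Case tables | `case_table()`, `read_case_table()`, `write_case_table()`, `clean_table()`, `validate_table()` |
| Induction | `c45()`, `c45_control()`, `class_entropy()`, `split_scores()`, `select_split()`, `prune_tree()`, `classify()`, `predict()`, `serialize_tree()` |
| Evaluation | `stratified_folds()`, `cross_validate()`, `holdout_evaluate()`, `confusion_matrix()`, `cohen_kappa()` |
| Quizzes | `enumerate_paths()`, `build_quizzes()`, `assign_levels()`, `draw_quiz()`, `grade_attempt()` |
| Sessions | `session_state()`, `update_session()`, `advancement_eligible()`, `restart_level()`, `progress_summary()`, `rank_students()` |
| Simulation | `sample_ground_truth()`, `generate_cases()`, `recovery_check()` |

The methods vignette (`vignettes/decision-tree-case-quizzes.Rmd`) documents
the model, the design decisions, and what the synthetic experiments do and
do not show.
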