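# sortscan

Analysis toolkit for massively parallel reporter assays of yeast 3' end
(terminator) sequences measured by sort-seq: thousands of designed 3' end
variants are cloned behind a fluorescent reporter, cells are FACS-sorted
into 16 expression bins, and variant barcodes are sequenced per bin. The
package covers the full computational path:

* **Design** — scanning mutagenesis (10 bp/10 bp-step with duplicate
  random replacements; 9 bp/3 bp-step), saturation mutagenesis of
  terminator elements, A/T-content series, composed synthetic terminators
  (EE/PE/cleavage), and checksummed 11 bp barcodes.
* **Simulation** — a generative model of the assay: ground-truth
  expression driven by the TA-dinucleotide content of a planted
  polyadenylation *efficiency element* (EE), gamma-distributed single-cell
  expression sorted into bins, Poisson sequencing reads.
* **Inference** — per-variant mean expression by interval-censored
  maximum-likelihood gamma fitting of the binned read counts
  (`mean = k*theta`), plus technical-noise summaries from barcode
  replicate groups (median group RSD).
* **Element mapping** — per-window log2 fold-change profiles versus wild
  type, absolute-threshold element calling with run merging, polyA-site
  relative statistics, and a permutation test for motif co-occurrence.
* **Sequence model** — an L1-penalized logistic regression (glmnet) on 60
  mono/di-nucleotide features of the mutated windows' wild-type sequence,
  cross-validated with folds grouped by parent sequence, then slid across
  native 3' ends to score element strength.

The scientific center is the EE: a short TA-rich element ~40 bp upstream
of the main polyadenylation site whose disruption collapses expression to
a low mode (< 1 a.u.), and whose strength, read from sequence alone,
predicts part of the native expression range.

## Worked example

```r
library(sortscan)

cfg <- library_config(n_native = 40, n_rsd_groups = 20)
res <- run_pipeline(cfg, seed = 3)
str(res$report[c("median_rsd", "replicate_r_squared",
                 "element_recovery_rate", "classification_rate",
                 "peak_offset", "ee_expression_r")])
#> List of 6
#>  $ median_rsd           : num 0.131
#>  $ replicate_r_squared  : num 0.835
#>  $ element_recovery_rate: num 1
#>  $ classification_rate  : num 0.975
#>  $ peak_offset          : int -41
#>  $ ee_expression_r      : num 0.901
```

Reading the numbers: barcode replicates of identical sequences fluctuate
by ~13% (the platform's technical noise); two independent random
replacements of the same window agree with R² ≈ 0.84, so effects come
from the sequence removed, not the one introduced; the planted element is
re-discovered in every parent here; the held-out classifier flags the
strongest mutation as a positive element in ~98% of parents; the mean
score profile of intact native sequences peaks ~41 bp upstream of the
main polyA site — where the elements were planted; and per-sequence
element scores correlate with measured expression at r ≈ 0.9. (Exact
values vary with seed and library size.)

Individual stages are plain functions if you want the pieces:

```r
lib <- generate_library(cfg, seed = 3)       # manifest + truth + counts
est <- fit_library(normalize_counts(lib$counts))
prof <- fold_change_profiles(lib$manifest, est)
calls <- call_elements_all(prof)             # element intervals per parent
inst <- build_instances(prof, lib$manifest)
model <- train_cv(inst)$model
score <- score_native(model, lib$manifest$variable_region[1])
```

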