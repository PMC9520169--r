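# opensetr

Open-set recognition with outlier exposure, for plant-disease image
monitoring and similar fine-grained classification problems where samples
from *unknown* classes keep arriving after training.

## The problem

A disease classifier deployed in a greenhouse sees more than the K diseases
it was trained on: healthy tissue, irrelevant objects, and diseases nobody
labeled yet. A closed-set softmax will confidently misassign all of them.
Open-set recognition (OSR) asks the model to classify the K known classes
*and* flag everything else as unknown, so that flagged samples can be
curated, labeled and folded back into training (continual learning). A
practical lever is **outlier exposure**: a modest set of known outliers
(healthy parts, irrelevant images, suspected unknown diseases) available at
training time.

`opensetr` implements and compares two detectors that share one trainable
backbone F(·):

**Two-head network.** Two softmax heads C₁, C₂ on one backbone are trained
to agree on labeled inliers (summed cross-entropy) and then fine-tuned on
exposed outliers with a margin hinge on their mean L1 discrepancy,

    L_dis(O) = max{ m − (1/|O|) Σ_o d(p₁(·|x_o), p₂(·|x_o)), 0 },
    d(p₁, p₂) = Σ_k |p₁(k) − p₂(k)|  ∈ [0, 2],

so the heads disagree on outlier-like inputs. A sample gets the shared
argmax label only when the heads agree, their discrepancy is below a
threshold θ_d (grid-searched on validation data), and both heads are
confident (θ_p = 0.95); otherwise it is unknown. The discrepancy itself is
the sample's outlier score. A four-step continual-learning loop then mines
pseudo-inliers and pseudo-outliers from unlabeled data, retrains with
FixMatch consistency plus supervised contrastive regularization, and
fine-tunes again.

**Disassembled semi-supervised OpenMatch.** A closed-set head C plus K
one-vs-all (OVA) binary heads D_j, each giving p_j(t=0|x) (inlier for class
j) vs p_j(t=1|x). Stage 1 trains on labeled inliers (cross-entropy + OVA
hard-negative loss) and exposed outliers (all OVA heads pushed to
"outlier") — OpenMatch as a plain OoD detector. Stage 2 continues
semi-supervised: per-class entropy minimization and soft open-set
consistency regularization (SOCR) on unlabeled batches, and, after a
warm-up, FixMatch — unlabeled samples whose predicted-class OVA head clears
τ = 0.95 become pseudo-inliers whose strong-augmented views are trained by
cross-entropy — plus a temperature-scaled contrastive loss over a pool of
strong-augmented pseudo-inlier embeddings,

    r(u′) = −(1/|P(u′)|) Σ_{p′∈P(u′)} log [ exp(⟨z_u′, z_p′⟩/T) / Σ_{v′≠u′} exp(⟨z_u′, z_v′⟩/T) ].

The decision rule classifies by argmax of C and rejects when the matching
OVA head says outlier (p_ŷ(t=1) ≥ 0.5).

Because no public image corpus accompanies this problem setting, the
package ships a deterministic synthetic generator that emulates its
structure: K known classes rendered as class-specific lesion motifs (hue
band × ellipse eccentricity × spot count) on noisy leaf backgrounds, plus
the three outlier families — irrelevant textures, lesion-free "normal"
tissue, and an unknown-disease motif disjoint from every known class.
Reference confusion matrices and dataset totals from a published
eight-class strawberry-disease study are included as plain-text fixtures
under `inst/extdata/` for metric verification.

## Worked example

```r
library(opensetr)

schema <- dataset_schema(K = 4)                      # 64 x 64 RGB, 3 outlier families
bundle <- generate_dataset(schema, n_labeled_per_class = 40, n_unlabeled = 200,
                           n_ood = 100, n_val = 100, n_test = 200, seed = 1)
run <- run_twohead_pipeline(bundle, twohead_config(seed = 1))
run
#> <osr_run> method = twohead, final accuracy = 0.995, AUROC = 1.000
glance(run)
#> # A tibble: 1 × 4
#>   method  accuracy auroc     n
#>   <chr>      <dbl> <dbl> <int>
#> 1 twohead    0.995     1   200
run$reports$final$confusion
#>          predicted
#> truth     class01 class02 class03 class04 unknown
#>   class01      24       0       0       0       1
#>   class02       0      25       0       0       0
#>   class03       0       0      25       0       0
#>   class04       0       0       0      25       0
#>   unknown       0       0       0       0     100
```

The test split is half inliers, half outliers. The confusion matrix has
K + 1 outcomes — the last row/column is the unknown class — so the 0.995
accuracy says 199 of 200 test images were either given their correct
disease label or correctly rejected; the AUROC of 1.0 says every outlier
out-scored every inlier on the inter-head discrepancy. `tidy(run)` exposes
the per-epoch loss history, `autoplot(run)` plots it,
`predict(run, newdata)` scores new samples, and
`run_openmatch_pipeline()` is the drop-in OVA-based alternative. The
`run_ablation_ood_types()` harness retrains while varying which outlier
families are exposed, and `run_ablation_openmatch_stages()` compares
OpenMatch's stage-1 detector against its semi-supervised continuations.

A thin command-line interface over the same functions ships at
`inst/cli/osr.R` (subcommands `generate-data`, `train-twohead`,
`train-openmatch`, `evaluate`, `ablate`).

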