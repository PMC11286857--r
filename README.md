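# netsynergy

Network-based prediction and statistical evaluation of synergistic drug
combinations.

## What problem does this solve?

Effective drug combinations are rare, and screening all pairs of even a
modest drug collection experimentally is infeasible (1,488 drugs already
give 1,106,328 candidate pairs). netsynergy ranks candidate pairs for a
query disease computationally, by combining three layers of evidence on a
human molecular interaction network:

- **Topology (T).** Disease genes and drug-response genes each form modules
  on the network. The configuration associated with synergy —
  *Complementary Exposure* — has both drug modules overlapping the disease
  neighborhood (proximity z-scores `z(Q,A) < 0`, `z(Q,B) < 0`) while being
  mutually separated (`s_AB > 0`). Pairs in this class score `T = 2`,
  everything else 0.
- **Proximity (P).** The closest distance
  `d(Q,A) = (1/|A|) Σ_a min_q d(q,a)` is standardized against a
  degree-matched permutation null, sign-inverted and min–max scaled to
  `[0,1]` over the drug collection; `P` is the mean over the two drugs.
- **Transcriptional correlation (C).** Mean absolute cosine coefficient
  between the disease and drug expression signatures on the genes shared by
  the modules. Because raw module overlaps are tiny, modules can first be
  amplified by PRINCE-style network propagation with prior knowledge
  (network-based disease similarity; generalized-Jaccard chemical
  similarity of fingerprints).

The prediction score is `T + P + C ∈ [0, 4]`; rankings are evaluated by ROC
AUC against known synergistic pairs. The package also implements the
downstream statistics used to validate predictions in vitro — the Bliss
independent-action expectation `CI_mix = 1 − (1−v)(1−w)` and the Loewe
concentration-addition toxic unit `TU = Ca/EC_u^A + Cb/EC_u^B` (synergy
when `TU < 1`) — plus pathway analytics (hypergeometric
over-representation, pathway coverage, largest-connected-component
z-scores, DEG filtering) and a synthetic-data generator that plants
known-synergy structure so the whole pipeline is testable offline.

Intended users: computational biologists doing network pharmacology or drug
repositioning who have an interactome edge list, gene signatures and
(optionally) chemical fingerprints, and want a reproducible, fully offline
pair-ranking pipeline with honest statistics.

## Worked example

```r
library(netsynergy)

# a small planted benchmark: 3 synergistic drug pairs + 6 decoys on a
# 500-gene scale-free network
b <- synth_bundle(synth_config(n_genes = 500, n_planted_pairs = 3,
                               n_decoy_drugs = 6, disease_module_size = 30,
                               drug_module_size = 16, n_other_diseases = 3),
                  seed = 42)

res <- run_pipeline(b, mode = "netprop", n_perm = 100, seed = 1)
head(res$pairs[, c("drug_a", "drug_b", "class", "T", "P", "C", "total",
                   "known_synergistic")], 5)
#>      drug_a    drug_b class T     P     C total known_synergistic
#> 1 drug_p01a drug_p03a    II 2 0.967 0.710  3.68             FALSE
#> 2  drug_d02 drug_p01a    II 2 0.696 0.895  3.59             FALSE
#> 3 drug_p01a drug_p02a    II 2 0.689 0.835  3.52             FALSE
#> 4 drug_p01a drug_p03b    II 2 0.775 0.746  3.52             FALSE
#> 5  drug_d02 drug_p03a    II 2 0.664 0.784  3.45             FALSE
sprintf("AUC = %.3f", res$auc)
#> "AUC = 0.852"
```

Every top pair is in class II (`T = 2`: both drugs close to the disease,
modules mutually separated) with high scaled proximity `P` and strong
absolute signature correlation `C`. The ranked negatives at the top are
combinations of planted drugs from *different* true pairs — individually
disease-associated drugs whose pairing was never planted — which is exactly
the hard negative class this score family cannot fully separate; the AUC
against the planted labels is 0.852 here.

A single proximity statistic looks like this:

```r
proximity_z(b$net, b$disease_module, b$drug_modules[["drug_p01a"]],
            n_perm = 100, seed = 1)
#> <proximity_result> d = 1.0000, mu = 1.6131, sigma = 0.1850, z = -3.3142 (100 permutations)
```

The planted drug module sits 1 hop from the disease module on average,
versus 1.61 ± 0.19 for degree-matched random modules: z = −3.3, i.e.
significantly closer than chance.

And the experimental-synergy layer, on a simulated dose–response plate with
a planted 30% excess over the Bliss expectation:

```r
plate <- generate_plate(synth_config(), synergistic = TRUE, seed = 3)
head(plate_synergy(plate)[, c("conc_a", "conc_b", "observed_effect", "ca",
                              "bliss_expected", "ia_excess")], 3)
#>   conc_a conc_b observed_effect    ca bliss_expected ia_excess
#> 1  0.092  0.401           0.421 0.349          0.200      0.22
#> 2  0.184  0.802           0.534 0.475          0.254      0.28
#> 3  0.368  1.605           0.669 0.647          0.539      0.13
```

Toxic units well below 1 (CA synergy) and observed effects above the Bliss
expectation (IA synergy), as planted.

A thin command-line front end over the same functions ships in
`inst/scripts/netsynergy.R` (subcommands `synth`, `run`, `proximity`,
`separation`, `propagate`, `score`, `synergy`, `eval`).

See `vignettes/netsynergy-methods.Rmd` for the models, parameter choices
and the design of the synthetic benchmark.

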