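# mltcseq

Clustering people with Multiple Long-Term Conditions (MLTC) from
longitudinal electronic health records.

People accumulating two or more chronic conditions are the norm, not the
exception, in ageing primary-care populations, and understanding which
conditions travel together — and in whom — matters for service design and
aetiology. `mltcseq` implements a sequence-representation-learning pipeline
for this problem: coded patient histories become chronological token
sequences, a transformer encoder turns each history into a fixed-length
patient embedding, and gender-stratified K-Means over those embeddings
yields multimorbidity clusters that are then characterised
epidemiologically. Because the primary-care databases this method targets
are access-restricted, the package ships a synthetic cohort generator with
known ground truth (morbidity archetypes, planted comorbidity pairs,
configurable demographic marginals), so every stage is testable end to end
on a desk.

The package is aimed at methodologists in epidemiology and clinical
informatics who want a transparent, fully inspectable implementation of
this class of pipeline at laptop scale.

## The pipeline

1. **Synthetic cohorts** (`generate_cohort`): each patient is drawn from one
   morbidity archetype (low-burden, cardiometabolic, mental-health,
   respiratory, mixed); conditions are sampled at archetype prevalences
   with an odds-ratio uplift on planted comorbidity pairs; linked
   medications are emitted as monthly refill streams; demographic
   marginals default to published UK primary-care cohort margins
   (54.8% female; ethnicity recorded for 37.7%, of whom 93.4% White;
   22.6% in the least deprived IMD quintile).
2. **Sequences** (`cohort_to_sequences`): diagnosis codes at the ICD-10
   three-character level, medication groups and lab-abnormality tokens,
   chronologically ordered; monthly medications deduplicated (first
   prescription kept, re-admitted after a ≥6-month gap); tokens seen in
   fewer than `min_patient_count` patients pruned; visit numbers pooled by
   calendar month; each token paired with age, calendar year, gender and
   visit channels; maximum sequence length 64.
3. **Encoder** (`rtd_pretrain`, `diffcse_finetune`, `embed_patients`): a
   disentangled-attention transformer whose attention combines
   content–content, content–relative-position and relative-position–content
   terms, with token + age + year + gender + visit + absolute-position
   input embeddings. Pretraining is replaced-token detection: a generator
   learns masked-token prediction (15% dynamic masking) and a discriminator
   labels generator-corrupted positions, with gradient-disentangled sharing
   of the token embedding table. Fine-tuning is contrastive: pooled patient
   embeddings are made invariant to dropout-noise views (temperature 0.05)
   and sensitive to generator-made edits (conditional detection term,
   lambda 0.005). Forward and backward passes are implemented directly in
   dense matrix algebra and verified by finite-difference gradient checks.
4. **Clustering** (`select_optimal_k`, `fit_final_kmeans`,
   `bootstrap_stability`, `temporal_cohesion`): the cluster number is
   chosen by bootstrapped agglomerative (Ward) clustering on stratified
   subsamples scored by silhouette (Davies-Bouldin and Calinski-Harabasz
   for corroboration); stability is assessed by Hungarian-matching
   bootstrap K-Means centroids to the final centroids on cosine distance,
   and by re-embedding age-spliced histories (ages 50–100) and comparing
   cluster cohesion over time.
5. **Evaluation** (`dfipf`, `cdfipf`, `chi2_one_vs_all`, ...): clusters are
   characterised with cluster-weighted disease frequencies

   DF-IPF(d, p) = n_dp / Σ_d' n_d'p · log(|P| / |{p ∈ P : d ∈ p}|)

   c-DF-IPF(i, d) = mean DF-IPF in cluster i · log(|K| / |{k : d ∈ k}|),

   one-vs-all chi-squared tests with the signed-Z symbol scheme
   (`++` ≥ 50, `+` ≥ 10, `-` ≤ −10, `--` ≤ −50), Welch t-tests for
   continuous variables, observed/expected ratios and exclusivity, and
   comorbidity-pair cosine similarity of token embeddings.
6. **LCA baseline** (`fit_lca`, `select_classes`): EM for a mixture of
   independent Bernoulli condition profiles with AIC/BIC class selection.

`run_pipeline()` orchestrates any subset of stages with one global seed,
versioned output directories and a JSON manifest.

## Worked example

```r
library(mltcseq)

co <- generate_cohort(cohort_config(n_patients = 500, prop_female = 1,
                                    seed = 21))
sq <- cohort_to_sequences(co, min_patient_count = 5)
pt <- rtd_pretrain(sq$sequences, sq$vocab, desk_model_config(), seed = 11)
ft <- diffcse_finetune(pt$generator, sq$sequences, sq$vocab, seed = 5)
emb <- embed_patients(ft$encoder, sq$sequences, sq$vocab)

range(pt$history$mlm_loss)
#> [1] 2.287166 3.644304       # masked-prediction loss, last vs first epoch

te <- token_embeddings(ft$encoder, sq$vocab)
cs <- comorbidity_similarity(te, default_comorbidity_pairs(), seed = 2)
c(cs$median_pair, cs$median_random)
#> [1] 0.58 0.05               # planted pairs vs random couples (rounded)

km <- fit_final_kmeans(emb, k = 5, seed = 3)
truth <- co$truth$archetype[match(rownames(emb), co$truth$patient_id)]
mclust::adjustedRandIndex(km$cluster, truth)
#> [1] 0.79                    # archetype recovery at desk scale (rounded)
```

The masked-prediction loss falls from 3.64 to 2.29 over 30 epochs on this
500-patient corpus; planted comorbidity pairs end up with a median token
cosine similarity of ~0.58 against ~0.05 for random couples; and K-Means
on the patient embeddings recovers the five planted archetypes at ARI
~0.8 (a few percent of patients draw no archetype-distinctive conditions
at all, which caps attainable recovery — see the methods vignette).

## Scope

The package is a desk-scale reimplementation of the method: it does not
ship clinical codelists or terminology mappings (interfaces accept any
mapping table), does not model practice-level coding variation, and makes
no attempt to reproduce results that require restricted data. The methods
vignette (`vignettes/mltc-clustering-methods.Rmd`) documents the model,
its assumptions, all tunable parameters and the design decisions.
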