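# rpifuse

Predicting lncRNA–protein interactions (RPIs) from multiple information
sources. Long non-coding RNAs act through physical association with
RNA-binding proteins; mapping those associations experimentally is slow,
so computational screening of candidate pairs is a standard first step.
`rpifuse` is aimed at computational biologists who have sequences (and,
optionally, secondary structures and a protein–protein interaction
network) for a set of RNAs and proteins, plus a list of known interacting
pairs, and want a trained classifier that scores new pairs.

## Method

Each candidate pair (R, P) is described by four feature blocks:

- **sequence** (739): stacked k-mer frequencies of R for k = 1..4 over
  A\<C\<G\<U (340 values), concatenated with conjoint-triad group k-mer
  frequencies of P for k = 1..3 over the seven-group partition
  {A,G,V}{I,L,F,P}{Y,M,T,S}{H,N,Q,W}{R,K}{D,E}{C} (399 values);
- **structure** (40): the digitized dot-bracket string of R
  (. → 0, brackets → 1) and C/E/H string of P (0/1/2), each compressed to
  its first 20 type-II discrete-cosine coefficients
  X_i = √(2/l) Σ_n x_n cos[(π/l)(n+½)(i+½)];
- **physchem** (25): per dinucleotide property, the lag-1 auto-covariance
  of R's normalized property series (22 values), plus the first-tier
  sequence-order factor (1/(L−1)) Σ_j (v_j − v_{j+1})² of P for
  hydropathy, hydrophilicity and mass (3 values);
- **ppi** (100): P's row of the PPI score matrix (≤ 400 reference
  proteins, unit diagonal) projected onto the top 100 principal axes;
  proteins without PPI data map to the zero vector.

Blocks are screened independently by random-forest Gini importance
(keep the top ⌊0.8·d⌋ features: 739 → 591, 40 → 32, 25 → 20, 100 → 80),
then classified by a parallel CNN: per block, three 1-D convolutions
(kernel 3, ReLU then batch-norm, two max-pool stages), branch outputs
fused by concatenation (or two-stage stacking) into a fully connected
16-8-2 head with softmax; a pair is called interacting when
P(interacting) > 0.5. Evaluation reports ACC, SEN, SPE, PRE, F1, MCC and
the rank-based (Mann–Whitney) AUC, with stratified five-fold
cross-validation that refits selection inside each fold. A synthetic-data
generator plants a motif-containment interaction rule so the whole
pipeline is testable without external databases. Details and rationale:
`vignettes/rpifuse-methods.Rmd`.

## Worked example

```r
library(rpifuse)

cfg <- simulation_config(seed = 11)   # 60 RNAs x 60 proteins, 400 interacting pairs
ds  <- simulate_rpi_data(cfg)         # sequences, structures, PPI edges, labels
nrow(ds$pairs)
#> [1] 800

res <- rpi_pipeline(ds, model_config(seed = 11), seed = 11)
#> ppi block: 2.8% of pairs use the zero fallback vector
res$metrics
#> ACC 0.9371  SEN 0.9625  SPE 0.9114  PRE 0.9167  F1 0.9390  MCC 0.8753  AUC 0.9565

sapply(res$masks, function(m) length(m$kept_indices))
#>  sequence structure  physchem       ppi
#>       591        32        20        80

head(res$predictions, 3)
#>         score predicted
#> 1 0.337758327  negative
#> 2 0.038761517  negative
#> 3 0.004786532  negative
```

`rpi_pipeline()` encodes the 800 labelled pairs, fits the selection masks
and the network on a stratified 80% training split, and scores the 20%
held-out pairs: here 93.7% of held-out pairs are classified correctly and
the rank-AUC is 0.957 — the planted interaction rule is recovered almost
completely despite the 2% label noise the generator injects. The mask
sizes show the 80% retention rule acting on each block's published width.
The per-pair scores are softmax probabilities; rows with score ≤ 0.5 are
called non-interacting.

A thin command-line front end (`inst/scripts/rpifuse`) exposes
`simulate`, `encode`, `select`, `train`, `evaluate` and `predict`
subcommands over the same functions, reading and writing FASTA/TSV files.

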