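# tcrdiff

Denoising-diffusion modelling of epitope-specific T cell receptor (TCR)
CDR3β repertoires, with TCR–epitope binding prediction built on the same
model.

## The problem

The CDR3β loop of the TCR β chain is the dominant determinant of which
peptide–MHC complexes a T cell recognises. `tcrdiff` addresses the two
sides of repertoire engineering with one learned object:

* **Generation** — given a target epitope peptide, sample nucleotide-level
  CDR3β sequences from a conditional denoising diffusion probabilistic
  model (DDPM).
* **Prediction** — given a (CDR3β, epitope) pair, score binding with a
  classifier whose features come from the diffusion model's encoder.

CDR3β amino-acid sequences (filtered to 7–24 residues) are back-translated
with the most frequent human codon per residue and one-hot encoded over
(A, T, G, C) in a zero-padded 72-nt frame. The forward process corrupts a
clean matrix X₀ over T = 10 steps with a linear schedule β: 1e-4 → 0.1
(α_t = 1 − β_t, ᾱ_t = ∏ α_s):

    q(X_t | X_{t−1}) = N(X_t; √(1−β_t) X_{t−1}, β_t I)
    X_t = √ᾱ_t X₀ + √(1−ᾱ_t) ε,  ε ~ N(0, I)

A conditional U-Net ε_θ(X_t, t, e) — skip connections, 512-dim bottleneck
by default, sinusoidal timestep embedding, and a 1024-dim epitope
embedding injected into every block — is trained to predict the noise by
MSE (Adam, lr 1e-4, early stopping at Δ < 0.001 over 3 epochs). Sequences
are generated by ancestral sampling from pure noise and decoded with a
threshold/arg-max rule. Two binding predictors extend the encoder: a
7-layer head without HLA, and a 5-layer HLA-aware head with the locus
one-hot (HLA-A/B/C) concatenated into every layer; dropout 0.6 on all but
the final layer.

Everything runs offline: a synthetic-repertoire generator emulates the
statistical structure the method assumes (conserved `CASS…F` termini,
class-specific core motifs per epitope, a healthy non-binding pool), and
the default epitope encoder is a deterministic 1024-dim featurization with
a pluggable seam for protein-language-model backends. The network core
(convolutions, group norm, backprop, Adam) is implemented in vectorised
base R and verified against numerical differentiation in the test suite.

## Worked example

```r
library(tcrdiff)

linear_schedule(10)
#> <noise_schedule> T = 10, beta 0.0001..0.1, alpha_bar_T = 0.5951

spec <- synthetic_spec(n_epitopes = 2, tcrs_per_epitope = 50, seed = 42)
spec
#> <synthetic_spec> 2 epitopes x 50 TCRs, lengths 7-24, CASS...F, motif 5, mutation 0.10, seed 42

rep <- generate_repertoire(spec)
head(rep$pairs, 3)
#> # A tibble: 3 × 6
#>   cdr3b               nt                              epitope hla   label source
#> 1 CASSCMQVRMEEREFHAVF TGCGCCAGCAGCTGCATGCAGGTGAGAATG… TCAIDW… HLA-C     1 synth…
#> 2 CASSDMCVRNFAFGIVVF  TGCGCCAGCAGCGACATGTGCGTGAGAAAC… TCAIDW… HLA-C     1 synth…
#> 3 CASSCMCVRTF         TGCGCCAGCAGCTGCATGTGCGTGAGAACC… TCAIDW… HLA-C     1 synth…

cfg <- diffusion_config(lr = 2e-3, max_epochs = 40, batch_size = 25,
                        early_stop_patience = Inf,
                        unet = unet_config(l_max = 72, channels = c(8, 16),
                                           bottleneck = 32, t_dim = 32))
model <- train_generator(rep$pairs, config = cfg, seed = 7)
model
#> <tcr_diffusion> 188492 params, T = 10, 40 epochs (early stop: no), final loss 0.45083

generate_tcrs(model, rep$epitopes[1], 5, seed = 3)
#> # A tibble: 5 × 4
#>   epitope   nt          peptide ok
#> 1 TCAIDWTPE "TGC"       "C"     TRUE
#> 2 TCAIDWTPE "GGAGCTAGC" "GAS"   TRUE
#> 3 TCAIDWTPE "CGCGCC"    "RA"    TRUE
#> 4 TCAIDWTPE ""          ""      FALSE
#> 5 TCAIDWTPE "TCT"       "S"     TRUE
```

Forty epochs of a small network only begin to denoise (the loss has
fallen from 1.0 — the pure-noise baseline — to 0.45, and samples are
short fragments). The study configuration used by the tests and the
acceptance script, `study_generator_config()` (450 epochs, channels
16→32, bottleneck 64), recovers the conserved `CASS` prefix in
essentially all samples and separates epitope classes in latent space;
`vignette("tcrdiff-methods")` describes the model, its assumptions, and
these configurations in detail.

Downstream, the same model object feeds the whole analysis:

```r
bp    <- build_predictor(model, predictor_config("bp"))      # 7-layer head
bp    <- train_predictor(bp, labelled_pairs, epochs = 120)
tidy(bp)                                 # per-epoch held-out accuracy / F1
lat   <- extract_latents(model, rep$pairs)
knn_purity(lat, k = 5)                   # class purity in PCA-10 space
autoplot(latent_map(lat, seed = 1))      # UMAP view (python umap-learn)
```

A thin command-line dispatcher over the same functions lives at
`inst/cli/tcrdiff.R` (subcommands `simulate`, `train-gen`, `generate`,
`train-bp`, `predict`, `evaluate`).

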