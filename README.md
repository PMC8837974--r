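# bulbarvoice

Voice-based detection of **bulbar involvement in amyotrophic lateral
sclerosis (ALS)** from sustained-vowel recordings.

Bulbar involvement — degeneration of corticobulbar motor neurons serving the
speech and swallowing musculature — shows up in the voice before it is
obvious to the ear: glottal cycles become irregular (jitter, shimmer), the
harmonic structure drowns in aspiration noise (lower harmonics-to-noise
ratio, HNR), and the high harmonics fade. `bulbarvoice` implements a
complete, reproducible pipeline that turns a set of sustained Spanish-vowel
recordings (/a e i o u/, 3–4 s, one WAV per vowel) into a per-recording
feature vector and a cross-validated diagnostic report, for clinical voice
researchers and speech-signal engineers.

Because no public patient cohort exists for this problem, the package ships
a first-class **synthetic vowel generator** with known ground truth, so
every stage — and the pipeline end to end — is testable without patient
data.

## The method

1. **Preprocessing** — decimate 44.1 kHz recordings by 5 (anti-aliased, to
   8820 Hz; vowel information lives below ~4 kHz), z-score the signal
   (`z = (x − x̄)/S`), and cut a 150 ms segment centred at mid-phonation.
2. **15 phonatory features** — glottal cycles are located by pitch-guided
   peak picking with waveform-matching refinement; from the cycle table
   (periods `T_i`, peak-to-peak amplitudes `A_i`):
   - jitter: absolute `mean|T_i − T_{i−1}|`, relative (% of mean period),
     rap (3-point), ppq5 (5-point);
   - shimmer: dB `mean|20·log10(A_{i+1}/A_i)|`, relative (%), apq3/5/11;
   - HNR per frame: `10·log10(r(T0)/(1 − r(T0)))` with `r(T0)` the
     normalized autocorrelation peak at the fundamental period;
   - pitch mean/SD/min/max.
3. **35 time–frequency features** — the analytic signal's discrete Wigner
   distribution is smoothed with the Choi–Williams kernel
   `exp(−θ²τ²/σ)` and normalized (CWDN); its marginals `m_t(t)`
   (instantaneous power) and `m_f(f)` (spectral energy density) form the
   interference-free joint density `p_D(f,t) = m_t(t)·m_f(f)`. From it, per
   7 frequency bands (0–80, 80–250, 250–550, 550–900, 900–1500, 1500–3000,
   3000–4410 Hz): band energies `E_Bn`, frequency peaks `f_Cres`, centroids
   `f_Med`, spectral informations `IE_Bn`; plus Shannon entropies `H_t`,
   `H_f`, `H_tf = H_t + H_f`, the kurtosis `K` of `m_t`, and joint
   time–frequency moments `t1f1`, `t7f7`, `t15f15` (near-zero `t1f1`
   certifies the marginal independence that makes `p_D` valid).
4. **Feature screening** — per comparison (C vs B, C vs NB, B vs NB,
   C vs A, with A = B ∪ NB; sexes always separate): MANOVA omnibus (Wilks'
   Λ) plus per-feature F tests; keep features with p < 0.05.
5. **Classification** — stratified 10-fold CV over five model families
   (RF, LR, LDA, NN, SVM), minority-class upsampling and feature scaling
   inside the training folds only, 50% probability threshold; accuracy,
   sensitivity and specificity from fold-pooled confusion counts.

## Worked example

One synthetic pathological vowel through the feature extractor:

```r
library(bulbarvoice)
rec <- synthesize_vowel(voice_spec(f0 = 120, jitter_rel = 1.5,
                                   shimmer_rel = 5, hnr_db = 18,
                                   vowel = "a", sex = "M", seed = 42))
rec
#> <bv_recording> 132300 samples @ 44100 Hz (3.000 s)
seg <- preprocess_recording(rec)      # 8820 Hz, z-scored, 150 ms
round(unlist(phonatory_features(seg))[c("jitter_relative",
      "shimmer_relative", "hnr_mean", "pitch_mean")], 3)
#>  jitter_relative shimmer_relative         hnr_mean       pitch_mean
#>            1.388            5.826           11.256          119.883
```

The injected 1.5% jitter and 5% shimmer are recovered (the estimator sees
slightly more shimmer because the 18 dB noise also moves the per-cycle
peaks, and the cycle irregularity depresses the autocorrelation-based HNR
below the 18 dB noise-only value — both expected estimator physics).
Time–frequency features from the same segment:

```r
tf <- extract_tf_features(seg)
round(tf[c("E_Bn2", "E_Bn6", "H_f", "H_tf", "K", "t1f1")], 4)
#>   E_Bn2   E_Bn6     H_f    H_tf       K    t1f1
#>  0.1125  0.0014  4.8859 12.6282  1.8883  0.0080
```

`E_Bn2` holds the fundamental's band share, `t1f1 ≈ 0` confirms the
marginals are independent. A small end-to-end cohort (3 subjects per group,
5 vowels each; a few minutes of CPU):

```r
run <- run_pipeline(run_config(n_per_group = 3, sex = "F", seed = 7,
                    cv = cv_config(seed = 7, n_folds = 5, rf_ntree = 200)))
run$selection$C_vs_B
#> <bv_selection> C_vs_B (F): 22/50 features at p < 0.05
run$cv$C_vs_B
#> <bv_cv_report> C_vs_B (F), 5-fold CV
#>     accuracy sensitivity specificity
#> RF       100         100         100
#> LR       100         100         100
#> LDA       90          80         100
#> NN       100         100         100
#> SVM      100         100         100
run$cv$B_vs_NB
#> <bv_cv_report> B_vs_NB (F), 5-fold CV
#>     accuracy sensitivity specificity
#> RF      93.3        93.3        93.3
#> LR      83.3        86.7        80.0
#> LDA     66.7        53.3        80.0
#> NN      73.3        66.7        80.0
#> SVM     83.3        86.7        80.0
```

Controls versus bulbar patients separate almost perfectly, while B vs NB is
markedly harder — by design, the synthetic NB group contains undiagnosed
"lookalike" subjects, reproducing the qualitative clinical picture.

Real recordings run through the same path: put the WAVs next to a
`metadata.csv` (columns `subject_id, sex, group, vowel, path`) and use
`run_config(input_dir = "...")`, or the CLI:

```sh
Rscript -e 'bulbarvoice::bulbarvoice_cli()' synth --n-per-group 10 --sex F --seed 7 --out cohort/
Rscript -e 'bulbarvoice::bulbarvoice_cli()' extract --in cohort/ --out features.csv
Rscript -e 'bulbarvoice::bulbarvoice_cli()' classify --features features.csv --comparison C_vs_B --sex F
```

## Documentation

The methods vignette (`vignettes/bulbarvoice-methods.Rmd`) documents the
models, the parameter choices and their defaults, what the synthetic cohort
does and does not emulate, and the numerical edge-case policies.
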