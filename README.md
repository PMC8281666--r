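# imhcmr

In-silico comparison of bright-blood versus dark-blood T2\*-weighted
cardiovascular magnetic resonance (CMR) for intramyocardial hemorrhage
(IMH).

## The problem

Hemorrhage within a reperfused myocardial infarction (MI) deposits iron
whose magnetic susceptibility shortens T2\*, so IMH appears as a
hypointense core on T2\*-weighted gradient-echo images. Bright-blood
T2\*-weighted CMR is the validated reference for detecting it, but
dark-blood variants — which add a double-inversion-recovery (DIR)
preparation to null chamber blood — are often used interchangeably. The
DIR preparation costs longitudinal magnetization (two imperfect adiabatic
inversions, worse at 3 T where the pulses are longer) and stagnant blood
along the hypokinetic infarct wall escapes nulling. Both effects erode
the contrast that threshold-based IMH quantification depends on.

`imhcmr` is for imaging scientists who want those mechanisms in a
controlled setting: it builds a digital left-ventricular phantom with
known ground truth, renders paired bright/dark T2\*-weighted and LGE
images, and runs the complete clinical quantification chain on them.

## What it computes

* **Phantom + signal model** — spoiled-GRE magnitude signal
  `S = PD·sin(α)·(1−E1)/(1−E1·cos α)·exp(−TE/T2*)`, with the DIR
  preparation applied at the magnetization level: in-slice tissue keeps
  the fraction `1 − (1 − κ(2η_ns−1)(2η_sel−1))·e^(−TI/T1)` of its
  steady-state magnetization, flowing blood sees only the non-selective
  pulse and nulls near `TI = T1·ln 2`. Rician noise (magnitude of two
  Gaussian quadrature channels).
* **Quantification** — remote reference ROI; MI zone as LGE signal
  ≥ mean + 5 SD of remote; IMH core as T2\*w signal ≤ mean − 2 SD within
  the MI zone (4-connected cores, minimum size 2 px); IMH extent as %LV
  myocardium.
* **Signal metrics** — Relative SNR = `(SI_remote,DB/σ_air,DB) /
  (SI_remote,BB/σ_air,BB) × 100%`, Relative CNR analogously from the
  remote−IMH contrast, and COV = σ/SI per region.
* **Segmental diagnostics** — 6-segment AHA-style partition per slice,
  positivity when the hypointense area exceeds 1% of the segment,
  sensitivity/specificity/accuracy of dark-blood calls against
  bright-blood ground truth, AUC by rank-sum over continuous segment
  fractions.
* **Agreement** — two emulated readers (ROI jitter + threshold
  perturbation), ICC(2,1) with F-based 95% CI, Bland–Altman bias and
  limits of agreement (bright − dark), OLS regression of in-vivo extents
  on a noise-free fine-grid ex-vivo stand-in.

## Worked example

```r
library(imhcmr)

subj   <- simulate_subject(subject_config(field = "1.5T", phase = "acute"), seed = 7)
seg_bb <- quantify_subject(subj, "bright")
seg_db <- quantify_subject(subj, "dark")
subject_signal_metrics(subj, seg_bb, seg_db)
```

prints (abridged):

```
Simulated subject (1.5T, acute): 192x192x6, true IMH extent 4.62% LV
IMH extent: true 4.62%, bright 4.33%, dark 3.30%
relative SNR 77.0%, relative CNR 84.4%, COV 0.114 (bright) vs 0.157 (dark)
```

The same phantom measured on the dark-blood arm loses about a quarter of
its apparent hemorrhage: the DIR preparation compresses the tissue
signals while the noise floor is unchanged, so boundary pixels fall above
the `mean − 2·SD` detection threshold. A full cohort:

```r
report <- run_study(study_config(n_subjects = 5, master_seed = 1234))
print(report)
#> In-silico dark- vs bright-blood T2*w study: 20 subjects in 4 cells
#>   1.5T acute   relSNR  77.2%  relCNR  85.6%  extent BB 6.70 / DB 5.33 %LV  bias +1.37  sens 1.00
#>   3T acute     relSNR  62.0%  relCNR  67.2%  extent BB 7.37 / DB 5.76 %LV  bias +1.61  sens 1.00
#>   1.5T chronic relSNR  77.4%  relCNR  78.6%  extent BB 3.01 / DB 2.85 %LV  bias +0.17  sens 1.00
#>   3T chronic   relSNR  62.3%  relCNR  61.5%  extent BB 3.17 / DB 2.94 %LV  bias +0.23  sens 1.00
#>   in-vivo bright vs ex-vivo extent: y = 0.94x +0.18, R2 = 0.99
```

Every cell shows the dark arm below 100% relative SNR/CNR (more so at
3 T), a smaller measured IMH extent with positive bright-minus-dark bias,
and a strong in-vivo/ex-vivo extent correlation. `report$per_subject`
holds the per-subject rows behind each summary; with `out_dir` set, the
tables and a run log with every preset echoed are written as CSV/text. A
command-line wrapper lives at `inst/cli/run_study.R`.

See the vignette (`vignettes/dark-blood-t2star-methods.Rmd`) for the
model, preset calibration, numerical conventions and limitations.

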