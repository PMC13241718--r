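# scarseg

Interactive myocardial scar segmentation and quantification for
late gadolinium enhancement cardiovascular MR (LGE-CMR), in R.

After myocardial infarction, the mass of scarred myocardium on LGE-CMR
predicts mortality, arrhythmia, and response to revascularization — but
manual delineation is slow and poorly reproducible, and semi-automated
thresholding (the full-width-at-half-maximum method, FWHM) is sensitive to
operator choices. `scarseg` implements a prompt-driven alternative for
researchers studying interactive segmentation workflows: a segmentation
backbone conditioned on user prompts (a bounding box around the scar
and/or a few positive clicks), trained with an uncertainty-aware composite
loss on Gaussian-smoothed soft labels

    L_total = λ_Dice·L_Dice + λ_BCE·L_BCE + λ_KL·L_KL,
    L_KL    = Σ_i s_i log( s_i / (p_i + ε) ),

plus scar-mass quantification from voxel geometry (1.05 g/cm³ myocardial
density), the FWHM reference method with exclusion zones, and the
repeatability statistics used in method-agreement studies (Bland–Altman,
ICC, CCC, within-subject CV, paired t). Because clinical LGE data cannot
be redistributed, the package ships a seeded synthetic short-axis phantom
generator — annular myocardium, bright blood pool, hyperenhanced
subendocardial scar wedge, bias field and noise, exact ground-truth
masks, simulated raters — on which every component runs end to end on a
laptop CPU.

## Worked example

Generate a phantom slice, segment it with the FWHM reference method, and
quantify:

```r
library(scarseg)

sl <- generate_slice(phantom_spec(seed = 1))   # 128x128, 1.5 mm, 8 mm thick
sum(sl$scar_mask)                              # 100 ground-truth scar pixels
scar_mass(sl$scar_mask, sl$geometry)           # 1.89 g

# operator ROI at the enhancement peak, then half-peak thresholding
roi <- sl$scar_mask * 0
pk  <- which(sl$image * sl$scar_mask == max(sl$image * sl$scar_mask), arr.ind = TRUE)
roi[pk[1, 1] + -1:1, pk[1, 2] + -1:1] <- sl$scar_mask[pk[1, 1] + -1:1, pk[1, 2] + -1:1]
fw <- fwhm_segment(sl$image, sl$myo_mask, roi)
quantify_slice(fw, sl$scar_mask, sl$geometry,
               lv_mass = scar_mass(sl$myo_mask, sl$geometry))
#>   dsc hd_mm pred_mass_g gt_mass_g mass_error_g mass_error_pct_lv
#> 1   1     0        1.89      1.89            0                 0
```

`dsc = 1` and zero mass error: on this noise level the half-peak threshold
separates scar from remote myocardium exactly. Prompts serialize to JSON:

```r
p <- make_prompt(sl$scar_mask, "box_and_points", seed = 2)
prompt_to_json(p)
#> {"box":[67,55,81,79],"points":[[70,72],[76,70],[76,58],...],"strategy":"box_and_points"}
```

Repeatability statistics for two simulated raters measuring 41 subjects:

```r
set.seed(3)
truth <- rnorm(41, 30, 12)                       # true scar masses, g
r1 <- truth + rnorm(41, 0, 0.3)                  # rater 1
r2 <- truth + rnorm(41, -0.08, 0.3)              # rater 2 (slight bias)
agreement_report(r1, r2)
#>   n pairs        : 41
#>   bias           : 0.0871
#>   95% LoA        : [-0.5337, 0.7079]
#>   Lin's CCC      : 0.9995
#>   ICC (single)   : 0.9995
#>   CV %           : 0.78
#>   paired t, p    : 1.7608, 0.08592
```

Sub-gram limits of agreement and ICC ≈ 1 mean the two raters are clinically
interchangeable; `bonett_n(0.9, 0.1, k = 2)` (= 57) gives the sample size
needed to estimate an ICC near 0.90 with a 0.10-wide confidence interval.

Training the built-in prompt-conditioned backbone on a phantom cohort:

```r
cohort <- generate_cohort(125, make_spec_sampler(grid_size = 64),
                          slices_per_subject = 2, seed = 11)
split  <- stratified_split(cohort, c(0.8, 0.2, 0), seed = 11)   # by scar burden
slices <- lapply(cohort, normalize_intensity)
ids    <- vapply(slices, function(r) r$subject_id, character(1))
fit <- train_backbone(tiny_backbone(seed = 11),
                      slices[ids %in% split$train], slices[ids %in% split$val],
                      train_config(lr0 = 3e-3, max_epochs = 30, seed = 11))
evaluate_dsc(fit$backbone, slices[ids %in% split$val], "box_and_points")
#> [1] 0.9263496
```

A command-line interface wrapping the same functions is installed at
`inst/cli/scarseg` (subcommands: phantom, preprocess, augment, train,
segment, quantify, agreement, quality).

## Package layout

| Area | Functions |
|---|---|
| Phantom | `phantom_spec`, `generate_slice`, `generate_cohort`, `stratified_split`, `simulate_rater` |
| Preprocess | `resample_to_grid`, `normalize_intensity`, `preprocess_slice` |
| Augmentation | `augment_config`, `sample_transform`, `apply_spatial`, `apply_intensity`, `plan_to_json` |
| Supervision | `make_soft_labels`, `dice_loss`, `bce_loss`, `kl_loss`, `total_loss` |
| Prompts | `bbox_from_mask`, `augment_box`, `sample_points`, `make_prompt`, `box_iou` |
| Engine | `tiny_backbone`, `train_backbone`, `predict_mask`, `refine_mask`, `lr_at_epoch` |
| Quantify | `dsc`, `hausdorff_mm`, `scar_mass`, `mass_error`, `fwhm_segment`, `quantify_slice` |
| Agreement | `bland_altman`, `ccc`, `icc`, `cv_pct`, `paired_t`, `bonett_n`, `agreement_report` |
| Quality | `quality_metrics`, `cluster_quality`, `compare_groups` |
| I/O & CLI | `read_slice`, `write_slice`, `write_cohort`, `run_cli` |

See `vignettes/scarseg-methods.Rmd` for the full model description,
parameter choices, and limitations.
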