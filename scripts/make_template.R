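#!/usr/bin/env Rscript
# Build the packaged default BOS template from the synthetic COP-excursion
# generator and store it as JSON under inst/extdata. Run from the
# repository root. The template is synthetic: it emulates the calibration
# protocol (full-range COP excursions on each foot) rather than reproducing
# any laboratory measurement.

suppressMessages(pkgload::load_all(".", quiet = TRUE))

trial <- generate_cop_excursion_trial(foot_length = 0.25, foot_width = 0.09,
                                      seed = 20260926L)
profiles <- cop_excursion_profiles(trial)
template <- build_template(profiles, body_weight = trial$meta$body_weight,
                           n_rays = 360L)
# round to 1e-6 normalized units to keep the JSON compact
template$vertices <- round(template$vertices, 6)
write_bos_template(template, "inst/extdata/bos_template_synthetic.json")
cat("wrote", nrow(template$vertices), "vertices, area",
    stsbalance:::polygon_area(template$vertices), "\n")
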