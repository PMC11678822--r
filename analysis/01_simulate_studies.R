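#!/usr/bin/env Rscript
# Simulate the four crossover studies analysed downstream: pilot (n = 24)
# and pivotal (n = 106 / n = 98 completers scale) studies at the 200 mg
# and 400 mg strengths, all on the 20-point 0-72 h sampling grid with a
# true GMR of 1 and an intra-subject CV of 50%. Raw concentration tables
# go to scratch/data/ (large); the study configurations go with them so
# later scripts can re-read everything through the package's I/O layer.

library(bepilot)

studies <- list(
  pilot_200   = list(preset = "pazopanib_200", n = 24L,  seed = 201L),
  pivotal_200 = list(preset = "pazopanib_200", n = 106L, seed = 202L),
  pilot_400   = list(preset = "pazopanib_400", n = 24L,  seed = 401L),
  pivotal_400 = list(preset = "pazopanib_400", n = 98L,  seed = 402L))

dir.create("scratch/data", showWarnings = FALSE, recursive = TRUE)
for (nm in names(studies)) {
  s <- studies[[nm]]
  ps <- study_preset(s$preset, n_subjects = s$n)
  st <- simulate_study(ps$params, ps$var, ps$design, seed = s$seed,
                       label = nm)
  write_study(st, file.path("scratch/data", paste0(nm, ".csv")))
  yaml::write_yaml(list(lloq_ng_ml = st$lloq_ng_ml, dose_mg = st$dose_mg,
                        nominal_times_h = st$nominal_times_h,
                        label = st$label),
                   file.path("scratch/data", paste0(nm, ".yaml")))
  print(st)
}
cat("\nWrote", length(studies), "study CSVs + configs under scratch/data/\n")
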