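#!/usr/bin/env Rscript
## The six-configuration comparative study: every catalog implant under
## the three physiological load cases, on the default phantom at the
## desk-scale coarse mesh preset.

library(stemfea)

cfg <- coarse_preset(study_config(models = 1:6,
                                  output_dir = "results/study"),
                     size = 3)
t0 <- Sys.time()
report <- run_study(cfg)
cat("study wall time:", format(Sys.time() - t0), "\n")
print(report$rows, digits = 4)
if (length(report$failed)) cat("FAILED:", report$failed, "\n")
cat("rows:", nrow(report$rows), "; artifacts in results/study\n")
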