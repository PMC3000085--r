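#!/usr/bin/env Rscript
# Generate three synthetic congeneric series sized like the classes of a
# classical Aurora-B inhibitor QSAR campaign (24/8, 33/8 with one planted
# outlier, 24/7) at realistic assay noise, and persist them as SDF + activity CSV +
# truth JSON under results/series/.

suppressMessages(library(qsar3d))

out <- "results/series"
fx <- benchmark_fixtures()          # default noise_sd = 0.25 log units

for (nm in names(fx)) {
  paths <- write_series(fx[[nm]], file.path(out, nm), paste0("series_", nm))
  ser <- fx[[nm]]
  acts <- vapply(c(ser$train, ser$test), function(m) m$activity, numeric(1))
  cat(sprintf(
    "series %s: %d train / %d test, activities %.3f..%.3f, planted %s%s\n",
    nm, length(ser$train), length(ser$test), min(acts), max(acts),
    paste(ser$truth$planted_kinds, collapse = "+"),
    if (length(ser$truth$outlier_ids))
      paste0(", planted outlier ", ser$truth$outlier_ids) else ""))
}
cat("written under", out, "\n")
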