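#!/usr/bin/env Rscript
# StDev*Coeff contour grids for the top model of each series, at the
# contribution levels classically used for these map types (steric 95/5,
# electrostatic 75/25 or 80/20, hydrophobic 80/20, donor 80/20 or 85/15),
# exported as OpenDX volumes with JSON sidecars under
# results/contours_<series>/.

suppressMessages(library(qsar3d))

levels_for <- function(kind, series) {
  if (series == "A" && kind == "comsia_S") c(95, 5)
  else if (series == "A" && kind == "comsia_E") c(75, 25)
  else if (series == "C" && kind == "comsia_D") c(85, 15)
  else c(80, 20)
}

fx <- benchmark_fixtures()
for (nm in names(fx)) {
  ser <- fx[[nm]]
  tr <- ser$train
  sc <- search_config(bootstrap_runs = 0, seed = 1)
  s <- run_search(tr, ser$test, lattice = ser$lattice, sconfig = sc)
  fl <- flag_outliers(s, tr)
  if (any(fl$flagged)) {
    keep <- !vapply(tr, function(m) m$id %in% fl$id[fl$flagged], logical(1))
    s <- run_search(tr[keep], ser$test, lattice = ser$lattice, sconfig = sc)
  }
  top <- top_candidate(s)
  outdir <- file.path("results", paste0("contours_", nm))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (k in top$kinds) {
    lv <- levels_for(k, nm)
    g <- stdev_coeff_grid(top$model, top$dset, s$lattice, k)
    g <- levels_by_contribution(g, lv[1], lv[2])
    path <- file.path(outdir, paste0("contour_", k, ".dx"))
    export_grid(g, path, format = "dx")
    cat(sprintf(
      "series %s %s: favored level (%d%%) %.3g, disfavored (%d%%) %.3g -> %s\n",
      nm, k, lv[1], g$favored_level, lv[2], g$disfavored_level, path))
  }
}
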