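#!/usr/bin/env Rscript

# Stage 1: synthesize the study cohort.
#
# Eight subjects, each scanned in triplicate, at the 234-region
# parcellation: 24 structural connectomes drawn from the degree-corrected
# weighted block model (8 communities, 12 rich-club hubs, 10% scan noise),
# plus the region-to-cognitive-system label table. Matrices are written as
# edge-list TSVs so the later stages (and any external tool) can re-read
# them; a summary line per scan reports density and strength statistics.

library(netctrl)

seed <- 42
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

params <- generator_params(seed = seed)
cohort <- generate_cohort(params, n_subjects = 8, n_scans = 3)
labels <- generate_system_labels(params$n_regions, seed = seed)
write_system_labels(labels, file.path(out_dir, "labels.tsv"))

for (conn in cohort) {
  f <- sprintf("connectome_%s_scan%s.tsv", conn$subject, conn$scan)
  write_connectome(conn, file.path(out_dir, f), format = "edgelist")
  w <- conn$A[upper.tri(conn$A)]
  message(sprintf(
    "%s scan %s: density %.3f, median weight %g, max strength %g",
    conn$subject, conn$scan, mean(w > 0), median(w[w > 0]),
    max(weighted_degree(conn))))
}
message("cohort of ", length(cohort), " connectomes written to ", out_dir)
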