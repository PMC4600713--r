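#!/usr/bin/env Rscript

# Stage 4: figures.
#
# Scatter plots of each controllability diagnostic (aggregated rank)
# against weighted-degree rank, a bar chart of size-normalized hub
# percentages per cognitive system, and group-wise hub means with
# across-subject dispersion.

library(netctrl)

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
mr <- utils::read.delim("results/mean_ranks.tsv")
enr <- utils::read.delim("results/enrichment.tsv")
hm <- utils::read.delim("results/system_hub_means.tsv")

pdf("results/figures/degree_scatter.pdf", width = 9, height = 3.2)
op <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
for (d in c("avg_ctrl", "modal_ctrl", "boundary_ctrl")) {
  r <- cor(mr[[d]], mr$degree)
  plot(mr$degree, mr[[d]], pch = 16, cex = 0.6,
       col = "#00000080", xlab = "weighted degree (mean rank)",
       ylab = paste(d, "(mean rank)"),
       main = sprintf("%s  r = %.2f", d, r))
}
par(op)
dev.off()

pdf("results/figures/system_enrichment.pdf", width = 8, height = 4)
op <- par(mar = c(9, 4, 2, 1))
wide <- t(sapply(split(enr, enr$diagnostic),
                 function(e) e$norm_pct[order(e$system)]))
colnames(wide) <- sort(unique(enr$system))
barplot(wide, beside = TRUE, las = 2,
        ylab = "size-normalized hub share (%)",
        legend.text = rownames(wide), args.legend = list(x = "topright"))
par(op)
dev.off()

pdf("results/figures/group_hub_means.pdf", width = 6, height = 4)
op <- par(mar = c(8, 4, 2, 1))
groups <- unique(hm$group)
diags <- unique(hm$diagnostic)
vals <- sapply(groups, function(g)
  sapply(diags, function(d) {
    v <- hm$mean_ctrl[hm$group == g & hm$diagnostic == d]
    if (length(v)) v else NA
  }))
bp <- barplot(vals, beside = TRUE, las = 2, ylab = "mean hub rank",
              legend.text = diags, args.legend = list(x = "topright"))
sds <- sapply(groups, function(g)
  sapply(diags, function(d) {
    v <- hm$sd_across_subjects[hm$group == g & hm$diagnostic == d]
    if (length(v)) v else NA
  }))
arrows(bp, vals - sds, bp, vals + sds, angle = 90, code = 3,
       length = 0.03)
par(op)
dev.off()

message("figures written to results/figures/")
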