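#!/usr/bin/env Rscript
# Exploratory and summary figures: 3-D t-SNE of per-segment band feature
# vectors, the per-subject colorplot, the per-band accuracy chart, the
# p-value grid and the directed-connectivity diagram.

library(pdcnet)

fset <- readRDS("results/feature_set.rds")
sw <- readRDS("results/band_sweep.rds")
mask <- readRDS("results/gamma_mask.rds")

files <- render_outputs("results/figures", fset = fset, sweep = sw,
                        mask = mask, node_labels = fset$node_labels,
                        summary_table = read.csv("results/rhythm_summary.csv"))

# t-SNE of the band-60 feature vectors, colored by class
y <- tsne_embed(fset$tables[["band60"]], dims = 3, perplexity = 30, seed = 3)
df <- data.frame(d1 = y[, 1], d2 = y[, 2], class = fset$meta$class_label)
p <- ggplot2::ggplot(df, ggplot2::aes(d1, d2, colour = class)) +
  ggplot2::geom_point(alpha = 0.7) +
  ggplot2::labs(title = "t-SNE of band-60 PDC feature vectors (dims 1-2 of 3)")
ggplot2::ggsave("results/figures/tsne_band60.png", p, width = 6, height = 5)

cat("Figures written:\n")
for (f in c(files, "results/figures/tsne_band60.png")) cat(" ", f, "\n")
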