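#!/usr/bin/env Rscript
# Step 4 - aggregate the CV records into win-percentage curves over the
# cutoff grid (the shape of the published four-panel comparison: model-
# vs-model win percentage against C, with the removed-data fraction as the
# secondary axis) and plot them.
#
# Reads results/cv_records.csv, writes results/curves.csv and, when ggplot2
# is available, results/comparison_curves.pdf.

suppressPackageStartupMessages(library(affectdyn))
rec <- read.csv("results/cv_records.csv")

curves <- do.call(rbind, lapply(split(rec, rec$study), function(r) {
  cur <- build_curve(r[, setdiff(names(r), "study")])
  cur$study <- r$study[1]
  as.data.frame(cur)
}))
write_curve_csv(curves, "results/curves.csv")
print(curves, digits = 3)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  long <- do.call(rbind, lapply(
    c("ou_vs_var", "ou_vs_stationary", "var_vs_stationary"),
    function(p) data.frame(study = curves$study, cutoff = curves$cutoff,
                           pair = p, win = curves[[p]],
                           removed = curves$removed_fraction)))
  long$x <- ifelse(is.infinite(long$cutoff), 12, long$cutoff)
  gg <- ggplot(long, aes(x, win, colour = pair)) +
    geom_area(aes(y = removed), fill = "grey80", colour = NA) +
    geom_line() + geom_point() +
    scale_x_reverse(breaks = c(12, 10, 8, 6),
                    labels = c(expression(infinity), "10", "8", "6")) +
    facet_wrap(~study) +
    labs(x = "MAD cutoff C (more removed to the right)",
         y = "win fraction / removed fraction") +
    theme_minimal()
  ggsave("results/comparison_curves.pdf", gg, width = 9, height = 4)
  message("wrote results/comparison_curves.pdf")
}
message("wrote results/curves.csv")
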