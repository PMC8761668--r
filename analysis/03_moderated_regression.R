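#!/usr/bin/env Rscript
# Step 3: hierarchical moderated regression and region of significance.
#
# Education enters first, then the main effects of standardized MAST and
# carrier status, then their product. A significant product term is
# followed up with per-group simple slopes, the crossover point of the
# two genotype groups' regression lines with a bootstrap 95% CI, and the
# Johnson-Neyman bounds outside which the group difference is
# significant.

suppressPackageStartupMessages(library(gxecross))
cohort <- read_cohort("results/cohort.tsv")
dat <- analysis_frame(cohort)

hier <- hierarchical_fit(dat)
print(hier)

ros <- ros_analysis(dat, ci_method = "bootstrap", n_boot = 2000, seed = 17)
cat("\n")
print(ros)

steps_tab <- do.call(rbind, lapply(hier$steps, function(s) {
  tab <- s$coefficients[s$coefficients$term %in% s$terms_added, ]
  cbind(step = s$step, tab, delta_r2 = s$delta_r2, r2 = s$r2)
}))
utils::write.table(format(steps_tab, digits = 4),
                   "results/hierarchical_regression.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
jsonlite::write_json(
  list(crossover = ros$crossover, ci = ros$crossover_ci,
       jn = ros$jn, slopes = ros$slopes, x_range = ros$x_range),
  "results/ros.json", auto_unbox = TRUE, digits = NA, na = "null")

dir.create("results/figures", showWarnings = FALSE)
grDevices::pdf("results/figures/ros_crossover.pdf", width = 6, height = 5)
plot(ros, main = "Group regression lines and crossover 95% CI")
dev.off()
cat("\nwrote results/hierarchical_regression.tsv, results/ros.json,",
    "results/figures/ros_crossover.pdf\n")
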