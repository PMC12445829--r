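#!/usr/bin/env Rscript
# Stage 4 -- ring-width processing: RWL ingest, spline detrending (50%
# frequency cutoff at 30 yr), core averaging, biweight site chronologies and
# chronology quality statistics (rbar, EPS, AR1, mean sensitivity).

library(frostring)

data_dir <- "results/data"
out <- "results"

stats_rows <- list()
for (s in c("high", "low")) {
  for (sp in c("sensitive", "reference")) {
    rwl <- read_rwl(file.path(data_dir, sprintf("rings_%s_%s.rwl", s, sp)))
    trees <- average_cores(detrend_rwl(rwl, nyrs = 30))
    chron <- biweight_chronology(trees)
    st <- chronology_stats(trees)
    write.csv(chron, file.path(out, sprintf("chronology_%s_%s.csv", s, sp)),
              row.names = FALSE, quote = FALSE)
    stats_rows[[paste(s, sp)]] <- data.frame(
      site = s, species = sp, n_trees = st$n_trees,
      first = st$span[1], last = st$span[2],
      rbar = st$rbar, eps = st$eps, ar1 = st$ar1,
      mean_sensitivity = st$mean_sensitivity)
  }
}
stats_tab <- do.call(rbind, stats_rows)
rownames(stats_tab) <- NULL
write.csv(stats_tab, file.path(out, "chronology_stats.csv"),
          row.names = FALSE, quote = FALSE)
print(stats_tab, digits = 3)
cat("\nEPS above the conventional 0.85 quality threshold:",
    all(stats_tab$eps > 0.85), "\n")
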