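#!/usr/bin/env Rscript
# Stage 3 -- climate/phenology frost risk: last spring frosts, safety
# margins, damage-window flags and their temporal trends.
#
# For every site-year: the last day through June with tmin <= -1.0 degC, the
# safety margin (predicted leaf-out minus last frost; negative = frost after
# leaf-out) and whether any frost <= -1.0 degC falls within 5 d before to
# 14 d after predicted leaf-out. Trends are Theil-Sen slopes (d per decade)
# with Mann-Kendall significance.

library(frostring)

data_dir <- "results/data"
out <- "results"

sites <- data.frame(site_id = c("high", "low"), latitude = 47.4,
                    elevation = c(1365, 1085))
records <- list()
trends <- list()
for (s in sites$site_id) {
  cl <- read_climate_csv(file.path(data_dir, sprintf("climate_%s.csv", s)), sites)[[s]]
  leaf <- read.csv(file.path(out, sprintf("leafout_%s.csv", s)))
  rec <- safety_margin_records(cl, leaf, threshold = -1, window = c(-5L, 14L))
  write.csv(rec, file.path(out, sprintf("safety_margin_%s.csv", s)),
            row.names = FALSE, quote = FALSE)
  records[[s]] <- rec
  trends[[s]] <- list(
    leafout = unclass(theil_sen_trend(rec$leafout_doy, rec$year)),
    last_frost = unclass(theil_sen_trend(rec$last_frost_doy, rec$year)),
    safety_margin = unclass(theil_sen_trend(rec$margin_days, rec$year)))
  cat(sprintf("site %s: leaf-out trend %+.2f d/decade (p=%.3f), last frost %+.2f (p=%.3f), margin %+.2f (p=%.3f)\n",
              s, trends[[s]]$leafout$slope, trends[[s]]$leafout$mk_p,
              trends[[s]]$last_frost$slope, trends[[s]]$last_frost$mk_p,
              trends[[s]]$safety_margin$slope, trends[[s]]$safety_margin$mk_p))
}
jsonlite::write_json(trends, file.path(out, "frost_trends.json"),
                     auto_unbox = TRUE, digits = NA)

rs <- risk_summary(do.call(rbind, records),
                   periods = list(c(1931, 1976), c(1977, 2021)))
write.csv(rs$by_site, file.path(out, "risk_summary.csv"),
          row.names = FALSE, quote = FALSE)
write.csv(rs$moving_average, file.path(out, "safety_margin_ma10.csv"),
          row.names = FALSE, quote = FALSE)
print(rs$by_site)
print(rs$negative_by_period)
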