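#!/usr/bin/env Rscript
# Build occupancy-rate and log growth-rate series from the simulated
# survey, plus the site distance matrix used by the synchrony analysis.

library(moransync)

survey <- read.csv("results/data/survey.csv")
series <- growth_rate(occupancy_rate(survey))
write.csv(as.data.frame(series), "results/series.csv", row.names = FALSE)

centres <- site_centres(series)
D <- pairwise_distance(centres)
write.csv(data.frame(site = rownames(D), round(D, 2)),
          "results/site_distances_km.csv", row.names = FALSE)

cat(sprintf("%d sites, %d site-years, %d growth-rate observations\n",
            length(unique(series$site)), nrow(series),
            sum(!is.na(series$growth))))
cat(sprintf("inter-site distances %.0f-%.0f km (mean %.0f)\n",
            min(D[upper.tri(D)]), max(D[upper.tri(D)]),
            mean(D[upper.tri(D)])))
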