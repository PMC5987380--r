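#!/usr/bin/env Rscript
# Per-percentile three-way factorial significance maps for Ct.Th, CSA and
# ellipticity (7 effect rows x 81 percent columns, banded red / yellow /
# green / blue), plus midshaft group means with 95% CI.
#
# Reads:  results/cortical_profile.csv (from 04_cortical_profiles.R)
# Writes: results/statmap.csv, results/group_summary_midshaft.csv,
#         results/statmap_<response>.svg

library(tibiamorph)

profiles <- read.csv("results/cortical_profile.csv")
responses <- c("ct_th_mm", "csa_mm2", "ellipticity")

sm <- heatmap_statmap(profiles, responses)
write.csv(sm, "results/statmap.csv", row.names = FALSE)

mid <- profiles[profiles$percent == 50, ]
gs <- do.call(rbind, lapply(responses, function(r) {
  cbind(response = r, group_summary(mid, r))
}))
write.csv(gs, "results/group_summary_midshaft.csv", row.names = FALSE)

if (capabilities("cairo")) {
  for (r in responses) {
    svg(sprintf("results/statmap_%s.svg", r), width = 8, height = 3)
    print(plot_statmap(sm, r))
    dev.off()
  }
}

for (r in responses) {
  sub <- sm[sm$response == r, ]
  nb <- tapply(sub$band != "blue", sub$effect, sum)
  message(sprintf("%s: non-blue percentiles per effect row:", r))
  print(nb)
}
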