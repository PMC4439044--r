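#!/usr/bin/env Rscript
# Stage 2: expand the trapped catch into seasonal passage estimates by
# phenotype (quasibinomial efficiency model + 2000 beta-binomial
# Monte-Carlo draws) and summarise migration phenology.

library(phenosurv)

world <- read_world("results/world")
daily <- daily_phenotype_catch(world$inputs$catch, world$inputs$measured)
eff <- fit_efficiency(world$inputs$trials)
print(eff)

est <- simulate_passage(daily, eff, world$inputs$environment,
                        n_draws = 2000, seed = 20101L)
print(est)

se_J <- vapply(phenotype_levels(), function(p) {
  row <- est$estimates[est$estimates$phenotype == p, ]
  se_from_interval(row$point, row$lo95, row$hi95, draws = est$draws[, p])
}, numeric(1))
out <- est$estimates
out$se <- c(se_J, NA)[match(out$phenotype, c(phenotype_levels(), "total"))]
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/passage_estimates.csv", row.names = FALSE)

phen <- do.call(rbind, lapply(phenotype_levels(), function(p) {
  cbind(phenotype = p, phenology(est$daily$date, est$daily[[p]]))
}))
write.csv(phen, "results/phenology.csv", row.names = FALSE)
cat("\nPhenology (range, IQR, median date):\n")
print(phen, row.names = FALSE)

if (!is.null(world$truth)) {
  truth <- unlist(world$truth$totals)
  idx <- match(phenotype_levels(), out$phenotype)
  cat("\nRelative error of point estimates vs truth:\n")
  print(round(out$point[idx] / truth - 1, 3))
}
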