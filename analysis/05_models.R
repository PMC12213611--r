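#!/usr/bin/env Rscript
# Model selection over the site aggregates: for each analysis (whole
# profile, organic horizons, mineral horizons) build the candidate set
# around SOC ~ FRC + MAT + MAP + clay + ecosystem class with a random
# intercept for the profile-depth bin, fit all reductions, and select by
# AIC (AICc when n < 40, the full model ineligible). Also runs the
# diameter-protocol rank check on the whole-profile residuals.

suppressPackageStartupMessages(library(rootsoc))

src <- "results/synthetic"
t <- read_site_tables(file.path(src, "sites.csv"),
                      file.path(src, "horizons.csv"),
                      file.path(src, "roots.csv"))
agg <- site_aggregates(t)
agg$depth_bin <- depth_bin(agg$max_profile_depth)

reports <- list()
for (an in c("whole", "organic", "mineral")) {
  resp <- switch(an, whole = "soc_total", organic = "soc_organic",
                 mineral = "soc_mineral")
  frc <- switch(an, whole = "frc_total", organic = "frc_organic",
                mineral = "frc_mineral")
  dat <- agg
  if (an == "organic") {       # only sites that have organic horizons
    dat <- agg[agg$soc_organic > 0, ]
    dat$depth_bin <- droplevels(dat$depth_bin)
  }
  use_random <- length(unique(dat$depth_bin)) > 1
  sel <- select_soc_model(dat, response = resp,
                          fixed = c(frc, "mat", "map", "clay_profile",
                                    "ecosystem_class"),
                          random = if (use_random) "depth_bin")
  reports[[an]] <- model_report(sel)
  b <- sel$selected
  cat(sprintf("%-8s n=%2d  %s: %s ~ %s  (pseudo R2 = %.2f)\n", an, b$n,
              toupper(sel$criterion), resp,
              if (length(b$spec$fixed)) paste(b$spec$fixed, collapse = " + ")
              else "1",
              if (is.na(b$marginal_pseudo_r2)) b$adj_r2
              else b$marginal_pseudo_r2))
}

# does the 2-mm vs 4-mm fine-root cutoff drive the FRC-SOC residuals?
res <- residuals(lm(soc_total ~ frc_total, agg))
proto <- t$roots$diameter_protocol[match(agg$site_id, t$roots$site_id)]
w <- diameter_protocol_check(res, proto)
cat(sprintf("diameter protocols: Z = %.2f, p = %.2f (n = %d vs %d)\n",
            w$z, w$p.value, w$n_2mm, w$n_4mm))
reports$diameter_protocol <- w[c("statistic", "z", "p.value",
                                 "n_2mm", "n_4mm")]

write_outputs(list(models = reports), "results")
cat("wrote results/models.json\n")
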