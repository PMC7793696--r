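#!/usr/bin/env Rscript
# Trend statistics on the per-run summaries: per group, the mixed-effects
# session/run model (Type I ANOVA, Satterthwaite df) with its two-stage
# cross-check, for SMR imaginary coherence and MSC; plus a paired pre/post
# comparison of the session-1 vs session-10 baseline-run coherence.
# Tables -> results/.

library(smrcoh)

summaries <- utils::read.csv("results/run_summaries.csv")

for (outc in c("band_imcoh", "band_msc")) {
  res <- analyze_summaries(summaries, outcome = outc, out_dir = "results")
  message("== ", outc, " ==")
  print(as.data.frame(res$anova_table), digits = 4)
  for (g in names(res$trends)) {
    ts <- res$trends[[g]]$two_stage
    message(sprintf(
      "%s group two-stage: session %.5f (p = %.4f), run %.5f (p = %.4f)",
      g, ts$session$mean_slope, ts$session$p, ts$run$mean_slope, ts$run$p))
  }
}

# pre/post: baseline-run coherence in the first vs last session, per group
pp <- do.call(rbind, lapply(unique(summaries$group), function(g) {
  d <- summaries[summaries$group == g & summaries$run == 1, ]
  pre <- d$band_imcoh[d$session == 1][order(d$subject[d$session == 1])]
  post <- d$band_imcoh[d$session == 10][order(d$subject[d$session == 10])]
  cbind(group = g, prepost_tests(pre, post, family_size = 2))
}))
message("baseline-run ImCoh, session 1 vs 10:")
print(as.data.frame(pp), digits = 3)
utils::write.csv(pp, "results/prepost_baseline_imcoh.csv", row.names = FALSE)
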