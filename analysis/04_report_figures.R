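#!/usr/bin/env Rscript
# Training-performance figures: SMR coherence by run (within-session, averaged
# over sessions) and by session (between-session, averaged over runs), per
# group, with Cousineau-Morey within-subject error bars ->
# results/figures/.

library(smrcoh)

summaries <- utils::read.csv("results/run_summaries.csv")
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

curves <- training_curves(summaries, "band_imcoh")
utils::write.csv(curves$by_run, "results/figures/curve_by_run.csv",
                 row.names = FALSE)
utils::write.csv(curves$by_session, "results/figures/curve_by_session.csv",
                 row.names = FALSE)

plots <- plot_training_curves(summaries, "band_imcoh")
ggplot2::ggsave("results/figures/imcoh_by_run.pdf", plots$by_run,
                width = 5, height = 3.5)
ggplot2::ggsave("results/figures/imcoh_by_session.pdf", plots$by_session,
                width = 5, height = 3.5)
message("wrote training-curve tables and figures under results/figures/")
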