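#!/usr/bin/env Rscript
# Step 1 — simulate the cohort and its telemetry.
#
# Generates the default 116-participant cohort (38 CN / 64 MCI / 14 MD),
# calibrated to the published group demographics, neuropsychological scores
# and baseline game performance, then simulates 24 training sessions per
# participant (3/week x 8 weeks, promotion to a higher difficulty level
# every 6 sessions). Public CSV interfaces go to results/; the bulky raw
# telemetry and a binary snapshot for the downstream steps go to scratch/.

suppressPackageStartupMessages(library(exerscreen))

seed <- 60928L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
cat(sprintf("Cohort: %d participants (%s)\n", nrow(cohort),
            paste(sprintf("%s=%d", names(table(cohort$group)),
                          table(cohort$group)), collapse = ", ")))

plays <- simulate_cohort_sessions(cohort, cfg)
cat(sprintf("Telemetry: %d plays over %d sessions/participant\n",
            nrow(plays), cfg$sessions_per_week * cfg$n_weeks))

write_participants_csv(cohort, "results/participants.csv")
write_sessions_csv(plays, "scratch/sessions.csv")
saveRDS(list(cfg = cfg, cohort = cohort, plays = plays), "scratch/01_simulated.rds")
cat("Wrote results/participants.csv, scratch/sessions.csv\n")
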