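#!/usr/bin/env Rscript
# Step 2 — score the telemetry and extract trend features.
#
# Applies the weighted per-game scoring equations, normalizes to the
# 10-point scale, aggregates per session and domain, and fits the
# mean/slope/intercept trend features for the total period and each
# difficulty level. Also writes a per-group calibration summary that can be
# compared against the published cohort table.

suppressPackageStartupMessages({library(exerscreen); library(dplyr)})

sim <- readRDS("scratch/01_simulated.rds")
scores <- score_sessions(sim$plays)
features <- build_feature_matrix(scores, sim$cohort)
cat(sprintf("Features: %d participants x %d features\n",
            nrow(features), length(feature_names(features))))

s1 <- scores |>
  filter(session_index == 1, !domain %in% c("heart_rate", "borg")) |>
  inner_join(select(sim$cohort, id, group), by = c(participant_id = "id")) |>
  group_by(group, domain) |>
  summarise(session1_mean = mean(score), .groups = "drop")
hr <- scores |>
  filter(domain == "heart_rate") |>
  inner_join(select(sim$cohort, id, group), by = c(participant_id = "id")) |>
  group_by(group) |>
  summarise(mean_heart_rate = mean(score), .groups = "drop")
summary_tbl <- sim$cohort |>
  group_by(group) |>
  summarise(n = dplyr::n(), age = mean(age), education = mean(education),
            mmse = mean(mmse), moca = mean(moca),
            tmt_a = mean(tmt_a), tmt_b = mean(tmt_b), .groups = "drop") |>
  left_join(hr, by = "group")
print(as.data.frame(summary_tbl), digits = 4)
print(as.data.frame(tidyr::pivot_wider(s1, names_from = domain,
                                       values_from = session1_mean)), digits = 3)

readr::write_csv(summary_tbl, "results/cohort_summary.csv")
readr::write_csv(s1, "results/session1_domain_means.csv")
readr::write_csv(features, "scratch/features.csv")
saveRDS(list(scores = scores, features = features), "scratch/02_features.rds")
cat("Wrote results/cohort_summary.csv, results/session1_domain_means.csv\n")
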