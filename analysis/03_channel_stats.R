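#!/usr/bin/env Rscript
# Channel-space group statistics per condition: baseline mixture, pointwise
# Welch tests with Bonferroni over channels x samples, run-length
# continuity filtering, response classification and the lance-to-touch
# signal-to-noise ratio.

source("analysis/00_common.R")

geo <- study_geometry()
cohort <- simulate_cohort(geo)

stats_rows <- list()
summary_rows <- list()
for (cond in names(cohort)) {
  eps <- epoch_averages(preprocess_condition(cohort[[cond]]))
  bl <- build_baseline(eps)
  pt <- continuity_filter(pointwise_test(eps, bl))
  cls <- classify_response(pt, eps)
  cls$condition <- cond
  stats_rows[[cond]] <- cls
  summary_rows[[cond]] <- data.frame(
    condition = cond,
    n_subjects = length(eps),
    n_comparisons = pt$n_comparisons,
    canonical = sum(cls$class == "canonical"),
    inverse = sum(cls$class == "inverse"),
    none = sum(cls$class == "none"),
    peak_uM = if (all(is.na(cls$peak_uM))) NA else
      round(max(cls$peak_uM, na.rm = TRUE), 3),
    latency_s = if (all(is.na(cls$peak_uM))) NA else
      round(cls$peak_latency_s[which.max(cls$peak_uM)], 1))
}
write.csv(do.call(rbind, stats_rows),
          results_path("03_channel_classes.csv"), row.names = FALSE)
write.csv(do.call(rbind, summary_rows),
          results_path("03_condition_summary.csv"), row.names = FALSE)

# signal-to-noise: lance single trials vs all pooled heel-touch trials
lance_peak <- suppressWarnings(max(stats_rows$lance_heel$peak_uM, na.rm = TRUE))
touch_peak <- suppressWarnings(max(stats_rows$touch_heel$peak_uM, na.rm = TRUE))
if (!is.finite(lance_peak) || !is.finite(touch_peak))
  stop("no classified response channel in a condition; rerun with a ",
       "different master seed or lower noise")
n_lance <- sum(vapply(cohort$lance_heel,
                      function(s) nrow(s$recording$events), 0L))
n_touch <- sum(vapply(cohort$touch_heel,
                      function(s) nrow(s$recording$events), 0L))
snr <- snr_ratio(lance_peak, n_lance, touch_peak, n_touch)
write.csv(data.frame(lance_peak_uM = lance_peak, lance_trials = n_lance,
                     touch_peak_uM = touch_peak, touch_trials = n_touch,
                     snr_ratio = snr),
          results_path("03_snr_ratio.csv"), row.names = FALSE)
cat("lance/touch SNR ratio:", snr, "\n")
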