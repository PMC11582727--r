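#!/usr/bin/env Rscript

# Stage 3 — behavioural evaluation.
#
# Reproduces the behavioural benchmark analyses on the simulated cohort:
# matching (choice ratios by programmed reward ratio), harvest rate, switch
# rates, the absDV-by-previous-feedback table for both tasks, and
# leave-one-out choice prediction (value task) plus the transfer of
# value-task parameters to the control task. Tables go to results/.

suppressPackageStartupMessages(library(foragefit))

in_dir <- "results/cohort"
files <- sort(list.files(in_dir, pattern = "_trials\\.tsv$",
                         full.names = TRUE))
if (length(files) == 0L) stop("run analysis/01_simulate.R first")
cohort <- lapply(files, read_trials)

message("matching table ...")
mt <- matching_table(cohort)
utils::write.table(mt, "results/matching_table.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
allr <- mt[mt$condition == "all", ]
message(sprintf("  choice ratio by reward ratio: %s",
                paste(sprintf("%s -> %.2f", allr$ratio, allr$choice_ratio),
                      collapse = ", ")))

sem <- function(x) sd(x) / sqrt(length(x))
metrics <- list()
add_metric <- function(name, x)
  metrics[[length(metrics) + 1L]] <<- data.frame(metric = name,
                                                 mean = mean(x), sem = sem(x),
                                                 n = length(x))

message("harvest and switch rates ...")
add_metric("harvest_pct", vapply(cohort, harvest_rate, 0))
add_metric("switch_value_pct", vapply(cohort, switch_rate, 0, "value"))
add_metric("switch_control_pct", vapply(cohort, switch_rate, 0, "control"))

message("absDV by previous feedback (both tasks) ...")
tabs <- lapply(cohort, absdv_by_feedback)
for (task in c("value", "control")) for (fb in c("blue", "yellow")) {
  x <- vapply(tabs, function(t)
    t$mean_absdv[t$task == task & t$prev_feedback == fb], 0)
  add_metric(sprintf("absdv_%s_%s", task, fb), x)
}

message("leave-one-out prediction (18 value blocks per participant) ...")
add_metric("loo_value_pct", vapply(cohort, function(d)
  leave_one_out_accuracy(d, "value")$accuracy_pct, 0))
message("transfer to the control task ...")
add_metric("loo_control_pct", vapply(cohort, function(d)
  leave_one_out_accuracy(d, "control")$accuracy_pct, 0))

out <- do.call(rbind, metrics)
utils::write.table(out, "results/evaluation_group.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

message("group summary (mean +/- s.e.m., n = ", length(cohort), "):")
for (i in seq_len(nrow(out))) {
  message(sprintf("  %-22s %7.2f +/- %.2f", out$metric[i], out$mean[i],
                  out$sem[i]))
}
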