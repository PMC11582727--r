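#!/usr/bin/env Rscript

# Stage 4 — fMRI regressors.
#
# Builds, for each participant, the BIDS-style events file (stimulus-identity
# events, per-option subjective-value modulators lpSV/hpSV/gSV/rSV/aSV/vSV,
# control-task 0/1 compliance modulators, response and feedback events) and
# the 35-regressor first-level design matrix: HRF-convolved, with the
# modulator pair of each condition serially orthogonalized. Outputs go to
# results/regressors/ (events for everyone; the full design matrix for the
# first participant, as one ~4900-scan x 35 text matrix is large).

suppressPackageStartupMessages(library(foragefit))

in_dir <- "results/cohort"
out_dir <- "results/regressors"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
files <- sort(list.files(in_dir, pattern = "_trials\\.tsv$",
                         full.names = TRUE))
if (length(files) == 0L) stop("run analysis/01_simulate.R first")

for (i in seq_along(files)) {
  d <- read_trials(files[i])
  fit <- fit_lnp(d, task = "value")
  for (ses in sort(unique(d$session))) {
    ev <- build_event_table(d, fit$values, session = ses)
    export_events(ev, file.path(out_dir,
                                sprintf("participant%02d_ses%d_events.tsv",
                                        i, ses)))
  }
  if (i == 1L) {
    X <- suppressWarnings(build_design_matrix(d, fit$values, tr = 1.5))
    export_matrix(X, file.path(out_dir, "participant01_design.tsv"))
    ortho <- max(vapply(modulator_groups(X), function(g)
      abs(sum(X[, g[1]] * X[, g[2]])), 0))
    message(sprintf("design matrix: %d scans x %d regressors; max |<m1,m2>| after orthogonalization = %.2e",
                    nrow(X), ncol(X), ortho))
  }
}
message("wrote events for ", length(files), " participants to ", out_dir)
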