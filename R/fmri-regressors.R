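#' Canonical double-gamma hemodynamic response function
#'
#' The community-standard canonical HRF: a gamma density peaking near 5-6 s
#' minus a later gamma density (undershoot near 15-16 s) scaled by
#' 1/`undershoot_ratio`, evaluated at `t` seconds and zero for `t < 0` or
#' `t > length_s`.
#'
#' @param t numeric vector of times in seconds.
#' @param peak shape of the response gamma (delay of response, default 6).
#' @param undershoot shape of the undershoot gamma (default 16).
#' @param undershoot_ratio response/undershoot amplitude ratio (default 6).
#' @param length_s support of the kernel in seconds (default 32).
#' @return numeric vector of HRF values.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, undershoot_ratio = 6,
                          length_s = 32) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / undershoot_ratio
  h[t < 0 | t > length_s] <- 0
  h
}

control_compliance <- function(choice, feedback) {
  # did trial t follow the instruction from trial t-1?
  # yellow at t-1 = switch, blue = keep; the block's first trial counts 1.
  n <- length(choice)
  comp <- rep(1L, n)
  if (n < 2L) return(comp)
  for (i in 2:n) {
    should_switch <- feedback[i - 1L] == "yellow"
    switched <- choice[i] != choice[i - 1L]
    comp[i] <- as.integer(switched == should_switch)
  }
  comp
}

#' Build the event table for the univariate GLM
#'
#' One row per modelled event: unmodulated trial-identity events per task x
#' modality condition at stimulus onset; two parametric stick events per
#' trial at the same onset carrying the per-option subjective values in the
#' value task (named lpSV/hpSV, gSV/rSV, aSV/vSV by condition) and 0/1
#' instruction-compliance weights in the control task; unmodulated response
#' and feedback events collapsed across tasks; and an instruction event at
#' each block start. Missed trials are dropped.
#'
#' @param dataset a `behavioral_dataset`.
#' @param value_series a [compute_subjective_values()] (or [fit_lnp()]
#'   `$values`) result aligned to the value-task trials.
#' @param session restrict to one session (onsets are per-session clocks);
#'   default 1.
#' @return an `event_table` data frame with columns `onset`, `duration`,
#'   `event_kind`, `task`, `condition`, `option`, `modulator`, `value`,
#'   sorted by onset.
#' @export
build_event_table <- function(dataset, value_series, session = 1L) {
  df <- as.data.frame(dataset)
  df <- df[df$session == session, , drop = FALSE]
  if (nrow(df) == 0L) {
    return(empty_event_table())
  }
  if (any(is.na(df$onset_stim))) stop("missing onset times")
  missed <- !df$choice %in% c("S1", "S2")
  if (any(missed)) {
    message(sprintf("excluding %d missed trials from the event table",
                    sum(missed)))
    df <- df[!missed, , drop = FALSE]
  }
  vals <- merge(df[, c("block", "trial", "task")],
                as.data.frame(value_series)[, c("block", "trial", "v1", "v2")],
                by = c("block", "trial"), all.x = TRUE)
  vals <- vals[order(vals$block, vals$trial), , drop = FALSE]
  df <- df[order(df$block, df$trial), , drop = FALSE]

  sv_names <- list(AudAud = c("lpSV", "hpSV"), VisVis = c("gSV", "rSV"),
                   AudVis = c("aSV", "vSV"))
  rows <- list()
  add <- function(onset, duration, kind, task, condition, option, modulator,
                  value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      onset = onset, duration = duration, event_kind = kind, task = task,
      condition = condition, option = option, modulator = modulator,
      value = value, stringsAsFactors = FALSE)
  }

  for (idx in split(seq_len(nrow(df)), df$block)) {
    b <- df[idx, , drop = FALSE]
    task <- b$task[1]; cond <- b$condition[1]
    add(b$onset_fix[1], 0, "instruction", task, cond, NA, "none", 1)
    add(b$onset_stim, 0, "stimulus", task, cond, NA, "none", 1)
    if (task == "value") {
      v <- vals[idx, , drop = FALSE]
      nm <- sv_names[[cond]]
      add(b$onset_stim, 0, "stimulus", task, cond, "S1", nm[1], v$v1)
      add(b$onset_stim, 0, "stimulus", task, cond, "S2", nm[2], v$v2)
    } else {
      comp <- control_compliance(b$choice, b$feedback)
      add(b$onset_stim, 0, "stimulus", task, cond, "S1", "compliance", comp)
      add(b$onset_stim, 0, "stimulus", task, cond, "S2", "compliance", comp)
    }
    add(b$onset_resp, 0, "response", task, cond, NA, "none", 1)
    add(b$onset_fbk, 0, "feedback", task, cond, NA, "none", 1)
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$onset, ev$event_kind, ev$modulator), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_table", "data.frame")
  ev
}

empty_event_table <- function() {
  ev <- data.frame(onset = numeric(0), duration = numeric(0),
                   event_kind = character(0), task = character(0),
                   condition = character(0), option = character(0),
                   modulator = character(0), value = numeric(0),
                   stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}

# the regressor label of an event-table row group
regressor_label <- function(task, condition, event_kind, modulator, option) {
  short <- c(value = "val", control = "ctl")[task]
  if (event_kind %in% c("response", "feedback", "instruction")) {
    return(event_kind)
  }
  if (modulator == "none") return(paste0(short, "_", condition))
  if (modulator == "compliance") {
    return(paste0(short, "_", condition, "_cmp", ifelse(option == "S1", 1, 2)))
  }
  modulator
}

#' Convolve an event table with the canonical HRF
#'
#' Each distinct regressor (task x condition identity, each parametric
#' modulator, response, feedback, instruction) is built as a stick series on
#' a fine time grid of `tr / microtime` seconds — parametric modulators are
#' mean-centered across their events first — convolved with the canonical
#' double-gamma HRF and sampled at the scan grid `0, tr, 2 tr, ...`.
#'
#' @param events an [build_event_table()] result.
#' @param tr repetition time in seconds (default 1.5).
#' @param n_scans number of volumes; defaults to covering the last event plus
#'   the HRF length.
#' @param microtime fine-grid bins per scan (default 16).
#' @return a `regressor_matrix`: numeric matrix (n_scans x regressors) with
#'   named columns, attributes `tr`, `microtime`, and `orthogonalized`
#'   (FALSE).
#' @export
convolve_hrf <- function(events, tr = 1.5, n_scans = NULL, microtime = 16L) {
  stopifnot(tr > 0)
  if (is.null(n_scans)) {
    last <- if (nrow(events)) max(events$onset) else 0
    n_scans <- ceiling((last + 32) / tr) + 1L
  }
  scan_end <- n_scans * tr
  if (nrow(events) && any(events$onset > scan_end)) {
    bad <- which(events$onset > scan_end)
    stop(sprintf("%d events fall after scan end (first at %.2f s > %.2f s)",
                 length(bad), min(events$onset[bad]), scan_end))
  }
  dt <- tr / microtime
  n_fine <- n_scans * microtime
  hrf <- canonical_hrf(seq(0, 32, by = dt))

  key <- if (nrow(events)) {
    mapply(regressor_label, events$task, events$condition, events$event_kind,
           events$modulator, events$option, USE.NAMES = FALSE)
  } else character(0)
  labels <- unique(key)
  X <- matrix(0, n_scans, length(labels))
  colnames(X) <- labels
  scan_idx <- pmin(n_fine, (seq_len(n_scans) - 1L) * microtime + 1L)
  for (j in seq_along(labels)) {
    sel <- key == labels[j]
    amp <- events$value[sel]
    parametric <- !all(events$modulator[sel] == "none")
    if (parametric) amp <- amp - mean(amp)
    fine <- numeric(n_fine)
    bins <- pmin(n_fine, floor(events$onset[sel] / dt) + 1L)
    for (i in seq_along(bins)) fine[bins[i]] <- fine[bins[i]] + amp[i]
    conv <- stats::convolve(fine, rev(hrf), type = "open")[seq_len(n_fine)]
    X[, j] <- conv[scan_idx]
  }
  structure(X, tr = tr, microtime = microtime, orthogonalized = FALSE,
            class = c("regressor_matrix", class(X)))
}

#' Serially orthogonalize regressor groups
#'
#' Within each group, each column is residualized against the (already
#' residualized) columns before it — sequential projection, i.e. modified
#' Gram-Schmidt without normalization — so shared variance is credited to the
#' earlier regressor and earlier columns are unchanged. A later column that
#' is linearly dependent on its predecessors is set to zero with a warning.
#'
#' @param matrix a `regressor_matrix` (or plain numeric matrix with column
#'   names).
#' @param groups list of character vectors of column names, each in the
#'   declared (chronological) order; columns not mentioned are untouched.
#' @return the matrix with the grouped columns orthogonalized; attribute
#'   `orthogonalized` set to TRUE.
#' @export
serial_orthogonalize <- function(matrix, groups) {
  X <- matrix
  for (g in groups) {
    g <- g[g %in% colnames(X)]
    if (length(g) < 2L) next
    for (j in 2:length(g)) {
      earlier <- X[, g[seq_len(j - 1L)], drop = FALSE]
      keep <- colSums(earlier^2) > 0
      v <- X[, g[j]]
      if (any(keep)) {
        E <- earlier[, keep, drop = FALSE]
        beta <- tryCatch(qr.coef(qr(E), v), error = function(e) NULL)
        if (is.null(beta)) {
          warning(sprintf("rank-deficient group at column %s; set to zero",
                          g[j]))
          v <- v * 0
        } else {
          beta[is.na(beta)] <- 0
          v <- v - drop(E %*% beta)
        }
        if (sqrt(sum(v^2)) < 1e-12 * max(1, sqrt(sum(X[, g[j]]^2)))) {
          warning(sprintf("column %s is collinear with earlier group members",
                          g[j]))
          v <- v * 0
        }
      }
      X[, g[j]] <- v
    }
  }
  attr(X, "orthogonalized") <- TRUE
  X
}

#' Default orthogonalization groups: the modulator pair of each condition
#'
#' @param matrix a `regressor_matrix`.
#' @return list of column-name pairs present in the matrix.
#' @export
modulator_groups <- function(matrix) {
  pairs <- list(c("lpSV", "hpSV"), c("gSV", "rSV"), c("aSV", "vSV"),
                c("ctl_AudAud_cmp1", "ctl_AudAud_cmp2"),
                c("ctl_VisVis_cmp1", "ctl_VisVis_cmp2"),
                c("ctl_AudVis_cmp1", "ctl_AudVis_cmp2"))
  Filter(function(g) all(g %in% colnames(matrix)), pairs)
}

#' Build the full 35-regressor first-level design matrix
#'
#' Reproduces the published regressor scheme for one session: for each task
#' (value, control) and modality condition one unmodulated identity regressor
#' plus two parametric regressors (subjective values in the value task, 0/1
#' compliance in the control task) = 18 columns; unmodulated response and
#' feedback regressors collapsed across tasks (2); and 15 nuisance columns —
#' block-start instruction (1), six motion placeholders (identically zero
#' here, 6), run indicators for all but the first run (a run = 3 consecutive
#' blocks; 7 across the two-session experiment), and a constant (1) — for 35
#' columns in total. Task regressors are HRF-convolved and the modulator pair
#' of each condition serially orthogonalized.
#'
#' @param dataset a `behavioral_dataset` (both sessions; sessions are
#'   concatenated in time as in a concatenated first-level GLM).
#' @param value_series value-task subjective values (e.g. `fit_lnp()$values`).
#' @param tr repetition time in seconds.
#' @param orthogonalize apply [serial_orthogonalize()] to the modulator pairs
#'   (default TRUE).
#' @return a `regressor_matrix` with 35 named columns and attribute
#'   `n_scans_per_session`.
#' @export
build_design_matrix <- function(dataset, value_series, tr = 1.5,
                                orthogonalize = TRUE) {
  df <- as.data.frame(dataset)
  sessions <- sort(unique(df$session))
  mats <- list()
  run_ids <- list()
  for (s in sessions) {
    ev <- build_event_table(dataset, value_series, session = s)
    m <- convolve_hrf(ev, tr = tr)
    mats[[as.character(s)]] <- m
    dfs <- df[df$session == s, , drop = FALSE]
    blocks <- sort(unique(dfs$block))
    run_of_block <- stats::setNames(
      (match(dfs$block, blocks) - 1L) %/% 3L + 1L, NULL)
    # scan-wise run id from block onset windows
    n_scans <- nrow(m)
    scan_t <- (seq_len(n_scans) - 1L) * tr
    run_scan <- rep(NA_integer_, n_scans)
    for (b in seq_along(blocks)) {
      bi <- dfs$block == blocks[b]
      t0 <- min(dfs$onset_fix[bi])
      run_scan[scan_t >= t0] <- (b - 1L) %/% 3L + 1L
    }
    run_scan[is.na(run_scan)] <- 1L
    run_ids[[as.character(s)]] <- run_scan + (which(sessions == s) - 1L) * 4L
  }
  all_labels <- unique(unlist(lapply(mats, colnames)))
  stacked <- do.call(rbind, lapply(mats, function(m) {
    out <- matrix(0, nrow(m), length(all_labels),
                  dimnames = list(NULL, all_labels))
    out[, colnames(m)] <- m
    out
  }))
  runs <- unlist(run_ids, use.names = FALSE)
  n_runs <- max(runs)
  run_cols <- sapply(seq(2, n_runs), function(r) as.numeric(runs == r))
  colnames(run_cols) <- paste0("run", seq(2, n_runs))
  motion <- matrix(0, nrow(stacked), 6,
                   dimnames = list(NULL, paste0("motion", 1:6)))
  X <- cbind(stacked, motion, run_cols, constant = 1)
  X <- structure(X, tr = tr, microtime = attr(mats[[1]], "microtime"),
                 orthogonalized = FALSE,
                 n_scans_per_session = vapply(mats, nrow, 0L),
                 class = c("regressor_matrix", "matrix", "array"))
  if (orthogonalize) X <- serial_orthogonalize(X, modulator_groups(X))
  X
}

#' Export / read event tables and regressor matrices
#'
#' Events are written as BIDS-style tab-separated events files with columns
#' `onset`, `duration`, `trial_type` (the regressor label) plus the modulator
#' columns; matrices as tab-separated text with a header. Both round-trip
#' through the matching readers.
#'
#' @param events an `event_table`; `matrix` a `regressor_matrix`.
#' @param path output path.
#' @return the path, invisibly; readers return the restored object.
#' @export
export_events <- function(events, path) {
  out <- as.data.frame(events)
  out$trial_type <- if (nrow(out)) {
    mapply(regressor_label, out$task, out$condition, out$event_kind,
           out$modulator, out$option, USE.NAMES = FALSE)
  } else character(0)
  out <- out[, c("onset", "duration", "trial_type", "event_kind", "task",
                 "condition", "option", "modulator", "value")]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) format(x, digits = 15,
                                                  trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(path)
}

#' @rdname export_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                          stringsAsFactors = FALSE,
                          colClasses = c(onset = "numeric",
                                         duration = "numeric",
                                         value = "numeric"))
  df$trial_type <- NULL
  for (col in c("event_kind", "task", "condition", "option", "modulator")) {
    df[[col]] <- as.character(df[[col]])
  }
  class(df) <- c("event_table", "data.frame")
  df
}

#' @rdname export_events
#' @export
export_matrix <- function(matrix, path) {
  df <- as.data.frame(unclass(matrix))
  df[] <- lapply(df, function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(tr = attr(matrix, "tr"),
               orthogonalized = isTRUE(attr(matrix, "orthogonalized")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname export_events
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  X <- as.matrix(df)
  meta_path <- paste0(path, ".meta.json")
  tr <- NA_real_; ortho <- FALSE
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    tr <- meta$tr; ortho <- isTRUE(meta$orthogonalized)
  }
  structure(X, tr = tr, orthogonalized = ortho,
            class = c("regressor_matrix", "matrix", "array"))
}
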