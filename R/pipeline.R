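#' Apply the synapse inclusion filters
#'
#' A bouton enters the analysis when it has at least `min_events`
#' detected release events and an overall release probability of at
#' least `min_pr` (both thresholds inclusive); the defaults are the
#' 10-event and Pr >= 0.05 criteria used for all spatial and temporal
#' analyses.
#'
#' @param summaries SynapseSummary table from [summarize_synapses()].
#' @param min_events minimum event count (default 10).
#' @param min_pr minimum overall release probability (default 0.05).
#' @return list: `kept` (filtered summaries with `passes_filters`
#'   column), `dropped` (rows with a `drop_reason` column).
#' @export
filter_synapses <- function(summaries, min_events = 10L, min_pr = 0.05) {
  stopifnot(min_events >= 1, min_pr >= 0, min_pr <= 1)
  ok_n <- summaries$n_events >= min_events
  ok_pr <- summaries$pr_overall >= min_pr
  keep <- ok_n & ok_pr
  reason <- ifelse(!ok_n, "min_events",
                   ifelse(!ok_pr, "min_pr", ""))
  kept <- summaries[keep, , drop = FALSE]
  kept[["passes_filters"]] <- rep(TRUE, nrow(kept))
  dropped <- summaries[!keep, , drop = FALSE]
  dropped[["drop_reason"]] <- reason[!keep]
  rownames(kept) <- rownames(dropped) <- NULL
  list(kept = kept, dropped = dropped)
}

#' Peak amplitude of a stimulus-train response
#'
#' Maximum baseline-subtracted deflection of a whole-synapse trace
#' during (and after) a stimulus train, the standard readout for
#' high-frequency train responses.
#'
#' @param trace list with `t_s` and `dff` (e.g. from
#'   [simulate_train_response()]), or a numeric vector.
#' @param baseline_window indices (or `t_s` range as length-2 numeric)
#'   treated as pre-train baseline; must precede the train.
#' @param train_start_s first AP time; baseline must end before it.
#' @return peak amplitude above baseline, same units as the trace.
#' @export
train_peak_amplitude <- function(trace, baseline_window = NULL,
                                 train_start_s = 0) {
  if (is.numeric(trace)) trace <- list(t_s = seq_along(trace) - 1,
                                       dff = trace)
  y <- trace$dff
  if (is.null(baseline_window)) {
    base <- 0
  } else {
    idx <- if (length(baseline_window) == 2 &&
               !is.integer(baseline_window))
      which(trace$t_s >= baseline_window[1] &
              trace$t_s <= baseline_window[2])
    else baseline_window
    if (any(trace$t_s[idx] >= train_start_s))
      stop("baseline window overlaps the train")
    base <- mean(y[idx])
  }
  max(y - base)
}

#' Two-group and multi-group statistical comparisons
#'
#' Thin wrappers over the standard tests: two-tailed Welch t test,
#' one-way ANOVA with Tukey-Kramer post-hoc, and the two-sample
#' Kolmogorov-Smirnov test. No multiple-testing correction is applied
#' by default; `p_adjust = "BH"` applies Benjamini-Hochberg across the
#' returned p-values.
#'
#' @param values_by_group named list of numeric vectors (>= 2 values
#'   per group; exactly 2 groups for `t` and `ks`).
#' @param test one of "t", "anova", "ks".
#' @param p_adjust "none" (default) or "BH".
#' @return data.frame: `test`, `comparison`, `statistic`, `p_value`,
#'   `n1`, `n2`.
#' @export
compare_groups <- function(values_by_group, test = c("t", "anova", "ks"),
                           p_adjust = c("none", "BH")) {
  test <- match.arg(test)
  p_adjust <- match.arg(p_adjust)
  ns <- vapply(values_by_group, length, 0L)
  if (any(ns < 2)) stop("each group needs at least 2 values")
  if (test %in% c("t", "ks") && length(values_by_group) != 2L)
    stop("exactly 2 groups required for t / K-S tests")
  labs <- names(values_by_group)
  if (is.null(labs)) labs <- paste0("g", seq_along(values_by_group))
  if (test == "t") {
    ht <- stats::t.test(values_by_group[[1]], values_by_group[[2]])
    out <- data.frame(test = "t", comparison = paste(labs, collapse = " vs "),
                      statistic = unname(ht$statistic),
                      p_value = ht$p.value, n1 = ns[1], n2 = ns[2])
  } else if (test == "ks") {
    ht <- suppressWarnings(stats::ks.test(values_by_group[[1]],
                                          values_by_group[[2]]))
    out <- data.frame(test = "ks", comparison = paste(labs, collapse = " vs "),
                      statistic = unname(ht$statistic),
                      p_value = ht$p.value, n1 = ns[1], n2 = ns[2])
  } else {
    df <- data.frame(value = unlist(values_by_group, use.names = FALSE),
                     group = factor(rep(labs, ns)))
    fit <- stats::aov(value ~ group, data = df)
    tk <- stats::TukeyHSD(fit)$group
    pairs <- rownames(tk)
    out <- data.frame(test = "anova_tukey", comparison = pairs,
                      statistic = tk[, "diff"], p_value = tk[, "p adj"],
                      n1 = ns[vapply(strsplit(pairs, "-"), `[`, "", 2)],
                      n2 = ns[vapply(strsplit(pairs, "-"), `[`, "", 1)])
  }
  if (p_adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

## ------------------------------------------------------------------ I/O

event_schema <- c("event_id", "synapse_id", "stim_index", "t_s", "x_nm",
                  "y_nm", "amplitude", "label_release", "label_sync")

#' Write / read an EventRecord table
#'
#' CSV with a fixed, documented column set; floats are serialized at
#' full precision (17 significant digits) so that a write-then-read
#' round trip reproduces the values exactly.
#'
#' @param events EventRecord data.frame.
#' @param path CSV path.
#' @return `read_event_csv` returns the validated data.frame.
#' @export
write_event_csv <- function(events, path) {
  miss <- setdiff(event_schema, names(events))
  if (length(miss)) stop("events table missing columns: ",
                         paste(miss, collapse = ", "))
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(format(events[, event_schema], digits = 17,
                          trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_csv
#' @export
read_event_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(event_schema, names(df))
  if (length(miss))
    stop("event CSV at '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
  num <- c("t_s", "x_nm", "y_nm", "amplitude")
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  for (cn in c("event_id", "synapse_id", "stim_index"))
    df[[cn]] <- as.integer(df[[cn]])
  df
}

#' Write a trace matrix as CSV with a frame-interval header
#'
#' @param traces trace matrix from [simulate_dataset()].
#' @param path CSV path.
#' @export
write_trace_csv <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_interval_s=%.17g n_pre=%d",
                     attr(traces, "frame_interval_s"),
                     attr(traces, "n_pre")), con)
  utils::write.table(format(as.data.frame(traces), digits = 17,
                            trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[0-9.eE+-]+", hdr))[[1]]
  vals <- stats::setNames(as.numeric(sub(".*=", "", kv)),
                          sub("=.*", "", kv))
  m <- as.matrix(utils::read.csv(path, skip = 1, header = FALSE))
  dimnames(m) <- NULL
  n_pre <- as.integer(vals[["n_pre"]])
  dt <- vals[["frame_interval_s"]]
  attr(m, "frame_interval_s") <- dt
  attr(m, "n_pre") <- n_pre
  attr(m, "event_index") <- n_pre + 1L
  attr(m, "t_s") <- seq(-n_pre * dt, by = dt, length.out = ncol(m))
  m
}

## ------------------------------------------------------------- pipeline

#' Run the full simulation-to-statistics pipeline
#'
#' For each requested condition: remap the generator configuration,
#' simulate, fit every event's kinetics, summarize synapses, apply the
#' inclusion filters, and compute population statistics (amplitude
#' decomposition, tau decomposition with ultrafast ratio, retrieval
#' category proportions) and per-synapse spatial statistics over the
#' filtered synapses. Fully deterministic given `config$seed`.
#'
#' @param config a [generator_config()] (the control arm).
#' @param conditions character vector of condition names (default
#'   "control").
#' @param min_events,min_pr inclusion filters (see [filter_synapses()]).
#' @param out_dir when non-`NULL`, tables are written there (CSV/JSON)
#'   together with a run-summary JSON echoing the configuration, seed,
#'   software version and per-stage counts.
#' @param site_diameter_nm release-site clustering diameter.
#' @return list of class `ph_pipeline_result`, one element per
#'   condition, each with `dataset`, `kinetics`, `summaries`, `kept`,
#'   `dropped`, `population`, `spatial`, plus a `run_summary` element.
#' @export
run_pipeline <- function(config, conditions = "control",
                         min_events = 10L, min_pr = 0.05,
                         out_dir = NULL, site_diameter_nm = 50) {
  t0 <- Sys.time()
  res <- list()
  for (cond in conditions) {
    cfg <- apply_condition_map(config, cond)
    cfg$seed <- derive_seed(config$seed, match(cond, list_conditions()))
    ds <- simulate_dataset(cfg)
    kin <- analyze_kinetics(ds$traces)
    summaries <- summarize_synapses(ds$events, cfg$n_stimuli,
                                    synapse_ids = seq_len(cfg$n_synapses))
    flt <- filter_synapses(summaries, min_events, min_pr)
    keep_ev <- ds$events$synapse_id %in% flt$kept$synapse_id
    ev <- ds$events[keep_ev, , drop = FALSE]
    kin_kept <- kin[keep_ev, , drop = FALSE]
    sync <- ev$label_sync == "synchronous"

    pop <- list(n_events = nrow(ev),
                n_synapses_kept = nrow(flt$kept))
    if (sum(sync) >= 50) {
      pop$amplitude <- amplitude_decomposition(ev$amplitude[sync])
      pop$mvr_uvr_ratio <- with(flt$kept,
        stats::median(mvr_uvr_ratio[is.finite(mvr_uvr_ratio)]))
    }
    ok_tau <- kin_kept$fit_ok
    if (sum(ok_tau) >= 50) {
      pop$tau_mixture <- fit_bi_gaussian_histogram(
        kin_kept$tau_s[ok_tau], bin_width = 0.05)
      pop$ultrafast_ratio <- tryCatch(ultrafast_ratio(pop$tau_mixture),
                                      error = function(e) NA_real_)
    }
    pop$retrieval_proportions <-
      prop.table(table(kin_kept$category))

    spatial <- lapply(split(ev[sync, c("x_nm", "y_nm")], ev$synapse_id[sync]),
                      function(p) if (nrow(p) >= 1)
                        spatial_summary(p, site_diameter_nm) else NULL)

    res[[cond]] <- list(condition = cond, config = cfg, dataset = ds,
                        kinetics = kin, summaries = summaries,
                        kept = flt$kept, dropped = flt$dropped,
                        population = pop, spatial = spatial)
  }
  run_summary <- list(
    package_version = as.character(utils::packageVersion("phevents")),
    seed = config$seed,
    config_hash = config_hash(config),
    conditions = conditions,
    counts = lapply(res, function(r)
      list(events_simulated = nrow(r$dataset$events),
           events_after_filter = r$population$n_events,
           synapses_simulated = r$config$n_synapses,
           synapses_kept = nrow(r$kept),
           synapses_dropped = nrow(r$dropped))),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  res$run_summary <- run_summary
  class(res) <- "ph_pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(unclass(config))),
               collapse = "\n")
  ## small stable polynomial hash; avoids an external digest dependency
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483629
  sprintf("%08x", h)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conds <- setdiff(names(res), "run_summary")
  for (cond in conds) {
    r <- res[[cond]]
    safe <- gsub("[^A-Za-z0-9._-]", "_", cond)
    write_event_csv(r$dataset$events,
                    file.path(out_dir, paste0("events_", safe, ".csv")))
    utils::write.csv(r$kinetics,
                     file.path(out_dir, paste0("kinetics_", safe, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$summaries,
                     file.path(out_dir, paste0("synapses_", safe, ".csv")),
                     row.names = FALSE)
    pop <- r$population
    pop$amplitude$mixture <- unclass(pop$amplitude$mixture)
    pop$tau_mixture <- unclass(pop$tau_mixture)
    pop$retrieval_proportions <- as.list(pop$retrieval_proportions)
    jsonlite::write_json(pop,
                         file.path(out_dir, paste0("population_", safe,
                                                   ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  jsonlite::write_json(res$run_summary,
                       file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.ph_pipeline_result <- function(x, ...) {
  conds <- setdiff(names(x), "run_summary")
  cat("ph_pipeline_result:", length(conds), "condition(s)\n")
  for (cond in conds) {
    r <- x[[cond]]
    cat(sprintf("  %-24s %5d events, %d/%d synapses kept\n", cond,
                r$population$n_events, nrow(r$kept),
                r$config$n_synapses))
  }
  invisible(x)
}
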