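# Pipeline orchestration and the command-line entry point.

#' Default demo run configuration
#'
#' Two synthetic cohorts (regular young-wildtype rhythm vs the
#' bradycardic, arrhythmic seizure-like rhythm), a synchronized
#' optical/electrical pair, and a small ddCt example.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in every output.
#' @param n_hearts Hearts per cohort.
#' @param duration_s Recording length per heart, seconds.
#' @return A named list understood by [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("flybeat_demo_"), seed = 7,
                        n_hearts = 5, duration_s = 30) {
  list(out_dir = out_dir, seed = as.integer(seed),
       cohorts = c("wt_young", "sei_like"),
       n_hearts = n_hearts, duration_s = duration_s,
       bin_width = 0.1, threshold = 0.15, tolerance_s = 0.15)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage:%s] %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Analyze one synthetic heart end to end
#'
#' Generates a schedule, renders the diameter trace, segments beats and
#' parses phases; returns the tables and summaries.
#'
#' @param spec A [synth_spec()].
#' @param speed_smooth Speed-trace smoothing window in samples (default 5,
#'   suited to noisy traces).
#' @return List: `ground_truth`, `trace`, `beats`, `summary`, `phases`.
#' @export
analyze_synthetic_heart <- function(spec, speed_smooth = 5) {
  gt <- .stage("synth", make_beat_schedule(spec))
  tr <- .stage("synth", render_diameter_trace(gt, spec))
  bt <- .stage("beats", segment_beats(tr))
  ph <- .stage("phases",
               parse_phases(movement_trace(tr, speed_smooth), bt))
  list(ground_truth = gt, trace = tr, beats = bt,
       summary = summarize_beats(bt), phases = ph)
}

#' Run the demo pipeline
#'
#' Executes the full synthetic pipeline per the configuration: cohort
#' generation, beat segmentation, phase parsing, one synchronized
#' optical/electrical pair with AP analysis and event matching, and a ddCt
#' example. Writes per-cohort CSVs and a deterministic `summary.json`
#' (identical config + seed always produces identical output).
#'
#' @param config A list as produced by [demo_config()].
#' @return The summary list, invisibly; outputs under `config$out_dir`.
#' @export
run_pipeline <- function(config = demo_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort_summaries <- list()
  for (ci in seq_along(config$cohorts)) {
    preset <- config$cohorts[ci]
    rows <- list()
    for (h in seq_len(config$n_hearts)) {
      spec <- synth_spec(preset, duration_s = config$duration_s,
                         seed = config$seed + 1000L * ci + h)
      res <- analyze_synthetic_heart(spec)
      s <- res$summary
      rows[[h]] <- data.frame(
        heart = h, n_beats = s$n_beats, mean_di = s$mean_di,
        mean_si = s$mean_si, median_hp = s$median_hp, ai = s$ai,
        dd = s$dd, sd = s$sd, fs = s$fs,
        mean_iso = mean(res$phases$iso, na.rm = TRUE),
        mean_velocity = mean(res$phases$shortening_velocity, na.rm = TRUE))
    }
    tab <- do.call(rbind, rows)
    data.table::fwrite(tab, file.path(config$out_dir,
                                      paste0("cohort_", preset, ".csv")))
    cohort_summaries[[preset]] <- lapply(
      tab[, -1], function(x) mean(x, na.rm = TRUE))
  }

  # one synchronized pair on the first cohort's preset
  spec <- synth_spec(config$cohorts[1], duration_s = config$duration_s,
                     seed = config$seed)
  gt <- .stage("synth", make_beat_schedule(spec))
  pair <- .stage("synth", render_sync_pair(gt, spec))
  aligned <- .stage("sync", align_pair(pair$voltage, pair$optical))
  bt <- .stage("beats", segment_beats(pair$optical))
  bt$onset <- bt$onset + aligned$offset
  bt$relaxation_end <- bt$relaxation_end + aligned$offset
  ev <- .stage("aps", detect_events(pair$voltage))
  mr <- .stage("sync", match_events(bt, ev,
                                    tolerance_s = config$tolerance_s))
  ap_sum <- record_summary(ev, duration_s = config$duration_s,
                           window_s = min(30, config$duration_s),
                           min_aps = 1)

  ct <- data.frame(
    sample = rep(c("c1", "c2", "c3", "e1", "e2", "e3"), each = 2),
    group = rep(c("control", "experimental"), each = 6),
    gene = rep(c("target", "actin"), 6),
    ct = c(25, 20, 25.2, 20.1, 24.8, 19.9, 26, 20, 26.2, 20.1, 25.8, 19.9))
  dd <- .stage("qpcr", delta_delta_ct(ct))

  summary <- list(
    package = "flybeat",
    version = as.character(utils::packageVersion("flybeat")),
    seed = config$seed,
    parameters = config[c("n_hearts", "duration_s", "bin_width",
                          "threshold", "tolerance_s")],
    cohorts = cohort_summaries,
    sync = list(n_beats = mr$n_beats, n_ap_events = mr$n_ap_events,
                matched_fraction = mr$matched_fraction,
                median_latency_s = mr$median_latency_s),
    electrical = ap_sum[c("resting_vm", "mean_amplitude",
                          "mean_peaks_per_burst", "mean_event_duration")],
    qpcr = list(mean_ddct = dd$per_gene$mean_ddct_experimental,
                mean_fold = dd$per_gene$mean_fold_experimental))
  jsonlite::write_json(summary,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}

#' Command-line entry point
#'
#' Subcommands: `synth` (write synthetic recordings), `beats`, `phases`,
#' `aps` (analyze a trace CSV), `sync` (align a voltage + trace pair),
#' `qpcr` (Ct table math), `demo` (full deterministic demo run). Invoked
#' by the `inst/cli/flybeat.R` script:
#' `Rscript flybeat.R <subcommand> [options]`.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code: 0 ok, 1 usage error, 2 data error.
#' @export
flybeat_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: flybeat <synth|beats|phases|aps|sync|qpcr|demo> [options]",
    "  synth  --preset wt_young --seed 1 --duration 30 --out DIR",
    "  beats  TRACE.csv [--bin 0.1] [--summary OUT.json]",
    "  phases TRACE.csv [--threshold 0.15]",
    "  aps    VOLT.csv [--prominence 10] [--group-ms 300]",
    "  sync   VOLT.csv TRACE.csv [--tolerance 0.15]",
    "  qpcr   CT.csv --mode <dct|ddct> [--reference NAME]",
    "  demo   [--seed 7] [--out DIR]",
    sep = "\n")
  if (!length(args)) { message(usage); return(1L) }
  cmd <- args[1]
  rest <- args[-1]
  opt <- function(name, default = NULL) {
    i <- which(rest == paste0("--", name))
    if (length(i) == 1 && i < length(rest)) rest[i + 1] else default
  }
  pos <- rest[!startsWith(rest, "--") &
                !seq_along(rest) %in% (which(startsWith(rest, "--")) + 1)]
  handle <- function(expr) {
    tryCatch({ expr; 0L }, error = function(e) {
      message("error: ", conditionMessage(e)); 2L
    })
  }
  switch(cmd,
    synth = handle({
      out <- opt("out", ".")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      spec <- synth_spec(opt("preset", "wt_young"),
                         duration_s = as.numeric(opt("duration", 30)),
                         seed = as.integer(opt("seed", 1)))
      gt <- make_beat_schedule(spec)
      write_trace_csv(render_diameter_trace(gt, spec),
                      file.path(out, "diameter.csv"))
      write_trace_csv(render_voltage_trace(gt, spec),
                      file.path(out, "voltage.csv"))
      write_ground_truth_json(gt, file.path(out, "ground_truth.json"))
      message("wrote diameter.csv, voltage.csv, ground_truth.json to ", out)
    }),
    beats = handle({
      if (!length(pos)) stop("trace CSV required")
      tr <- read_diameter_csv(pos[1])
      bt <- segment_beats(tr)
      s <- summarize_beats(bt)
      print(s)
      out <- opt("summary")
      if (!is.null(out)) {
        jsonlite::write_json(unclass(s), out, auto_unbox = TRUE,
                             digits = 10)
      }
    }),
    phases = handle({
      if (!length(pos)) stop("trace CSV required")
      tr <- read_diameter_csv(pos[1])
      bt <- segment_beats(tr)
      ph <- parse_phases(movement_trace(tr, 5), bt,
                         threshold = as.numeric(opt("threshold", 0.15)))
      utils::write.csv(ph, stdout(), row.names = FALSE)
    }),
    aps = handle({
      if (!length(pos)) stop("voltage CSV required")
      vt <- read_voltage_csv(pos[1])
      ev <- detect_events(vt,
                          prominence_mv = as.numeric(opt("prominence", 10)),
                          group_ms = as.numeric(opt("group-ms", 300)))
      utils::write.csv(ev, stdout(), row.names = FALSE)
    }),
    sync = handle({
      if (length(pos) < 2) stop("voltage CSV and trace CSV required")
      vt <- read_voltage_csv(pos[1])
      tr <- read_diameter_csv(pos[2])
      pair <- align_pair(vt, tr)
      bt <- segment_beats(pair$optical)
      ev <- detect_events(vt)
      mr <- match_events(bt, ev,
                         tolerance_s = as.numeric(opt("tolerance", 0.15)))
      print(mr)
    }),
    qpcr = handle({
      if (!length(pos)) stop("Ct CSV required")
      tab <- as.data.frame(data.table::fread(pos[1]))
      mode <- opt("mode", "ddct")
      if (mode == "dct") {
        utils::write.csv(delta_ct(tab, opt("reference", "MCM2")),
                         stdout(), row.names = FALSE)
      } else {
        r <- delta_delta_ct(tab, opt("reference", "actin"))
        utils::write.csv(r$per_gene, stdout(), row.names = FALSE)
      }
    }),
    demo = handle({
      cfg <- demo_config(out_dir = opt("out", "flybeat_demo"),
                         seed = as.integer(opt("seed", 7)))
      run_pipeline(cfg)
      message("demo outputs written to ", cfg$out_dir)
    }),
    { message("unknown subcommand: ", cmd, "\n", usage); 1L }
  )
}
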