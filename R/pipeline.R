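# End-to-end orchestration: simulate -> link -> classify -> outcomes ->
# model -> network -> optimize -> report, each stage reading/writing the
# documented CSV artifacts.

#' Pipeline stage names, in execution order
#' @return Character vector.
#' @export
pipeline_stages <- function() {
  c("simulate", "link", "classify", "outcomes", "model", "network",
    "optimize", "report")
}

#' Pipeline configuration
#'
#' @param simulation A [sim_config()] (or `NULL` when `input_dir` supplies
#'   user CSVs with the documented dictionary).
#' @param stages Subset of [pipeline_stages()] to run; later stages that
#'   depend on a toggled-off stage are skipped with it.
#' @param seed Integer; when non-`NULL`, overrides the simulation seed and
#'   seeds every stochastic stage.
#' @param outdir Output directory.
#' @param input_dir Optional directory of pre-existing `ed.csv`,
#'   `inpatient.csv`, `hospitals.csv` (skips the simulate stage).
#' @param percent_digits Report rounding for percentages, default 1.
#' @param network_year Year for the transfer graph; default latest year with
#'   events.
#' @param model_spec A [model_spec()] for the GLMM stage.
#' @return List of class `retriage_pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            stages = pipeline_stages(),
                            seed = NULL, outdir = NULL, input_dir = NULL,
                            percent_digits = 1, network_year = NULL,
                            model_spec = retriage::model_spec()) {
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(simulation = simulation, stages = stages, seed = seed,
                 outdir = outdir, input_dir = input_dir,
                 percent_digits = percent_digits, network_year = network_year,
                 model_spec = model_spec),
            class = "retriage_pipeline_config")
}

stage_error <- function(stage, e, ledger = NULL) {
  msg <- paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  if (!is.null(ledger)) {
    msg <- paste0(msg, "\nledger state:\n",
                  paste(utils::capture.output(print(as.data.frame(ledger))),
                        collapse = "\n"))
  }
  stop(msg, call. = FALSE)
}

#' Run the full re-triage analysis pipeline
#'
#' Executes the configured stages, writes every artifact under `outdir`
#' (`cohort.csv`, `ledger.csv`, `rates_{state,rtcc,lemsa,center}.csv`,
#' `table1.csv`, `table2.csv`, `model_coefficients.csv`, `network.graphml`,
#' `network_nodes.geojson`, `alternatives.csv`, `report.md`, plus the
#' synthetic input CSVs), and runs the cross-module consistency checks
#' (ledger conservation; transfer-graph suboptimal weight share equals the
#' rate table's suboptimal rate for the network year). A stage failure
#' aborts with the stage name and the ledger state.
#'
#' @param config A [pipeline_config()].
#' @param outdir,seed Optional overrides of the config fields.
#' @return List: `manifest` (tibble `stage`, `artifact`, `path`, `rows`) and
#'   the in-memory objects (`directory`, `events`, `ledger`, `rates`,
#'   `model`, `graph`, `optimization`).
#' @export
run_retriage_pipeline <- function(config = pipeline_config(), outdir = NULL,
                                  seed = NULL) {
  stopifnot(inherits(config, "retriage_pipeline_config"))
  outdir <- outdir %||% config$outdir %||% stop("outdir is required", call. = FALSE)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  seed <- seed %||% config$seed
  stages <- config$stages
  manifest <- list()
  note <- function(stage, artifact, path, rows) {
    manifest[[length(manifest) + 1L]] <<-
      tibble::tibble(stage = stage, artifact = artifact, path = path,
                     rows = as.integer(rows))
  }
  result <- list()
  ledger <- NULL
  pct <- config$percent_digits

  ## ---- simulate ----
  if (!is.null(config$input_dir)) {
    directory <- read_hospital_directory_csv(file.path(config$input_dir, "hospitals.csv"))
    ed <- read_encounters_csv(file.path(config$input_dir, "ed.csv"))
    ip <- read_encounters_csv(file.path(config$input_dir, "inpatient.csv"))
    truth <- NULL
  } else {
    if (!"simulate" %in% stages) stop("no input_dir and simulate stage toggled off", call. = FALSE)
    tryCatch({
      cfg <- config$simulation
      if (!is.null(seed)) cfg$seed <- as.integer(seed)
      directory <- generate_hospital_directory(cfg)
      sim <- generate_encounters(cfg, directory)
      ed <- sim$ed; ip <- sim$inpatient; truth <- sim$truth
      paths <- write_synthetic_dataset(sim, directory, outdir)
      note("simulate", "ed.csv", paths[["ed"]], nrow(ed))
      note("simulate", "inpatient.csv", paths[["inpatient"]], nrow(ip))
      note("simulate", "hospitals.csv", paths[["hospitals"]], nrow(directory))
      note("simulate", "ground_truth.csv", paths[["ground_truth"]], nrow(truth))
    }, error = function(e) stage_error("simulate", e))
  }
  result$directory <- directory

  ## ---- link ----
  if (!"link" %in% stages) {
    return(list(manifest = dplyr::bind_rows(manifest), directory = directory))
  }
  linked <- tryCatch(link_cohort(ed, ip, directory),
                     error = function(e) stage_error("link", e))
  ledger <- linked$ledger
  if (sum(ledger$n_removed) + nrow(linked$cohort) + nrow(linked$undertriaged)
      != ledger$n_remaining[1]) {
    stage_error("link", simpleError("ledger conservation violated"), ledger)
  }
  p <- file.path(outdir, "cohort.csv")
  readr::write_csv(linked$cohort, p, na = ""); note("link", "cohort.csv", p, nrow(linked$cohort))
  p <- file.path(outdir, "ledger.csv")
  readr::write_csv(ledger, p); note("link", "ledger.csv", p, nrow(ledger))
  result$ledger <- ledger
  result$undertriaged <- linked$undertriaged
  result$inpatient_dedup <- deduplicate_records(ip)$records

  ## ---- classify ----
  if (!"classify" %in% stages) {
    return(c(list(manifest = dplyr::bind_rows(manifest)), result))
  }
  events <- tryCatch({
    label_optimality(linked$cohort, directory) |> encode_covariates()
  }, error = function(e) stage_error("classify", e, ledger))
  result$events <- events
  rates <- list()
  for (lv in c("STATE", "RTCC", "LEMSA", "CENTER")) {
    rt <- aggregate_rates(events, level = lv, directory = directory)
    rates[[lv]] <- rt
    p <- file.path(outdir, sprintf("rates_%s.csv", tolower(lv)))
    readr::write_csv(rt, p, na = ""); note("classify", basename(p), p, nrow(rt))
  }
  result$rates <- rates
  t1 <- build_table1(events, digits = pct)
  p <- file.path(outdir, "table1.csv")
  readr::write_csv(t1, p, na = ""); note("classify", "table1.csv", p, nrow(t1))

  ## ---- outcomes ----
  course <- NULL
  if ("outcomes" %in% stages) {
    course <- tryCatch({
      ev2 <- flag_readmissions(events, result$inpatient_dedup, directory)
      compare_hospital_course(ev2)
    }, error = function(e) stage_error("outcomes", e, ledger))
    t2 <- surgery_rate_table(course$events, digits = pct)
    p <- file.path(outdir, "table2.csv")
    readr::write_csv(t2, p, na = ""); note("outcomes", "table2.csv", p, nrow(t2))
    result$hospital_course <- course
  }

  ## ---- model ----
  if ("model" %in% stages) {
    fit <- tryCatch(fit_suboptimality_model(events, spec = config$model_spec),
                    error = function(e) stage_error("model", e, ledger))
    ct <- coefficient_table(fit)
    p <- file.path(outdir, "model_coefficients.csv")
    readr::write_csv(ct, p, na = ""); note("model", "model_coefficients.csv", p, nrow(ct))
    result$model <- fit
  }

  ## ---- network ----
  net_year <- config$network_year %||% max(events$year)
  if ("network" %in% stages) {
    graph <- tryCatch(build_transfer_graph(events, directory, year = net_year),
                      error = function(e) stage_error("network", e, ledger))
    # consistency: suboptimal edge-weight share must equal the rate table
    if (igraph::gsize(graph) > 0) {
      w_sub <- sum(igraph::E(graph)$weight[igraph::E(graph)$category != "OPTIMAL"])
      rt <- rates$STATE
      r_sub <- rt$rate[rt$year == as.character(net_year)]
      if (length(r_sub) == 1 && !is.na(r_sub) && abs(w_sub - r_sub) > 1e-9) {
        stage_error("network", simpleError(sprintf(
          "graph suboptimal weight share %.6f != rate table %.6f", w_sub, r_sub)),
          ledger)
      }
    }
    p <- file.path(outdir, "network.graphml")
    write_transfer_graphml(graph, p)
    note("network", "network.graphml", p, igraph::gsize(graph))
    p <- file.path(outdir, "network_nodes.geojson")
    write_transfer_geojson(graph, p)
    note("network", "network_nodes.geojson", p, igraph::vcount(graph))
    if (igraph::vcount(graph) > 0) {
      ly <- layout_graph(graph, "FORCE_DIRECTED", seed = (seed %||% 1L) + 7L)
      p <- file.path(outdir, "network_layout.csv")
      readr::write_csv(tibble::tibble(facility_id = rownames(ly),
                                      x = ly[, 1], y = ly[, 2]), p)
      note("network", "network_layout.csv", p, nrow(ly))
    }
    result$graph <- graph
  }

  ## ---- optimize ----
  if ("optimize" %in% stages) {
    opt <- tryCatch(optimize_all(events, directory),
                    error = function(e) stage_error("optimize", e, ledger))
    p <- file.path(outdir, "alternatives.csv")
    readr::write_csv(opt$alternatives, p, na = "")
    note("optimize", "alternatives.csv", p, nrow(opt$alternatives))
    result$optimization <- opt
  }

  ## ---- report ----
  if ("report" %in% stages) {
    p <- file.path(outdir, "report.md")
    writeLines(render_report(result, net_year, pct), p)
    note("report", "report.md", p, NA_integer_)
  }

  c(list(manifest = dplyr::bind_rows(manifest)), result)
}

render_report <- function(result, net_year, pct) {
  ev <- result$events
  st <- result$rates$STATE
  pooled <- st[st$year == "ALL", ]
  tr <- annual_trend(ev)$state
  lines <- c(
    "# Re-triage analysis report", "",
    sprintf("- Re-triages analysed: %d", pooled$n_retriage),
    sprintf("- Suboptimal: %d (%.*f%%)", pooled$n_suboptimal, pct,
            as_report_percent(pooled$rate, pct)),
    sprintf("- State rate by year: %s",
            paste(sprintf("%s %.*f%%", tr$year, pct,
                          as_report_percent(tr$rate, pct)), collapse = ", ")))
  rtcc <- result$rates$RTCC
  rtcc <- rtcc[rtcc$year == "ALL" & rtcc$n_retriage > 0, ]
  lines <- c(lines, "", "## RTCC", "",
             sprintf("- %s: %d/%d suboptimal (%.*f%%), share of state %.*f%%",
                     rtcc$unit_id, rtcc$n_suboptimal, rtcc$n_retriage, pct,
                     as_report_percent(rtcc$rate, pct), pct,
                     as_report_percent(rtcc$share_of_state_suboptimal, pct)))
  if (!is.null(result$optimization)) {
    s <- result$optimization$summary
    lines <- c(lines, "", "## Destination optimization", "",
               sprintf("- Alternative level I/II destination found for %.*f%% of suboptimal re-triages",
                       pct, as_report_percent(s$resolvable_fraction, pct)),
               sprintf("- State suboptimal rate %.*f%% before vs %.*f%% after hypothetical re-routing",
                       pct, as_report_percent(s$rate_before, pct),
                       pct, as_report_percent(s$rate_after, pct)))
  }
  if (!is.null(result$model)) {
    lines <- c(lines, "", "## Model", "",
               sprintf("- GLMM fitted on %d events; random-intercept SDs: %s",
                       result$model$n,
                       paste(sprintf("%s %.3f", result$model$random_effects$group,
                                     result$model$random_effects$sd),
                             collapse = ", ")))
  }
  lines
}
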