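# End-to-end orchestration: simulate / calibrate / score / density /
# survival / report, driven by a config list or JSON file.

default_pipeline_config <- function() {
  list(
    maps_dir = "maps", clinical_csv = "clinical.csv",
    detections_csv = "detections.csv", scores_csv = "scores.csv",
    calibration_json = "calibration.json", density_csv = "density.csv",
    survival_json = "survival.json", report_txt = "report.txt",
    truth_csv = "truth.csv",
    stride_px = 112L, patch_size_px = 224L, microns_per_pixel = 0.5,
    tsr_cutoff = 0.5, calibration_source = "fit",
    horizon_years = 5,
    covariates = c("stage", "age", "sex", "location", "cea", "grade",
                   "tsr_group", "til_group", "immune_score"),
    n_patients = 100L, seed = 1L, log_level = "info"
  )
}

load_pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (cfg$tsr_cutoff <= 0 || cfg$tsr_cutoff >= 1) stop("tsr_cutoff must lie in (0, 1)")
  cfg
}

pipe_log <- function(cfg, level, fmt, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_cohort_maps <- function(maps_dir) {
  if (!dir.exists(maps_dir)) stop("maps directory not found: ", maps_dir)
  slides <- list.dirs(maps_dir, recursive = FALSE)
  if (!length(slides)) stop("no slide directories under ", maps_dir)
  maps <- lapply(slides, function(d) {
    pmap <- read_map(d)
    list(pmap = pmap, seg = segment_map(pmap))
  })
  names(maps) <- vapply(maps, function(m) m$pmap$meta$slide_id, character(1))
  maps
}

#' Run one pipeline stage
#'
#' Orchestrates the analysis end to end; every stage reads and writes the
#' plain-text artifacts of the module interfaces, all randomness is routed
#' through `config$seed`, and identical (inputs, config, seed) reruns produce
#' identical artifacts.
#'
#' * `simulate` - synthetic cohort: clinical/truth CSVs, per-slide map
#'   directories, detections CSV.
#' * `calibrate` - tertile calibration JSON from a reference scores CSV.
#' * `score` - per-patient score records CSV (+ the calibration used).
#' * `density` - per-patient stroma-CD3 density CSV.
#' * `survival` - prognostic-table JSON (per-variable HR/CI/p, C-index,
#'   0-5y iAUC, per-group KM 5-year rates and log-rank tests).
#' * `report` - human-readable summary of the artifacts above.
#'
#' @param command One of `"simulate"`, `"calibrate"`, `"score"`, `"density"`,
#'   `"survival"`, `"report"`.
#' @param config Named list or path to a JSON config; unspecified entries
#'   fall back to documented defaults (paths are relative to `out_dir`).
#' @param out_dir Artifact directory, created if missing.
#' @return Invisibly, a named list of artifact paths written by the stage.
#' @export
run_pipeline <- function(command, config = list(), out_dir = ".") {
  commands <- c("simulate", "calibrate", "score", "density", "survival", "report")
  if (!command %in% commands)
    stop("unknown command '", command, "'; expected one of: ",
         paste(commands, collapse = ", "))
  cfg <- load_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(x) file.path(out_dir, x)
  switch(command,
    simulate = {
      sc <- sim_config(n_patients = cfg$n_patients, seed = cfg$seed)
      pipe_log(cfg, "info", "simulating %d patients (seed %d)", sc$n_patients, sc$seed)
      sim <- simulate_cohort(sc)
      utils::write.csv(sim$clinical, p(cfg$clinical_csv), row.names = FALSE, quote = FALSE)
      utils::write.csv(sim$truth, p(cfg$truth_csv), row.names = FALSE, quote = FALSE)
      dir.create(p(cfg$maps_dir), showWarnings = FALSE)
      for (id in names(sim$maps))
        write_map(sim$maps[[id]]$pmap, file.path(p(cfg$maps_dir), id))
      det <- do.call(rbind, lapply(names(sim$detections), function(id) {
        d <- as.data.frame(sim$detections[[id]])
        if (nrow(d)) cbind(slide_id = id, d) else NULL
      }))
      utils::write.csv(det, p(cfg$detections_csv), row.names = FALSE, quote = FALSE)
      invisible(list(clinical = p(cfg$clinical_csv), truth = p(cfg$truth_csv),
                     maps = p(cfg$maps_dir), detections = p(cfg$detections_csv)))
    },
    calibrate = {
      scores <- utils::read.csv(p(cfg$scores_csv))
      col <- if ("deep_til" %in% names(scores)) "deep_til" else names(scores)[1]
      cal <- calibrate_tertiles(scores[[col]], cfg$calibration_cohort %||% "reference")
      write_calibration(cal, p(cfg$calibration_json))
      pipe_log(cfg, "info", "calibrated tertiles: t33 = %.6g, t66 = %.6g", cal$t33, cal$t66)
      invisible(list(calibration = p(cfg$calibration_json)))
    },
    score = {
      maps <- read_cohort_maps(p(cfg$maps_dir))
      calibration <- if (identical(cfg$calibration_source, "fit")) "fit"
        else read_calibration(p(cfg$calibration_json))
      rec <- score_cohort(maps, calibration, cohort_id = basename(out_dir),
                          cutoff = cfg$tsr_cutoff)
      write_scores(rec, p(cfg$scores_csv))
      write_calibration(attr(rec, "calibration"), p(cfg$calibration_json))
      pipe_log(cfg, "info", "scored %d patients", nrow(rec))
      invisible(list(scores = p(cfg$scores_csv), calibration = p(cfg$calibration_json)))
    },
    density = {
      maps <- read_cohort_maps(p(cfg$maps_dir))
      det <- utils::read.csv(p(cfg$detections_csv))
      res <- lapply(names(maps), function(id) {
        d <- det[det$slide_id == id, , drop = FALSE]
        cd <- cell_detections(d$x_px, d$y_px, d$area_px2 %||% rep(50, nrow(d)),
                              slide_id = id)
        stroma_cd3_density(cd, maps[[id]]$seg)
      })
      out <- data.frame(
        patient_id = names(maps),
        n_cells_in_stroma = vapply(res, `[[`, integer(1), "n_cells_in_stroma"),
        stroma_area_mm2 = vapply(res, `[[`, numeric(1), "stroma_area_mm2"),
        density_cells_per_mm2 = vapply(res, `[[`, numeric(1), "density_cells_per_mm2"))
      utils::write.csv(out, p(cfg$density_csv), row.names = FALSE, quote = FALSE)
      pipe_log(cfg, "info", "densities for %d patients", nrow(out))
      invisible(list(density = p(cfg$density_csv)))
    },
    survival = {
      clin <- utils::read.csv(p(cfg$clinical_csv))
      scores <- utils::read.csv(p(cfg$scores_csv))
      dat <- merge(clin, scores, by = "patient_id")
      dat$immune_score <- factor(dat$immune_score)
      covs <- intersect(cfg$covariates, names(dat))
      fit <- cox_fit(dat, covs,
                     reference_levels = c(stage = "I", cea = "normal",
                                          grade = "low", tsr_group = "high",
                                          til_group = "low", immune_score = "1"),
                     mode = "both")
      km_groups <- lapply(split(dat, dat$immune_score), function(d)
        km_curve(d$os_years, d$os_event))
      five_year <- vapply(km_groups, function(k)
        survival_at(k, cfg$horizon_years), numeric(1))
      lr <- logrank_test(dat$os_years, dat$os_event, dat$immune_score)
      out <- list(
        table = fit$table, c_index = fit$c_index, iauc = fit$iauc,
        five_year_by_score = as.list(five_year),
        logrank = lr, n = nrow(dat))
      jsonlite::write_json(out, p(cfg$survival_json), auto_unbox = TRUE,
                           digits = NA, dataframe = "rows")
      pipe_log(cfg, "info", "survival analysis on %d patients", nrow(dat))
      invisible(list(survival = p(cfg$survival_json)))
    },
    report = {
      lines <- c("Deep-immune pipeline report", strrep("=", 27), "")
      if (file.exists(p(cfg$scores_csv))) {
        s <- utils::read.csv(p(cfg$scores_csv))
        lines <- c(lines, sprintf("Patients scored: %d", nrow(s)),
                   "Immune-score distribution:",
                   utils::capture.output(print(table(s$immune_score))), "")
      }
      if (file.exists(p(cfg$density_csv)) && file.exists(p(cfg$scores_csv))) {
        s <- utils::read.csv(p(cfg$scores_csv))
        d <- utils::read.csv(p(cfg$density_csv))
        m <- merge(s, d, by = "patient_id")
        gs <- group_density_summary(m$density_cells_per_mm2, m$immune_score)
        lines <- c(lines, "Stroma-CD3 density by immune score (cells/mm^2):",
                   utils::capture.output(print(gs$summary, row.names = FALSE)), "")
      }
      if (file.exists(p(cfg$survival_json))) {
        sv <- jsonlite::read_json(p(cfg$survival_json), simplifyVector = TRUE)
        lines <- c(lines,
                   sprintf("C-index: %.3f   iAUC(0-%gy): %.3f",
                           sv$c_index, cfg$horizon_years, sv$iauc),
                   sprintf("Log-rank across immune scores: chi2 = %.2f, p = %.3g",
                           sv$logrank$chi2, sv$logrank$p),
                   sprintf("%g-year survival by score: %s", cfg$horizon_years,
                           paste(sprintf("%s: %.1f%%", names(sv$five_year_by_score),
                                         100 * unlist(sv$five_year_by_score)),
                                 collapse = ", ")), "")
      }
      writeLines(lines, p(cfg$report_txt))
      pipe_log(cfg, "info", "report written to %s", p(cfg$report_txt))
      invisible(list(report = p(cfg$report_txt)))
    }
  )
}
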