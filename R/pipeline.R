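# deterministic per-stage seed derivation from the master seed
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * k) %% (.Machine$integer.max - 1)) + 1L
}

pipeline_logger <- function(out_dir, level = "info") {
  path <- file.path(out_dir, "run.log")
  function(stage, msg) {
    line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    stage, msg)
    cat(line, "\n", file = path, sep = "", append = TRUE)
    if (identical(level, "info")) rlang::inform(line)
    invisible(line)
  }
}

#' Run the full synthetic study pipeline
#'
#' One reproducible end-to-end run: simulate every synthetic dataset the
#' configuration requests, quantify the immunostained fields with
#' [segment_field()], fit the dose-response and summarize every assay, and
#' write a plain-text report. All outputs are deterministic functions of the
#' configuration (including its master seed). The run directory receives:
#' a config echo (`config.yaml`) with its MD5 content hash, the simulated
#' tables (`dose_response.csv`, `ldh.csv`, `tumor.csv`, `colonies.csv`),
#' per-field quantification (`quant.csv`), dose-response fits (`gi50.csv`),
#' cross-assay summaries (`summaries.csv`), `report.txt` and `run.log`.
#' Degenerate fields are excluded from summaries with a logged reason; any
#' stage failure is logged with the stage name and re-thrown.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `out_dir` and the file manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (!inherits(config, "run_config")) {
    stop_ihc("`config` must be a run_config", "ihcquant_bad_input")
  }
  # fail fast on unknown presets, before any output is written
  for (p in c(config$ihc$preset, config$ldh$preset, config$tumor$preset,
              config$colonies$preset)) {
    synth_preset(p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- pipeline_logger(out_dir, config$log_level)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      log(stage, paste0("FAILED: ", conditionMessage(e)))
      stop_ihc(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
               "ihcquant_pipeline_error")
    })
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  save_run_config(config, cfg_path)
  hash <- unname(tools::md5sum(cfg_path))
  writeLines(hash, file.path(out_dir, "config.md5"))
  log("config", sprintf("config echoed (md5 %s), master seed %d", hash, config$seed))

  seg_cfg <- do.call(segmentation_config, config$segmentation)
  welch <- isTRUE(config$stats$welch)

  # --- simulate ---------------------------------------------------------------
  sim <- run_stage("simulate", {
    study <- generate_ihc_study(
      config$ihc$preset, config$ihc$n_fields_per_group,
      seed = derive_seed(config$seed, 1),
      width = config$ihc$width, height = config$ihc$height
    )
    dr <- generate_dose_response(
      fourpl(config$dose_response$bottom, config$dose_response$top,
             config$dose_response$ec50, config$dose_response$hill),
      doses = config$dose_response$doses, cv = config$dose_response$cv,
      n_reps = config$dose_response$n_reps,
      seed = derive_seed(config$seed, 2),
      cell_line = config$dose_response$cell_line
    )
    ldh <- generate_ldh_plate(config$ldh$preset,
                              timepoints = config$ldh$timepoints,
                              seed = derive_seed(config$seed, 3))
    tum <- generate_tumor_series(config$tumor$preset,
                                 n_mice_per_group = config$tumor$n_mice_per_group,
                                 n_timepoints = config$tumor$n_timepoints,
                                 seed = derive_seed(config$seed, 4))
    col <- generate_colony_counts(config$colonies$preset,
                                  n_wells = config$colonies$n_wells,
                                  seed = derive_seed(config$seed, 5))
    readr::write_csv(dr, file.path(out_dir, "dose_response.csv"))
    readr::write_csv(ldh, file.path(out_dir, "ldh.csv"))
    readr::write_csv(tum, file.path(out_dir, "tumor.csv"))
    readr::write_csv(col, file.path(out_dir, "colonies.csv"))
    if (isTRUE(config$ihc$write_images)) {
      img_dir <- file.path(out_dir, "images")
      dir.create(img_dir, showWarnings = FALSE)
      purrr::pwalk(list(study$field, study$truth, study$field_id),
                   function(f, t, id) {
                     write_rgb_image(f, file.path(img_dir, paste0(id, ".tif")))
                     write_ground_truth(t, file.path(img_dir, paste0(id, "-truth.png")))
                   })
    }
    log("simulate", sprintf(
      "generated %d IHC fields (%s), %d dose-response rows, %d LDH rows, %d caliper rows, %d colony rows",
      nrow(study), config$ihc$preset, nrow(dr), nrow(ldh), nrow(tum), nrow(col)
    ))
    list(study = study, dr = dr, ldh = ldh, tum = tum, col = col)
  })

  # --- quantify ---------------------------------------------------------------
  quant <- run_stage("quantify", {
    rows <- purrr::map2(sim$study$field, sim$study$group, function(f, grp) {
      res <- tryCatch(segment_field(f, config = seg_cfg), error = function(e) {
        if (is_degenerate_error(e)) {
          log("quantify", sprintf("field '%s' excluded as degenerate: %s",
                                  f$field_id, conditionMessage(e)))
          return(NULL)
        }
        stop(e)
      })
      if (is.null(res)) return(NULL)
      dplyr::mutate(tidy(res), group = grp, .before = 1)
    })
    quant <- dplyr::bind_rows(rows)
    readr::write_csv(quant, file.path(out_dir, "quant.csv"))
    log("quantify", sprintf("%d field(s) quantified, %d excluded",
                            nrow(quant), nrow(sim$study) - nrow(quant)))
    quant
  })

  # --- fit --------------------------------------------------------------------
  gi50_tab <- run_stage("fit", {
    out <- sim$dr |>
      dplyr::group_by(.data$cell_line) |>
      dplyr::group_modify(function(d, key) {
        control_mean <- mean(d$count[d$dose_uM == 0])
        fit <- suppressWarnings(fit_4pl(d, dose_uM, count))
        g <- tryCatch(gi50(fit, control_mean), error = function(e) NA_real_)
        tibble::tibble(
          gi50_uM = g,
          converged = fit$converged,
          note = if (is.na(g)) "GI50 not reached" else "ok"
        )
      }) |>
      dplyr::ungroup()
    readr::write_csv(out, file.path(out_dir, "gi50.csv"))
    log("fit", sprintf("fitted %d dose-response curve(s)", nrow(out)))
    out
  })

  # --- summarize --------------------------------------------------------------
  summaries <- run_stage("summarize", {
    section <- quantify_section(quant, group, control = "control", welch = welch)
    ihc_rows <- dplyr::mutate(tidy(section), assay = "ihc", .before = 1)

    growth <- growth_curve_summary(sim$tum, control = "control", welch = welch)
    tumor_row <- dplyr::mutate(glance(growth), assay = "tumor",
                               measure = "endpoint_volume_mm3", .before = 1)
    tumor_row$day <- NULL

    col0 <- dplyr::filter(sim$col, .data$dose_uM %in% c(0, 0.1)) |>
      dplyr::mutate(group = ifelse(.data$dose_uM == 0, "control", "0.1uM"))
    colony_row <- compare_groups(col0, count, group, control = "control",
                                 welch = welch) |>
      dplyr::mutate(assay = "colony", measure = "colonies_per_well_0.1uM",
                    .before = 1)

    summaries <- dplyr::bind_rows(ihc_rows, tumor_row, colony_row)
    readr::write_csv(summaries, file.path(out_dir, "summaries.csv"))
    log("summarize", sprintf("%d summary row(s)", nrow(summaries)))
    list(summaries = summaries, section = section, growth = growth)
  })

  # --- report -----------------------------------------------------------------
  run_stage("report", {
    ldh_pct <- ldh_cytotoxicity(sim$ldh)
    grp <- summaries$section$groups
    sem_of <- function(measure, group) {
      grp$sem[grp$measure == measure & grp$group == group]
    }
    lines <- c(
      sprintf("ihcquant run report (seed %d, config md5 %s)", config$seed, hash),
      "",
      "Stained-area quantification (mean +/- SEM; unpaired two-tailed t-test):"
    )
    for (i in seq_len(nrow(summaries$section$comparison))) {
      cmp <- summaries$section$comparison[i, ]
      lines <- c(lines, sprintf(
        "  %-14s control %.4g +/- %.4g, treated %.4g +/- %.4g; change %+.1f%% (p = %.3g %s)",
        cmp$measure,
        cmp$control_mean, sem_of(cmp$measure, cmp$control),
        cmp$treated_mean, sem_of(cmp$measure, cmp$treated),
        cmp$percent_change, cmp$p_value, cmp$stars
      ))
    }
    e <- glance(summaries$growth)
    lines <- c(
      lines, "",
      sprintf("Tumor growth endpoint (day %g): control %.4g mm3, treated %.4g mm3; inhibition %.1f%% (p = %.3g %s)",
              e$day, e$control_mean, e$treated_mean, e$percent_inhibition,
              e$p_value, e$stars),
      "",
      "GI50 fits:"
    )
    for (i in seq_len(nrow(gi50_tab))) {
      lines <- c(lines, sprintf("  %s: GI50 = %.4g uM (%s)",
                                gi50_tab$cell_line[i], gi50_tab$gi50_uM[i],
                                gi50_tab$note[i]))
    }
    lines <- c(lines, "", "LDH release (percent cytotoxicity):")
    for (i in seq_len(nrow(ldh_pct))) {
      lines <- c(lines, sprintf("  %s at %g h: %.1f%%",
                                ldh_pct$condition[i], ldh_pct$time_h[i],
                                ldh_pct$percent_cytotoxicity[i]))
    }
    writeLines(lines, file.path(out_dir, "report.txt"))
    log("report", "report written")
  })

  manifest <- list.files(out_dir, recursive = TRUE)
  invisible(list(out_dir = out_dir, files = manifest))
}
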