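#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()]. Stages run in the fixed
#' order `synth`, `dsc`, `phase`, `hn`, `vft`, `kinetics`; requesting a
#' subset runs only those, and a stage whose inputs are missing (e.g. `hn`
#' without `synth`) is skipped with a note.
#'
#' @param seed Integer seed used by every synthetic stage.
#' @param stages Character vector of stage names (subset of the above).
#' @param out_dir Optional directory for per-stage CSV/JSON outputs; `NULL`
#'   keeps everything in the returned report only.
#' @param samples Sample names from [vft_presets()] to process in the
#'   dielectric stages (default: the rows without documented
#'   inconsistencies).
#' @param noise A [generator_config()] noise setting shared by generators.
#' @param tau_iso Isochrone for the summary table, s.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       stages = c("synth", "dsc", "phase", "hn", "vft",
                                  "kinetics"),
                       out_dir = NULL,
                       samples = NULL,
                       noise = generator_config(seed, "multiplicative", 0.005),
                       tau_iso = 0.63e-6) {
  known <- c("synth", "dsc", "phase", "hn", "vft", "kinetics")
  if (length(stages) > 0 && !all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  if (is.null(samples)) {
    pres <- vft_presets()
    samples <- pres$sample[pres$derived_ok]
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single integer", call. = FALSE)
  structure(list(seed = as.integer(seed), stages = known[known %in% stages],
                 out_dir = out_dir, samples = samples, noise = noise,
                 tau_iso = tau_iso),
            class = "run_config")
}

write_stage_csv <- function(df, cfg, name) {
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(df, file.path(cfg$out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  invisible(df)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates the five analysis stages end to end: synthetic-input
#' generation, DSC feature extraction, ideal phase diagrams, HN fitting of
#' dielectric spectra, VFT/Stickel relaxation-dynamics analysis, and
#' crystallization kinetics. Each stage records a status and timing; a
#' failed stage marks its dependents skipped rather than aborting the run.
#' The dielectric chain ends in a summary table (one row per sample:
#' kinetic Tg, fragility, VFT parameters, crossover, isochronal
#' temperature) mirroring the standard presentation of such studies.
#'
#' @param cfg A [run_config()].
#' @return List of class `pipeline_report`: `stages` (status/timing data
#'   frame), per-stage results (`phase`, `dsc`, `relaxation`, `summary`,
#'   `kinetics`), and `config`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  report <- list(config = cfg)
  status <- data.frame(stage = character(0), status = character(0),
                       seconds = numeric(0))
  note <- function(stage, st, secs)
    status <<- rbind(status, data.frame(stage = stage, status = st,
                                        seconds = round(secs, 3)))
  inputs <- NULL
  registry <- component_registry()

  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) e)
    secs <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      note(name, paste("failed:", conditionMessage(res)), secs)
      NULL
    } else {
      note(name, "ok", secs)
      res
    }
  }

  if ("synth" %in% cfg$stages) {
    inputs <- run_stage("synth", function() {
      pres <- vft_presets()
      rows <- pres[pres$sample %in% cfg$samples, , drop = FALSE]
      bds <- lapply(seq_len(nrow(rows)), function(i) {
        p <- vft_parameters(rows$log10_tau_inf[i], rows$B_K[i], rows$T0_K[i])
        make_bds_series(p, T_grid = bds_temperature_grid(p),
                        cfg = generator_config(cfg$seed + i,
                                               cfg$noise$noise_model,
                                               cfg$noise$noise_scale))
      })
      names(bds) <- rows$sample
      comps <- registry[c("EZB", "SVT", "FEN")]
      x_tern <- weight_to_mole(c(0.10, 0.20, 0.70),
                               vapply(comps, `[[`, 0, "molar_mass"))
      dsc <- make_dsc(comps, x_tern, rate = 10,
                      cfg = generator_config(cfg$seed, "gaussian-additive",
                                             0.01))
      pk <- crystallization_presets()
      kin <- lapply(seq_len(nrow(pk)), function(i)
        make_crystallization(pk$t_half_s[i],
                             temperature = pk$temperature_K[i],
                             cfg = generator_config(cfg$seed + 100 + i,
                                                    cfg$noise$noise_model,
                                                    cfg$noise$noise_scale),
                             sample_label = pk$scenario[i]))
      names(kin) <- pk$scenario
      list(bds = bds, dsc = dsc, kinetics = kin)
    })
  }

  if ("phase" %in% cfg$stages) {
    report$phase <- run_stage("phase", function() {
      comps <- registry[c("EZB", "SVT", "FEN")]
      pairs <- utils::combn(names(comps), 2, simplify = FALSE)
      bins <- do.call(rbind, lapply(pairs, function(pr) {
        e <- binary_eutectic(comps[[pr[1]]], comps[[pr[2]]])
        data.frame(system = paste(pr, collapse = "/"),
                   x_e_first = e$x_e, T_e_K = e$T_e)
      }))
      tern <- ternary_eutectic(comps[[1]], comps[[2]], comps[[3]],
                               grid_resolution = 0.02)
      write_stage_csv(bins, cfg, "binary_eutectics")
      write_stage_csv(tern$grid, cfg, "ternary_liquidus_surface")
      list(binary = bins,
           ternary = data.frame(x_EZB = tern$x_e[1], x_SVT = tern$x_e[2],
                                x_FEN = tern$x_e[3], T_e_K = tern$T_e))
    })
  }

  if ("dsc" %in% cfg$stages) {
    report$dsc <- run_stage("dsc", function() {
      if (is.null(inputs)) stop("no thermogram inputs (synth stage not run)")
      ev <- detect_endotherms(inputs$dsc)
      sl <- solidus_liquidus(ev)
      out <- data.frame(n_events = nrow(ev), solidus_K = sl$solidus_K,
                        liquidus_K = sl$liquidus_K,
                        eutectic_like = sl$eutectic_like)
      write_stage_csv(ev, cfg, "dsc_events")
      list(events = ev, summary = out)
    })
  }

  maps <- NULL
  if ("hn" %in% cfg$stages) {
    maps <- run_stage("hn", function() {
      if (is.null(inputs)) stop("no spectra inputs (synth stage not run)")
      lapply(inputs$bds, function(series) {
        taus <- vapply(series, function(s) fit_hn(s)$tau_alpha, 0)
        Ts <- vapply(series, `[[`, 0, "temperature")
        relaxation_map(Ts, taus)
      })
    })
    report$relaxation <- maps
  }

  if ("vft" %in% cfg$stages) {
    report$summary <- run_stage("vft", function() {
      if (is.null(maps)) stop("no relaxation maps (hn stage not run)")
      rows <- lapply(names(maps), function(nm) {
        p <- fit_vft(maps[[nm]])
        cross <- tryCatch(
          detect_crossover(stickel_transform(maps[[nm]]))$T_cross,
          error = function(e) NA_real_)
        cbind(dynamics_summary(p, sample = nm, tau_iso = cfg$tau_iso),
              T_cross_K = cross)
      })
      tab <- do.call(rbind, rows)
      write_stage_csv(tab, cfg, "dynamics_summary")
      if (!is.null(cfg$out_dir))
        jsonlite::write_json(tab, file.path(cfg$out_dir,
                                            "dynamics_summary.json"),
                             dataframe = "rows", auto_unbox = TRUE,
                             digits = NA)
      tab
    })
  }

  if ("kinetics" %in% cfg$stages) {
    report$kinetics <- run_stage("kinetics", function() {
      if (is.null(inputs)) stop("no kinetics inputs (synth stage not run)")
      tab <- do.call(rbind, lapply(inputs$kinetics, function(cs) {
        kt <- kinetic_times(normalize_series(cs))
        data.frame(sample = cs$sample_label, onset_s = kt$onset_s,
                   t_half_s = kt$t_half_s, endset_s = kt$endset_s)
      }))
      rownames(tab) <- NULL
      write_stage_csv(tab, cfg, "crystallization_summary")
      tab
    })
  }

  report$stages <- status
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$stages, row.names = FALSE)
  if (!is.null(x$summary)) {
    cat("\nDynamics summary (display rounding: K and m_p to integers):\n")
    s <- x$summary
    s$Tg_BDS_K <- round(s$Tg_BDS_K)
    s$m_p <- round(s$m_p)
    s$T_iso_K <- round(s$T_iso_K)
    s$T_cross_K <- round(s$T_cross_K)
    print(s, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
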