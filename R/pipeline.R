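#' Pipeline configuration
#'
#' One structured configuration drives [run_pipeline()]: stage selection,
#' colorimetry settings, fit and matching tolerances, output directory and
#' the seed from which every stochastic stage derives its stream. Unknown
#' keys are rejected and the configuration round-trips through YAML
#' unchanged.
#'
#' @param stages Character subset of
#'   `c("spectra", "color", "mass", "titration", "decay", "hplc", "seqid")`
#'   (default: all but the alignment-heavy `seqid`).
#' @param seed Integer master seed.
#' @param out_dir Output directory for JSON reports (`NULL` = don't write).
#' @param observer,illuminant,step_nm,path_scale Colorimetry settings.
#' @param tol_ppm Mass-match tolerance, ppm.
#' @param lambda_window Analysis window for lambda-max, nm.
#' @param titration_noise_sd Noise level for the titration stage fixtures, AU.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(stages = c("spectra", "color", "mass", "titration",
                                       "decay", "hplc"),
                            seed = 1, out_dir = NULL,
                            observer = "cie1931_2deg", illuminant = "D65",
                            step_nm = 1, path_scale = 1, tol_ppm = 10,
                            lambda_window = c(400, 700),
                            titration_noise_sd = 0.005) {
  known <- c("spectra", "color", "mass", "titration", "decay", "hplc", "seqid")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  structure(list(stages = stages, seed = as.integer(seed), out_dir = out_dir,
                 observer = observer, illuminant = illuminant,
                 step_nm = step_nm, path_scale = path_scale,
                 tol_ppm = tol_ppm, lambda_window = lambda_window,
                 titration_noise_sd = titration_noise_sd),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Unknown keys in the file are rejected rather than silently dropped.
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()]: a `"pipeline_config"`;
#'   [write_pipeline_config()]: `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param cfg A `"pipeline_config"`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the end-to-end characterisation pipeline on packaged fixtures
#'
#' Executes the selected stages against the synthetic fixture library and
#' returns (and optionally writes as JSON) one report per stage plus a
#' combined summary. Reports carry parameters, units and seeds and contain
#' no timestamps, so re-running with the same configuration and seed is
#' reproducible byte for byte.
#'
#' @param cfg A [pipeline_config()].
#' @return Named list of stage reports (each a plain list), invisibly also
#'   written to `cfg$out_dir` as `<stage>.json` plus `summary.json`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  reports <- list()
  for (stage in cfg$stages) {
    reports[[stage]] <- switch(stage,
      spectra = stage_spectra(cfg),
      color = stage_color(cfg),
      mass = stage_mass(cfg),
      titration = stage_titration(cfg),
      decay = stage_decay(cfg),
      hplc = stage_hplc(cfg),
      seqid = stage_seqid(cfg)
    )
  }
  summary <- list(stages = cfg$stages, seed = cfg$seed,
                  reports = lapply(reports, function(r) r$headline))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (stage in names(reports)) {
      jsonlite::write_json(reports[[stage]],
                           file.path(cfg$out_dir, paste0(stage, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(reports, list(summary = summary)))
}

stage_spectra <- function(cfg) {
  blues <- c("blue_no1", "spirulina", "rca_pH8", "alp2_pH7")
  metrics <- purrr::map_dfr(blues, function(nm) {
    dplyr::bind_cols(tibble::tibble(sample = nm),
                     spectral_metrics(make_spectrum_fixture(nm),
                                      window = cfg$lambda_window))
  })
  shifts <- purrr::map_dfr(c("P2", "P5", "P8"), function(p) {
    tibble::tibble(
      sample = p,
      shift_nm = bathochromic_shift(make_spectrum_fixture(paste0(p, "_0eq")),
                                    make_spectrum_fixture(paste0(p, "_Al13")),
                                    cfg$lambda_window))
  })
  list(units = list(lambda_max_nm = "nm", a_max = "AU",
                    violet_contribution = "nm*AU", shift_nm = "nm"),
       metrics = metrics, bathochromic_shifts = shifts,
       headline = list(alp2_lambda_max_nm = metrics$lambda_max_nm[metrics$sample == "alp2_pH7"],
                       P2_shift_nm = shifts$shift_nm[shifts$sample == "P2"]))
}

stage_color <- function(cfg) {
  settings <- colorimetry_settings(cfg$observer, cfg$illuminant,
                                   cfg$step_nm, cfg$path_scale)
  blues <- c("blue_no1", "spirulina", "rca_pH8", "alp2_pH7")
  rep <- purrr::map_dfr(blues, function(nm) {
    color_report(make_spectrum_fixture(nm), settings, sample = nm)
  })
  hue_ref <- rep$hue_deg[rep$sample == "blue_no1"]
  hue_alp2 <- rep$hue_deg[rep$sample == "alp2_pH7"]
  dh <- abs(hue_alp2 - hue_ref) %% 360
  dh <- min(dh, 360 - dh)
  de <- delta_e76(rep[rep$sample == "alp2_pH7", ], rep[rep$sample == "blue_no1", ])
  list(units = list(L_star = "CIELAB", hue_deg = "degrees", delta_e = "CIE76"),
       colors = rep,
       hue_match = list(abs_delta_hue_deg = dh, delta_e76 = de),
       headline = list(abs_delta_hue_alp2_vs_blue1_deg = dh))
}

stage_mass <- function(cfg) {
  p2 <- compose_anthocyanin(anthocyanin_spec(n_glucosyl = 3,
                                             acyl_groups = c(`Glc-2` = "sinapoyl")))
  observed <- mass_peak_library$alp2_esi_neg$observed_mz
  assign <- assign_stoichiometry(observed, p2, metal = "Al", tol_ppm = cfg$tol_ppm)
  list(units = list(mz = "Th", mass = "Da", ppm_error = "ppm"),
       p2_formula = format(p2),
       p2_cation_mz = monoisotopic_mass(p2),
       observed_mz = observed,
       assignments = assign$assignments,
       consensus_k = assign$consensus_k,
       headline = list(consensus_k = assign$consensus_k))
}

stage_titration <- function(cfg) {
  fits <- purrr::map_dfr(names(titration_library), function(nm) {
    d <- make_titration_fixture(nm, seed = cfg$seed + match(nm, names(titration_library)),
                                noise_sd = cfg$titration_noise_sd)
    f <- fit_pkh(d)
    tibble::tibble(sample = nm, pKh_true = attr(d, "metadata")$pKh_true,
                   pKh_hat = f$estimate, stderr = f$stderr,
                   ci_lo = f$ci95[1], ci_hi = f$ci95[2], n = f$n,
                   converged = f$converged)
  })
  list(units = list(pKh = "log units"), fits = fits, seed = cfg$seed,
       headline = list(P2_pKh_hat = fits$pKh_hat[fits$sample == "P2"]))
}

stage_decay <- function(cfg) {
  entries <- list(list(name = "rca_syrup", at = 10),
                  list(name = "alp2_syrup", at = 55))
  rows <- purrr::map_dfr(entries, function(e) {
    d <- make_decay_fixture(e$name)
    f <- fit_first_order(d)
    tibble::tibble(sample = e$name, k_per_day = f$k_per_day,
                   half_life_days = f$half_life_days, at_days = e$at,
                   percent_loss = percent_loss(f, e$at))
  })
  list(units = list(k_per_day = "1/day", percent_loss = "%"), decays = rows,
       headline = list(rca_loss_day10_pct = rows$percent_loss[rows$sample == "rca_syrup"],
                       alp2_loss_day55_pct = rows$percent_loss[rows$sample == "alp2_syrup"]))
}

stage_hplc <- function(cfg) {
  tables <- lapply(c(before = "untreated", after = "M73H_complete"), function(tr) {
    ch <- make_rca_chromatogram(tr)
    assign_peaks(integrate_peaks(ch, detect_peaks(ch)))
  })
  conv <- conversion_metrics(tables$before, tables$after)
  p2rel <- tables$before$relative_area[tables$before$peak == "P2"]
  list(units = list(area = "mAU*min", relative_area = "%"),
       untreated_peaks = tables$before, treated_peaks = tables$after,
       conversion = conv,
       headline = list(untreated_P2_relative_area_pct = p2rel,
                       conversion_fraction = conv$fraction_converted))
}

stage_seqid <- function(cfg) {
  panel <- make_sequence_panel(seed = cfg$seed)
  m <- identity_matrix(panel)
  summ <- screen_summary(panel)
  med_all <- median_identity(m)
  med_act <- median_identity(m, panel$id[panel$active])
  list(units = list(identity = "%"),
       screen = summ,
       median_identity_all = med_all,
       median_identity_active = med_act,
       headline = list(n_tested = summ$n_tested, n_active = summ$n_active,
                       median_identity_all = med_all,
                       median_identity_active = med_act))
}
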