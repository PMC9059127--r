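#' Write a titration series to disk
#'
#' Serializes every sample/reference spectrum pair of a series plus a
#' tab-delimited manifest (`manifest.tsv`: columns `sample_file`,
#' `reference_file`, one molality column per solute, `d2o_fraction`,
#' `path_length_mm`, `temperature_C`) and a solute table (`solutes.tsv`:
#' `name`, `molar_mass`, `role`).
#'
#' @param series a [solution_series()].
#' @param dir output directory (created if missing).
#' @param format spectrum file format, `"two_column_text"` or `"jcamp_dx"`.
#' @return The manifest path, invisibly.
#' @export
write_series <- function(series, dir, format = c("two_column_text", "jcamp_dx")) {
  format <- match.arg(format)
  ext <- if (format == "jcamp_dx") ".jdx" else ".txt"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  solutes <- do.call(c, lapply(series$samples, function(s)
    lapply(s$solutes, function(x) x)))
  all_names <- vapply(solutes, `[[`, "", "name")
  solutes <- solutes[!duplicated(all_names)]
  snames <- vapply(solutes, `[[`, "", "name")
  rows <- lapply(seq_along(series$samples), function(i) {
    s <- series$samples[[i]]
    sf <- sprintf("sample_%02d%s", i, ext)
    rf <- sprintf("reference_%02d%s", i, ext)
    write_spectrum(s$sample_spectrum, file.path(dir, sf), format)
    write_spectrum(s$reference_spectrum, file.path(dir, rf), format)
    mols <- vapply(snames, function(nm) sample_molality(s, nm), 0)
    c(sample_file = sf, reference_file = rf,
      stats::setNames(sprintf("%.10g", mols), snames),
      d2o_fraction = sprintf("%.6g", s$d2o_mass_fraction),
      path_length_mm = sprintf("%.6g", s$sample_spectrum$meta$path_length_mm),
      temperature_C = sprintf("%.6g", s$sample_spectrum$meta$temperature_C))
  })
  man <- do.call(rbind, rows)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sol <- do.call(rbind, lapply(solutes, function(x)
    data.frame(name = x$name, molar_mass = x$molar_mass, role = x$role)))
  utils::write.table(sol, file.path(dir, "solutes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

#' Read a titration series from a manifest
#'
#' Counterpart of [write_series()]. The varied solute is the one whose
#' molality changes across rows; a solute with constant non-zero molality
#' becomes the constant solute.
#'
#' @param manifest path to `manifest.tsv`.
#' @param solutes optional list of [solute_spec()]; defaults to
#'   `solutes.tsv` next to the manifest.
#' @return A [solution_series()].
#' @export
read_series_manifest <- function(manifest, solutes = NULL) {
  if (!file.exists(manifest)) stop("no such manifest: ", manifest, call. = FALSE)
  man <- utils::read.delim(manifest, check.names = FALSE,
                           stringsAsFactors = FALSE)
  required <- c("sample_file", "reference_file", "d2o_fraction",
                "path_length_mm", "temperature_C")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols))
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  snames <- setdiff(names(man), required)
  if (!length(snames) )
    stop("manifest has no solute molality column", call. = FALSE)
  if (is.null(solutes)) {
    sol_path <- file.path(dirname(manifest), "solutes.tsv")
    if (file.exists(sol_path)) {
      st <- utils::read.delim(sol_path, stringsAsFactors = FALSE)
      solutes <- lapply(seq_len(nrow(st)), function(i)
        solute_spec(st$name[i], st$molar_mass[i], st$role[i]))
    } else {
      stop("no solutes.tsv next to the manifest and no solutes given",
           call. = FALSE)
    }
  }
  names(solutes) <- vapply(solutes, `[[`, "", "name")
  unknown <- setdiff(snames, names(solutes))
  if (length(unknown))
    stop("manifest solute column(s) without a solute definition: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  samples <- lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    mols <- vapply(snames, function(nm) suppressWarnings(as.numeric(row[[nm]])), 0)
    if (any(!is.finite(mols)))
      stop(sprintf("manifest row %d: non-numeric molality", i), call. = FALSE)
    read1 <- function(fld) {
      p <- file.path(dirname(manifest), row[[fld]])
      if (!file.exists(p))
        stop(sprintf("manifest row %d: missing file '%s'", i, row[[fld]]),
             call. = FALSE)
      tryCatch(read_spectrum(p,
                             path_length_mm = as.numeric(row$path_length_mm),
                             temperature_C = as.numeric(row$temperature_C)),
               error = function(e)
                 stop(sprintf("manifest row %d: %s", i, conditionMessage(e)),
                      call. = FALSE))
    }
    solution_sample(read1("sample_file"), read1("reference_file"),
                    solutes = solutes[snames],
                    molalities = mols,
                    d2o_mass_fraction = as.numeric(row$d2o_fraction))
  })
  mols <- do.call(rbind, lapply(samples, function(s)
    vapply(snames, function(nm) sample_molality(s, nm), 0)))
  n_distinct <- apply(mols, 2, function(x) length(unique(x)))
  varied <- snames[which.max(n_distinct)]
  const <- setdiff(snames[apply(mols, 2, function(x) any(x > 0))], varied)
  solution_series(samples,
                  varied_solute = solutes[[varied]],
                  constant_solute = if (length(const)) solutes[[const[1]]])
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the analysis chain.
#'
#' @param analysis_window OD-band analysis window, cm^-1.
#' @param fit_order molality fit order for the derivative (1 or 2).
#' @param smooth_n Savitzky-Golay pre-smoothing window (points; 1 disables).
#' @param N_scan search range of the affected-number scan.
#' @param mc_draws,mc_seed Monte-Carlo settings for regime uncertainty.
#' @param calibration an [od_distance_calibration()].
#' @param dr distance-grid step for P(R) tables, Angstrom.
#' @param spectrum_format output format for spectrum files.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(analysis_window = c(2200, 2750),
                            fit_order = 1L, smooth_n = 25L,
                            N_scan = c(0.5, 5000),
                            mc_draws = 200L, mc_seed = 20220420,
                            calibration = od_distance_calibration(),
                            dr = 0.002,
                            spectrum_format = "two_column_text") {
  stopifnot(length(analysis_window) == 2, diff(analysis_window) > 0,
            fit_order %in% c(1L, 2L), length(N_scan) == 2,
            N_scan[1] > 0, diff(N_scan) > 0, mc_draws >= 0, dr > 0)
  structure(list(analysis_window = analysis_window, fit_order = fit_order,
                 smooth_n = smooth_n, N_scan = N_scan,
                 mc_draws = mc_draws, mc_seed = mc_seed,
                 calibration = calibration, dr = dr,
                 spectrum_format = spectrum_format),
            class = "pipeline_config")
}

# deterministic polynomial hash of the serialized configuration, recorded in
# reports so a result can be traced to its settings
config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis chain on a preset or on manifests
#'
#' Chains simulation (or manifest reading), single-solute fits for both
#' components, the two-solute titration profile, band descriptors and O...O
#' distance distributions, and writes a machine-readable result tree:
#' `profile.tsv`, `single_<solute>.json`, `descriptors.json`,
#' `delta_P_<molality>.tsv`, affected/double spectrum files, `config.json`
#' (with a config hash) and `log.txt`.
#'
#' @param out_dir output directory.
#' @param preset name of a two-solute [preset_scenario()]; the matching
#'   single-solute series are simulated with the same noise level and seed.
#' @param manifest,manifest_single_m,manifest_single_o alternatively, paths
#'   to a two-solute manifest and the two single-solute manifests.
#' @param config a [pipeline_config()].
#' @param seed RNG seed for simulation (`NULL` keeps the preset's).
#' @param noise_sd noise override for simulation.
#' @return Invisibly, a list with `profile`, `fit_m`, `fit_o`, `fits`
#'   (per-molality double fits) and the output paths.
#' @export
run_pipeline <- function(out_dir, preset = NULL,
                         manifest = NULL, manifest_single_m = NULL,
                         manifest_single_o = NULL,
                         config = pipeline_config(), seed = NULL,
                         noise_sd = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  say("config hash %s", config_hash(config))
  if (!is.null(preset)) {
    scn <- preset_scenario(preset, noise_sd = noise_sd, seed = seed)
    if (length(scn$components) != 2L)
      stop("run_pipeline needs a two-solute preset; got '", preset, "'",
           call. = FALSE)
    say("stage simulate: preset %s (seed %d)", preset, scn$seed)
    gen <- generate_series(scn)
    series <- gen$series
    nm_m <- scn$components[-scn$varied][[1]]$solute$name
    nm_o <- scn$components[[scn$varied]]$solute$name
    mk_single <- function(nm)
      generate_series(preset_scenario(paste0("single_", nm),
                                      noise_sd = noise_sd, seed = seed))$series
    series_m <- mk_single(nm_m)
    series_o <- mk_single(nm_o)
  } else {
    if (is.null(manifest) || is.null(manifest_single_m) ||
        is.null(manifest_single_o))
      stop("either a preset or all three manifests must be given",
           call. = FALSE)
    say("stage read: manifests")
    series <- read_series_manifest(manifest)
    series_m <- read_series_manifest(manifest_single_m)
    series_o <- read_series_manifest(manifest_single_o)
    nm_m <- series$constant_solute$name
    nm_o <- series$varied_solute$name
  }
  run_stage <- function(label, expr) {
    say("stage %s", label)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", label, conditionMessage(e)),
           call. = FALSE))
  }
  fit1 <- function(ser) fit_affected_water(
    ser, window = config$analysis_window, fit_order = config$fit_order,
    smooth_n = config$smooth_n, N_scan = config$N_scan)
  fit_m <- run_stage(paste0("single ", nm_m), fit1(series_m))
  fit_o <- run_stage(paste0("single ", nm_o), fit1(series_o))
  prof <- run_stage("double", titration_profile(
    series, fit_m, fit_o, window = config$analysis_window,
    smooth_n = config$smooth_n, N_scan = config$N_scan,
    mc_draws = config$mc_draws, mc_seed = config$mc_seed))
  fits <- attr(prof, "fits")

  ext <- if (config$spectrum_format == "jcamp_dx") ".jdx" else ".txt"
  wspec <- function(s, name) {
    p <- file.path(out_dir, paste0(name, ext))
    write_spectrum(s, p, config$spectrum_format)
    p
  }
  run_stage("report", {
    report1 <- function(fit, nm) {
      jsonlite::write_json(
        list(schema = "hdoshell/single/1", solute = nm, N = fit$N,
             window = fit$window,
             fit_residual_rms = fit$diagnostics$fit_residual_rms,
             n_samples = fit$diagnostics$n_samples,
             N_search_trace = fit$diagnostics$N_search_trace,
             config_hash = config_hash(config)),
        file.path(out_dir, paste0("single_", nm, ".json")),
        auto_unbox = TRUE, digits = NA)
      wspec(fit$affected_spectrum, paste0("affected_", nm))
    }
    report1(fit_m, nm_m)
    report1(fit_o, nm_o)
    prof_out <- as.data.frame(prof)
    # energetics of the double-affected water relative to the biomolecule
    nu_g_m <- gravity_center(fit_m$affected_spectrum, config$analysis_window)
    prof_out$delta_nu_g <- prof_out$nu_g_double - nu_g_m
    utils::write.table(prof_out, file.path(out_dir, "profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    P_m <- distance_distribution(fit_m$affected_spectrum,
                                 config$analysis_window,
                                 config$calibration, config$dr)
    desc <- list(schema = "hdoshell/descriptors/1",
                 config_hash = config_hash(config),
                 nu_g_m = nu_g_m,
                 nu_max_m = band_maximum(fit_m$affected_spectrum,
                                         config$analysis_window),
                 mode_R_m = P_m$mode, rows = list())
    for (f in fits) {
      tagg <- sprintf("m_o_%g", f$m_o)
      wspec(f$double_spectrum, paste0("double_", tagg))
      row <- list(m_o = f$m_o, regime = f$regime,
                  low_confidence = f$low_confidence)
      if (!f$low_confidence) {
        P_d <- distance_distribution(f$double_spectrum,
                                     config$analysis_window,
                                     config$calibration, config$dr)
        dP <- delta_P(P_d, P_m)
        utils::write.table(
          dP, file.path(out_dir, sprintf("delta_P_%s.tsv", tagg)),
          sep = "\t", quote = FALSE, row.names = FALSE)
        row$nu_g_double <- gravity_center(f$double_spectrum,
                                          config$analysis_window)
        row$delta_nu_g <- row$nu_g_double - nu_g_m
        row$mode_R_double <- P_d$mode
      }
      desc$rows[[tagg]] <- row
    }
    jsonlite::write_json(desc, file.path(out_dir, "descriptors.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(schema = "hdoshell/config/1", hash = config_hash(config),
           analysis_window = config$analysis_window,
           fit_order = config$fit_order, smooth_n = config$smooth_n,
           N_scan = config$N_scan, mc_draws = config$mc_draws,
           mc_seed = config$mc_seed, dr = config$dr,
           calibration = unclass(config$calibration)),
      file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  })
  say("done: %d molalities", nrow(prof))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(profile = prof, fit_m = fit_m, fit_o = fit_o, fits = fits,
                 out_dir = out_dir))
}
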