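# End-to-end orchestration: simulate a subject, analyze it, summarize a
# cohort, and run the species comparison. Deterministic under a single seed;
# outputs (when written) are listed in a manifest with content hashes.

#' Simulate and analyze one synthetic subject
#'
#' Generates a folded V1 patch, applies measurement noise (or decodes maps
#' from generated traveling-wave time series when `from_timeseries` is
#' TRUE), delineates V1, computes the foveal-distance field, fits the
#' magnification function, and summarizes the rCaS and eCaS.
#'
#' @param species `"human"` or `"macaque"`.
#' @param seed subject seed (drives noise and dropout).
#' @param hemisphere `"left"` or `"right"`.
#' @param subject_id identifier stored in outputs.
#' @param preset optional [species_preset()] override.
#' @param resolution grid vertices per mm.
#' @param noise list with `angle_sd`, `log_ecc_sd`, `dropout_rate`.
#' @param anatomy_jitter sd of the seeded log-normal jitter applied to the
#'   preset's fold depths per subject (default 0.1, factor clamped to
#'   [0.85, 1.05]); models between-subject anatomical variability while
#'   keeping all subjects of a species on a common grid. 0 disables.
#' @param delineation_args list of overrides for [delineate_v1()].
#' @param fit_args list of overrides for [fit_cmf()].
#' @param from_timeseries decode the maps from synthesized wedge/ring
#'   traveling-wave runs (the macaque-style route) instead of adding map
#'   noise directly (the pRF-style route).
#' @param ts_noise_sd,hemodynamic_delay time-series options when
#'   `from_timeseries` is TRUE.
#' @return list: `pial`, `white`, `truth`, `map`, `delineation`, `fit`,
#'   `samples`, `summaries` (rCaS and eCaS rows).
#' @export
simulate_subject <- function(species = "human", seed = 1L,
                             hemisphere = "left",
                             subject_id = sprintf("%s_%03d", species, seed),
                             preset = NULL, resolution = 2,
                             noise = list(), delineation_args = list(),
                             fit_args = list(), from_timeseries = FALSE,
                             ts_noise_sd = 0.5, hemodynamic_delay = 4,
                             anatomy_jitter = 0.1) {
  preset <- preset %||% species_preset(species)
  if (anatomy_jitter > 0) {
    set.seed(seed * 3L + 17L)
    fac <- pmin(pmax(exp(stats::rnorm(length(preset$fold_amplitudes), 0,
                                      anatomy_jitter)), 0.85), 1.05)
    preset$fold_amplitudes <- preset$fold_amplitudes * fac
  }
  patch <- generate_v1_patch(preset, resolution = resolution,
                             hemisphere = hemisphere,
                             subject_id = subject_id, seed = seed)
  noise <- utils::modifyList(list(angle_sd = 8, log_ecc_sd = 0.1,
                                  dropout_rate = 0.05), noise)
  map <- if (from_timeseries) {
    decode_subject_maps(patch$truth, preset, ts_noise_sd, hemodynamic_delay,
                        seed)
  } else {
    add_measurement_noise(patch$truth, angle_sd = noise$angle_sd,
                          log_ecc_sd = noise$log_ecc_sd,
                          dropout_rate = noise$dropout_rate, seed = seed)
  }
  delin <- do.call(delineate_v1, c(
    list(map = map, mesh = patch$pial,
         v1_hint = patch$truth$labels$labels$V1,
         stimulus_radius = preset$stimulus_radius),
    delineation_args))
  samples <- collect_samples(map, delin, patch$truth$labels)
  fit <- do.call(fit_cmf, c(list(samples = samples), fit_args))
  summaries <- do.call(rbind, lapply(c("rCaS", "eCaS"), function(s)
    summarize_sulcus(map, patch$pial, patch$white, patch$truth$labels,
                     delin, s)))
  list(pial = patch$pial, white = patch$white, truth = patch$truth,
       map = map, delineation = delin, fit = fit, samples = samples,
       summaries = summaries)
}

# Wedge + ring traveling-wave synthesis and decoding for one subject:
# opposite-direction run pairs, Fourier phase, direction combination,
# phase-to-visual decoding.
decode_subject_maps <- function(truth, preset, noise_sd = 0.5, delay = 4,
                                seed = 1L) {
  decode_one <- function(kind) {
    spec_f <- stimulus_spec(kind, direction = 1L,
                            sweep_range = if (kind == "wedge") c(0, 360)
                            else c(0, preset$stimulus_radius))
    spec_r <- utils::modifyList(spec_f, list(direction = -1L))
    class(spec_r) <- "stimulus_spec"
    ts_f <- generate_timeseries(truth, spec_f, noise_sd, delay, seed = seed)
    ts_r <- generate_timeseries(truth, spec_r, noise_sd, delay,
                                seed = seed + 500000L)
    pm <- combine_directions(fourier_phase(ts_f), fourier_phase(ts_r))
    phase_to_visual(pm, spec_f)
  }
  pa <- decode_one("wedge")
  ec <- decode_one("ring")
  coh <- vertex_overlay(rep(1, length(pa$values)), units = "unitless")
  retinotopic_map(pa, ec, coh)
}

#' Default pipeline configuration
#'
#' @param n_human,n_macaque subjects per species (defaults 24 and 6, one
#'   left and one right hemisphere each).
#' @param seed master seed; per-subject seeds are derived from it.
#' @param out_dir optional output directory; when given, tables and a
#'   manifest are written there.
#' @param ... overrides for `resolution`, `noise`, `delineation_args`,
#'   `fit_args`, `from_timeseries`, `measures`, `histogram_fractions`.
#' @return config list for [run_pipeline()].
#' @export
default_config <- function(n_human = 24L, n_macaque = 6L, seed = 1L,
                           out_dir = NULL, ...) {
  cfg <- list(n_human = n_human, n_macaque = n_macaque, seed = seed,
              out_dir = out_dir, resolution = 2,
              noise = list(angle_sd = 8, log_ecc_sd = 0.1,
                           dropout_rate = 0.05),
              delineation_args = list(), fit_args = list(),
              from_timeseries = FALSE, anatomy_jitter = 0.1,
              measures = c("mean_ecc", "pct_of_v1"),
              histogram_fractions = c(0.99, 0.75, 0.5, 0.25))
  utils::modifyList(cfg, list(...))
}

#' Run the full cohort pipeline
#'
#' Simulates `n_human + n_macaque` subjects (both hemispheres each),
#' analyzes every hemisphere, and produces per-hemisphere sulcal summaries,
#' per-subject magnification fits, group mean/SEM tables, and one
#' species-by-hemisphere ANOVA per sulcus and measure. A failing subject is
#' recorded and skipped, never fatal. With `out_dir` set, writes
#' `summaries.csv`, `fits.csv`, `group_tables.csv`, `anova.json`, and
#' `manifest.json` (md5 content hashes).
#'
#' @param config list from [default_config()].
#' @return list: `summaries`, `fits`, `group_tables`, `anovas`, `failures`,
#'   `manifest` (NULL unless written).
#' @export
run_pipeline <- function(config = default_config()) {
  plan <- expand.grid(hemisphere = c("left", "right"),
                      idx = seq_len(config$n_human + config$n_macaque),
                      stringsAsFactors = FALSE)
  plan$species <- ifelse(plan$idx <= config$n_human, "human", "macaque")
  summaries <- list(); fits <- list(); failures <- list()
  for (r in seq_len(nrow(plan))) {
    sp <- plan$species[r]; hemi <- plan$hemisphere[r]; i <- plan$idx[r]
    sid <- sprintf("%s_%03d", sp, i)
    seed_r <- (config$seed * 10000L + i * 7L +
                 ifelse(hemi == "right", 3L, 0L)) %% .Machine$integer.max
    res <- tryCatch(
      simulate_subject(sp, seed = seed_r, hemisphere = hemi,
                       subject_id = sid, resolution = config$resolution,
                       noise = config$noise,
                       delineation_args = config$delineation_args,
                       fit_args = config$fit_args,
                       from_timeseries = config$from_timeseries,
                       anatomy_jitter = config$anatomy_jitter),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(subject_id = sid, hemisphere = hemi,
                   message = conditionMessage(res))
      next
    }
    summaries[[length(summaries) + 1L]] <- res$summaries
    fits[[length(fits) + 1L]] <-
      data.frame(subject_id = sid, species = sp, hemisphere = hemi,
                 a = res$fit$a, b = res$fit$b,
                 r_squared = res$fit$r_squared,
                 n_samples = res$fit$n_samples,
                 converged = res$fit$converged)
  }
  summaries <- do.call(rbind, summaries)
  fits <- do.call(rbind, fits)
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(subject_id = character(), hemisphere = character(),
               message = character())
  group_tables <- do.call(rbind, lapply(config$measures, function(m)
    cbind(measure = m, group_table(summaries, m))))
  anovas <- list()
  for (s in unique(summaries$sulcus)) {
    for (m in config$measures) {
      sub <- summaries[summaries$sulcus == s & is.finite(summaries[[m]]), ]
      key <- paste(s, m, sep = ".")
      anovas[[key]] <- tryCatch(
        two_way_anova(sub[[m]], sub$species, sub$hemisphere),
        error = function(e) conditionMessage(e))
    }
  }
  manifest <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(summaries = "summaries.csv", fits = "fits.csv",
               group_tables = "group_tables.csv")
    for (nm in names(paths)) {
      utils::write.csv(get(nm), file.path(config$out_dir, paths[[nm]]),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(anovas, function(a) if (inherits(a, "anova_result"))
        list(effects = a$effects, grand_n = a$grand_n,
             design_balanced = a$design_balanced, ss_type = a$ss_type)
        else list(error = a)),
      file.path(config$out_dir, "anova.json"), auto_unbox = TRUE,
      digits = NA)
    files <- c(unname(paths), "anova.json")
    manifest <- data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(config$out_dir, files))),
      seed = config$seed)
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(summaries = summaries, fits = fits, group_tables = group_tables,
       anovas = anovas, failures = failures, manifest = manifest)
}

#' Write a complete synthetic subject to disk
#'
#' Surfaces as GIFTI (or FreeSurfer binary), truth overlays as curv/GIFTI,
#' labels as JSON, and a JSON sidecar of generator parameters.
#'
#' @param patch result of [generate_v1_patch()].
#' @param dir output directory (created).
#' @param format `"gifti"` or `"freesurfer"` for surfaces/overlays.
#' @return invisibly, the written file paths.
#' @export
write_subject <- function(patch, dir, format = c("gifti", "freesurfer")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sfx <- if (format == "gifti") ".surf.gii" else ""
  osfx <- if (format == "gifti") ".func.gii" else ".curv"
  files <- c(pial = paste0("pial", sfx), white = paste0("white", sfx),
             polar = paste0("polar_angle", osfx),
             ecc = paste0("eccentricity", osfx),
             labels = "labels.json", params = "params.json")
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  write_surface(patch$pial, paths["pial"],
                format = if (format == "gifti") "gifti" else "freesurfer")
  write_surface(patch$white, paths["white"],
                format = if (format == "gifti") "gifti" else "freesurfer")
  fmt <- if (format == "gifti") "gifti" else "curv"
  write_overlay(patch$truth$true_map$polar_angle, paths["polar"], fmt)
  write_overlay(patch$truth$true_map$eccentricity, paths["ecc"], fmt)
  write_labels(patch$truth$labels, paths["labels"], "json")
  jsonlite::write_json(patch$truth$params, paths["params"],
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(paths)
}
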