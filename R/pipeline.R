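#' Configuration for a per-specimen pipeline run
#'
#' Bundles every tunable parameter of the per-specimen pipeline with its
#' default, mirroring the segmentation and orientation stage arguments. All
#' physical parameters must be positive. A config can also be read from a
#' YAML or JSON file with [read_run_config()].
#'
#' @param voxel_size isotropic voxel size of the input stack, um.
#' @param closing_radius ball radius in voxels for [close_cortex()].
#' @param lacuna_threshold canal/lacuna volume boundary, um^3.
#' @param min_segment_length minimum segment chord length, voxels.
#' @param center_xy optional `(x, y)` override of the bone axis position in
#'   um; if `NULL` the centre is estimated from the periosteal boundary.
#' @param r2_mm optional calliper mid-shaft radius, mm; if `NULL` it is
#'   estimated by circle fit (needs a full cross-section).
#' @param exclusion optional path to an exclusion-mask TIFF (e.g. medullary
#'   bone) or a [binary_volume()].
#' @param specimen_id,species,bone,age_days identifying metadata.
#' @param seed integer seed recorded in the manifest (the per-specimen
#'   pipeline itself is deterministic).
#' @param out_dir output directory; `NULL` disables file output.
#' @param write_masks also write segmentation masks as TIFF.
#' @return list of class `run_config`.
#' @export
run_config <- function(voxel_size = 1.6, closing_radius = 8,
                       lacuna_threshold = 1000, min_segment_length = 3,
                       center_xy = NULL, r2_mm = NULL, exclusion = NULL,
                       specimen_id = NA, species = NA, bone = NA,
                       age_days = NA, seed = 1L, out_dir = NULL,
                       write_masks = FALSE) {
  if (voxel_size <= 0 || closing_radius <= 0 || min_segment_length <= 0)
    stop("physical parameters must be positive")
  if (lacuna_threshold < 0) stop("lacuna_threshold must be non-negative")
  structure(list(voxel_size = voxel_size, closing_radius = closing_radius,
                 lacuna_threshold = lacuna_threshold,
                 min_segment_length = min_segment_length,
                 center_xy = center_xy, r2_mm = r2_mm,
                 exclusion = exclusion, specimen_id = specimen_id,
                 species = species, bone = bone, age_days = age_days,
                 seed = as.integer(seed), out_dir = out_dir,
                 write_masks = write_masks),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals[intersect(names(vals),
                                     names(formals(run_config)))])
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s stage] %s", name, conditionMessage(e)), call. = FALSE))
}

config_hash <- function(config, extra = NULL) {
  payload <- list(config = config[setdiff(names(config), "exclusion")],
                  package_version = as.character(utils::packageVersion("bonevasc")),
                  extra = extra)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(payload, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Run the full per-specimen pipeline
#'
#' Executes segmentation, morphometry and orientation in order on one
#' grayscale cortex volume: Li thresholding, cortex closing, pore
#' extraction, canal/lacuna partition; porosity, canal and cortical
#' thickness, second moment of area; skeletonisation, segment decomposition
#' and length-weighted orientation indices. Identical inputs and config give
#' identical outputs (including byte-identical CSV files). Stage errors
#' propagate with the stage name; artefacts written before the failure are
#' retained.
#'
#' @param input a [grayscale_volume()] or the path of a multi-page TIFF.
#' @param config a [run_config()].
#' @return list of class `specimen_run`: `summary` (one row combining the
#'   morphometry and the orientation indices), `segments`, `indices`,
#'   `segmentation`, `frame`, `log`.
#' @export
run_specimen <- function(input, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  vol <- stage("input", {
    if (is.character(input)) read_volume_tiff(input, config$voxel_size)
    else if (inherits(input, "grayscale_volume")) input
    else stop("input must be a grayscale_volume or a TIFF path")
  })
  exclusion <- stage("input", {
    if (is.null(config$exclusion)) NULL
    else if (is.character(config$exclusion))
      read_mask_tiff(config$exclusion, config$voxel_size, "exclusion")
    else config$exclusion
  })

  out_dir <- config$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  seg <- stage("segmentation",
               segment_cortex(vol, closing_radius = config$closing_radius,
                              lacuna_threshold = config$lacuna_threshold,
                              exclusion = exclusion))
  if (!is.null(out_dir)) {
    comp <- seg$components
    write.csv(comp, file.path(out_dir, "pore_components.csv"),
              row.names = FALSE)
    if (isTRUE(config$write_masks)) {
      write_mask_tiff(seg$solid_cortex, file.path(out_dir, "solid_cortex.tif"))
      write_mask_tiff(seg$canals, file.path(out_dir, "canals.tif"))
      write_mask_tiff(seg$lacunae, file.path(out_dir, "lacunae.tif"))
    }
  }

  frame <- stage("orientation", {
    if (!is.null(config$center_xy)) bone_frame(config$center_xy)
    else estimate_center(seg$solid_cortex)
  })
  morpho <- stage("morphometry",
                  morphometry_summary(seg, r2_mm = config$r2_mm,
                                      specimen_id = config$specimen_id,
                                      species = config$species,
                                      bone = config$bone,
                                      age_days = config$age_days))
  segments <- stage("orientation", {
    skel <- skeletonize(seg$canals)
    extract_segments(skel, frame,
                     min_length = config$min_segment_length *
                       config$voxel_size)
  })
  indices <- stage("orientation", orientation_indices(segments))

  summary_row <- cbind(morpho, as.data.frame(indices))
  log <- list(threshold = seg$threshold,
              closing_radius = config$closing_radius,
              lacuna_threshold = config$lacuna_threshold,
              min_segment_length = config$min_segment_length,
              voxel_size = config$voxel_size,
              center_xy = frame$center,
              n_pore_components = nrow(seg$components),
              n_segments = indices$n_segments,
              seed = config$seed,
              manifest_hash = config_hash(config))

  if (!is.null(out_dir)) {
    write.csv(segments, file.path(out_dir, "segments.csv"),
              row.names = FALSE)
    write.csv(summary_row, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(summary = summary_row, segments = segments,
                 indices = indices, segmentation = seg, frame = frame,
                 log = log),
            class = "specimen_run")
}

#' @export
print.specimen_run <- function(x, ...) {
  cat("<specimen_run>\n")
  cat(sprintf("  porosity %.4f, canal thickness %.2f um, cortical thickness %.1f um\n",
              x$summary$porosity, x$summary$mean_canal_thickness_um,
              x$summary$cortical_thickness_um))
  print(x$indices)
  invisible(x)
}

#' Cross-specimen growth and microstructure statistics
#'
#' For each species x bone group with enough specimens, fits Gompertz growth
#' curves for bone length and mid-shaft diameter against age, derives the
#' growth-rate curves, the inflection age and the maximum rate, and
#' evaluates the radial (diametric) growth rate at each specimen's age.
#' Proportion outcomes (porosity and the four orientation indices, when
#' present) are then modelled by beta regression with a logit link against
#' age and against the radial growth rate, with likelihood-ratio p-values
#' and pseudo R-squared; unbounded outcomes (mean canal thickness, cortical
#' thickness) are correlated with the radial growth rate by Pearson's r.
#' Raw p-values are reported without multiple-testing correction; the
#' number of models is stated so readers can apply their own.
#'
#' @param specimens data.frame with columns `specimen_id`, `species`,
#'   `bone`, `age_days`, and any of `bone_length_mm`,
#'   `midshaft_diameter_mm`, `porosity`, `laminar_index`,
#'   `longitudinal_index`, `radial_index`, `oblique_index`,
#'   `mean_canal_thickness_um`, `cortical_thickness_um`.
#' @param min_specimens minimum number of distinct ages for a growth fit.
#' @return list of class `cohort_run`: `growth` (per-group fits and rate
#'   summaries), `specimens` (augmented with `radial_growth_rate` and
#'   `age_class`), `beta_models` (tidy model table), `correlations`,
#'   `n_models`.
#' @export
run_cohort <- function(specimens, min_specimens = 4) {
  req <- c("specimen_id", "species", "bone", "age_days")
  if (!all(req %in% names(specimens)))
    stop("specimens table must contain: ", paste(req, collapse = ", "))
  specimens$age_class <- unlist(Map(function(a, s)
    tryCatch(age_class(a, s), error = function(e) NA_character_),
    specimens$age_days, as.character(specimens$species)))

  groups <- unique(specimens[, c("species", "bone")])
  growth <- list()
  specimens$radial_growth_rate <- NA_real_
  for (gi in seq_len(nrow(groups))) {
    sel <- specimens$species == groups$species[gi] &
      specimens$bone == groups$bone[gi]
    sub <- specimens[sel, ]
    key <- paste(groups$species[gi], groups$bone[gi], sep = ".")
    fits <- list()
    for (response in c("bone_length_mm", "midshaft_diameter_mm")) {
      if (!response %in% names(sub)) next
      ok <- complete.cases(sub$age_days, sub[[response]])
      if (length(unique(sub$age_days[ok])) < min_specimens) {
        warning(sprintf("skipping %s %s: fewer than %d distinct ages", key,
                        response, min_specimens))
        next
      }
      fit <- tryCatch(fit_gompertz(sub$age_days[ok], sub[[response]][ok]),
                      error = function(e) {
                        warning(sprintf("skipping %s %s: %s", key, response,
                                        conditionMessage(e)))
                        NULL
                      })
      if (is.null(fit)) next
      fits[[response]] <- list(fit = fit, t_infl = fit$t_infl,
                               max_rate = fit$max_rate)
    }
    if (!is.null(fits$midshaft_diameter_mm))
      specimens$radial_growth_rate[sel] <-
        growth_rate(fits$midshaft_diameter_mm$fit, specimens$age_days[sel])
    growth[[key]] <- fits
  }

  prop_responses <- intersect(c("porosity", "laminar_index",
                                "longitudinal_index", "radial_index",
                                "oblique_index"), names(specimens))
  covariates <- c("age_days", "radial_growth_rate")
  beta_rows <- list()
  for (gi in seq_len(nrow(groups))) {
    sub <- specimens[specimens$species == groups$species[gi] &
                       specimens$bone == groups$bone[gi], ]
    for (resp in prop_responses) {
      for (cv in covariates) {
        d <- sub[complete.cases(sub[[resp]], sub[[cv]]), ]
        if (nrow(d) < min_specimens || sd(d[[cv]]) == 0) next
        row <- tryCatch({
          full <- beta_reg(stats::reformulate(cv, resp), d)
          null <- beta_reg(stats::reformulate("1", resp), d)
          lt <- lr_test(full, null)
          data.frame(species = groups$species[gi], bone = groups$bone[gi],
                     response = resp, covariate = cv,
                     slope = unname(coef(full)[2]),
                     lr_statistic = lt$statistic, p_value = lt$p.value,
                     pseudo_r2 = full$pseudo_r2, n = nrow(d))
        }, error = function(e) NULL)
        if (!is.null(row)) beta_rows[[length(beta_rows) + 1]] <- row
      }
    }
  }
  beta_models <- if (length(beta_rows)) do.call(rbind, beta_rows) else
    data.frame()

  cor_rows <- list()
  for (gi in seq_len(nrow(groups))) {
    sub <- specimens[specimens$species == groups$species[gi] &
                       specimens$bone == groups$bone[gi], ]
    for (resp in intersect(c("mean_canal_thickness_um",
                             "cortical_thickness_um"), names(sub))) {
      d <- sub[complete.cases(sub[[resp]], sub$radial_growth_rate), ]
      if (nrow(d) < 3) next
      row <- tryCatch({
        pr <- pearson_r(d$radial_growth_rate, d[[resp]])
        data.frame(species = groups$species[gi], bone = groups$bone[gi],
                   response = resp, covariate = "radial_growth_rate",
                   r = pr$r, p_value = pr$p.value, n = pr$n)
      }, error = function(e) NULL)
      if (!is.null(row)) cor_rows[[length(cor_rows) + 1]] <- row
    }
  }
  correlations <- if (length(cor_rows)) do.call(rbind, cor_rows) else
    data.frame()

  n_models <- nrow(beta_models) + nrow(correlations)
  message(sprintf(
    "run_cohort fitted %d statistical models; p-values are raw (no multiple-testing correction)",
    n_models))
  structure(list(growth = growth, specimens = specimens,
                 beta_models = beta_models, correlations = correlations,
                 n_models = n_models),
            class = "cohort_run")
}

#' @export
print.cohort_run <- function(x, ...) {
  cat(sprintf("<cohort_run> %d growth group(s), %d beta regression(s), %d correlation(s)\n",
              length(x$growth), nrow(x$beta_models), nrow(x$correlations)))
  for (key in names(x$growth)) {
    for (resp in names(x$growth[[key]])) {
      f <- x$growth[[key]][[resp]]
      cat(sprintf("  %s %s: max rate %.4g/day at %.1f days\n", key, resp,
                  f$max_rate, f$t_infl))
    }
  }
  invisible(x)
}
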