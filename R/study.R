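#' Median, interquartile range and data range of a group
#'
#' Quantiles use linear interpolation between order statistics (type 7).
#'
#' @param values nonempty numeric vector.
#' @return list with `median`, `iqr` (Q3 - Q1) and `data_range` (min, max).
#' @export
summarize_group <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("summarize_group: empty group")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], iqr = q[3] - q[1], data_range = range(values))
}

#' Synthetic study configuration
#'
#' Defines a cohort of synthetic animals mirroring the study design: four
#' treatment groups (control and three escalating cell doses), two occlusion
#' durations, a 48 h scan for every animal and an optional 9 d scan. Planted
#' speckle counts scale with dose as control 0, low 50, mid 300, high 1000.
#'
#' @param cohort optional data frame with columns `animal`, `group`
#'   (`"control"`, `"5e4"`, `"3e5"`, `"1e6"`), `occlusion_min` (45 or 90),
#'   `n_speckles`, `has_9d` (logical). Built automatically when `NULL`.
#' @param n_per_group animals per group for the automatic cohort.
#' @param two_timepoint_fraction fraction of each group given a 9 d scan
#'   (not every animal underwent both examinations).
#' @param out_dir output directory for [run_study()] tables.
#' @param seed study master seed; per-animal phantom seeds derive from it.
#' @param phantom named list of [phantom_config()] overrides shared by all
#'   animals (e.g. a smaller grid).
#' @param speckle a [speckle_config()].
#' @param norm_target normalization target mean.
#' @param poly_order bias-correction polynomial order.
#' @param write_nifti write per-animal volumes and masks as NIfTI.
#' @return list of class `study_config`.
#' @export
study_config <- function(cohort = NULL, n_per_group = 5L,
                         two_timepoint_fraction = 0.6,
                         out_dir = tempfile("vsoptrack_study_"), seed = 1L,
                         phantom = list(), speckle = speckle_config(),
                         norm_target = 1000, poly_order = 3L,
                         write_nifti = FALSE) {
  groups <- c(control = 0L, `5e4` = 50L, `3e5` = 300L, `1e6` = 1000L)
  if (is.null(cohort)) {
    rows <- list()
    for (g in names(groups)) {
      for (i in seq_len(n_per_group)) {
        rows[[length(rows) + 1L]] <- data.frame(
          animal = sprintf("%s_%02d", g, i), group = g,
          occlusion_min = if (i %% 2L == 0L) 90L else 45L,
          n_speckles = groups[[g]],
          has_9d = i <= ceiling(two_timepoint_fraction * n_per_group)
        )
      }
    }
    cohort <- do.call(rbind, rows)
  }
  stopifnot(all(c("animal", "group", "n_speckles", "has_9d") %in% names(cohort)))
  if (!all(cohort$group %in% names(groups))) {
    stop("study_config: group labels must be control, 5e4, 3e5 or 1e6")
  }
  structure(list(cohort = cohort, out_dir = out_dir, seed = as.integer(seed),
                 phantom = phantom, speckle = speckle,
                 norm_target = norm_target, poly_order = as.integer(poly_order),
                 write_nifti = write_nifti),
            class = "study_config")
}

# preprocess one session: brain extraction on T2, bias correction and
# normalization of both contrasts
preprocess_session <- function(t2, t2star, poly_order, norm_target,
                               affected_side = "right") {
  mask <- extract_brain(t2, affected_side = affected_side)
  t2c <- correct_bias(t2, mask, poly_order)$vol
  t2sc <- correct_bias(t2star, mask, poly_order)$vol
  list(mask = mask,
       t2 = normalize_mean(t2c, mask, norm_target),
       t2star = normalize_mean(t2sc, mask, norm_target))
}

#' Run the full synthetic study
#'
#' For every animal: generate the phantom (one or two timepoints), run
#' preprocessing (brain extraction, bias correction, mean normalization,
#' rigid re-alignment of the 9 d session), the delta-CSI statistic, infarct
#' volumetry (plus residual infarct where both timepoints exist), and the
#' T2* speckle re-analysis with longitudinal voxel-count comparison. Group
#' summaries (median, IQR, range) and pairwise Mann-Whitney comparisons
#' against the control group are tabulated for delta-CSI and infarct size.
#' Tables are written as CSV, the manifest and group comparisons as JSON.
#'
#' @param config a [study_config()].
#' @return list of class `study_report` with `animals` (per-animal table),
#'   `group_tables`, `comparisons`, `manifest` and per-animal `details`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- config$cohort
  details <- list()
  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(cohort))) {
    an <- cohort[i, ]
    pc_args <- c(list(n_speckles = an$n_speckles,
                      seed = config$seed + 1000L * i),
                 config$phantom[setdiff(names(config$phantom),
                                        c("n_speckles", "seed"))])
    pcfg <- do.call(phantom_config, pc_args)
    res <- tryCatch(
      run_one_animal(an, pcfg, config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      skipped[[an$animal]] <- conditionMessage(res)
      next
    }
    details[[an$animal]] <- res
    rows[[length(rows) + 1L]] <- res$row
  }
  animals <- do.call(rbind, rows)
  group_tables <- list()
  comparisons <- list()
  for (var in c("mean_dcsi", "infarct_pct", "voxel_count_48h")) {
    tab <- lapply(split(animals[[var]], animals$group), function(v) {
      v <- v[is.finite(v)]
      if (length(v) == 0L) return(NULL)
      s <- summarize_group(v)
      data.frame(n = length(v), median = s$median, iqr = s$iqr,
                 min = s$data_range[1], max = s$data_range[2])
    })
    tab <- do.call(rbind, tab)
    tab <- cbind(group = rownames(tab), tab)
    rownames(tab) <- NULL
    group_tables[[var]] <- tab
    ctrl <- animals[[var]][animals$group == "control"]
    ctrl <- ctrl[is.finite(ctrl)]
    cmp <- list()
    for (g in setdiff(unique(animals$group), "control")) {
      v <- animals[[var]][animals$group == g]
      v <- v[is.finite(v)]
      if (length(ctrl) == 0L || length(v) == 0L) next
      mw <- mann_whitney_u(ctrl, v)
      cmp[[g]] <- data.frame(variable = var, group = g, n_control = length(ctrl),
                             n_group = length(v), U = mw$U,
                             p_two_sided = mw$p_two_sided)
    }
    comparisons[[var]] <- do.call(rbind, cmp)
  }
  comparisons <- do.call(rbind, comparisons)
  rownames(comparisons) <- NULL

  utils::write.csv(animals, file.path(config$out_dir, "animals.csv"),
                   row.names = FALSE)
  for (var in names(group_tables)) {
    utils::write.csv(group_tables[[var]],
                     file.path(config$out_dir, paste0("group_", var, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(comparisons, file.path(config$out_dir, "comparisons.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = config$seed, n_animals = nrow(cohort),
    n_analysed = length(details), skipped = skipped,
    norm_target = config$norm_target, poly_order = config$poly_order,
    speckle = unclass(config$speckle),
    phantom_overrides = config$phantom,
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  structure(list(animals = animals, group_tables = group_tables,
                 comparisons = comparisons, manifest = manifest,
                 details = details, out_dir = config$out_dir),
            class = "study_report")
}

run_one_animal <- function(an, pcfg, config) {
  two_tp <- isTRUE(an$has_9d)
  if (two_tp) {
    pair <- generate_phantom_pair(pcfg)
    tp1 <- pair$tp1
  } else {
    tp1 <- generate_phantom(pcfg)
  }
  s1 <- preprocess_session(tp1$t2, tp1$t2star, config$poly_order,
                           config$norm_target, pcfg$affected_side)
  dcsi <- animal_delta_csi(s1$t2star, s1$mask,
                           lesion_mask = tp1$truth$lesion_mask)
  volu <- infarct_volumetry(s1$t2, s1$mask)
  map48 <- build_speckle_map(s1$t2star, s1$mask, config$speckle)

  row <- data.frame(
    animal = an$animal, group = an$group,
    occlusion_min = an$occlusion_min %||% NA,
    n_speckles = an$n_speckles,
    mean_dcsi = dcsi$mean_dcsi, sd_dcsi = dcsi$sd_dcsi,
    infarct_pct = volu$infarct_percent,
    lesion_mm3 = volu$lesion_volume_mm3,
    brain_mm3 = volu$brain_volume_mm3,
    voxel_count_48h = map48$voxel_count,
    voxel_count_9d = NA_real_, count_change_pct = NA_real_,
    residual_infarct_pct = NA_real_
  )
  det <- list(row = row, dcsi = dcsi, volumetry_48h = volu, map_48h = map48)

  if (two_tp) {
    reg <- register_rigid(pair$tp2$t2star, tp1$t2star)
    t2_9d <- apply_rigid(pair$tp2$t2, reg$transform)
    s2 <- preprocess_session(t2_9d, reg$resampled, config$poly_order,
                             config$norm_target, pcfg$affected_side)
    volu9 <- infarct_volumetry(s2$t2, s2$mask)
    map9 <- build_speckle_map(s2$t2star, s2$mask, config$speckle)
    cmpt <- compare_timepoints(map48, map9, transform = reg$transform,
                               match_tol_vox = config$speckle$match_tol_vox)
    row$voxel_count_9d <- map9$voxel_count
    row$count_change_pct <- cmpt$change_pct
    if (volu$lesion_volume_mm3 > 0) {
      row$residual_infarct_pct <- residual_percent(
        volu$lesion_volume_mm3, volu9$lesion_volume_mm3)$percent_of_48h
    }
    det$row <- row
    det$volumetry_9d <- volu9
    det$map_9d <- map9
    det$migration <- cmpt
    det$registration <- reg$transform
  }
  if (isTRUE(config$write_nifti)) {
    adir <- file.path(config$out_dir, an$animal)
    dir.create(adir, showWarnings = FALSE, recursive = TRUE)
    write_volume(s1$t2, file.path(adir, "t2_48h.nii.gz"))
    write_volume(s1$t2star, file.path(adir, "t2star_48h.nii.gz"))
    write_volume(with_data(s1$t2, volu$lesion_mask),
                 file.path(adir, "lesion_48h.nii.gz"))
    write_volume(with_data(s1$t2star, map48$hypo_mask),
                 file.path(adir, "hypo_48h.nii.gz"))
  }
  det
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d animals analysed (of %d), outputs in %s\n",
              x$manifest$n_analysed, x$manifest$n_animals, x$out_dir))
  invisible(x)
}

#' Read a study configuration from YAML
#'
#' A structured-text front end for [study_config()]: top-level keys mirror
#' its arguments, `cohort` is a list of records, `phantom` a mapping of
#' [phantom_config()] overrides.
#'
#' @param path YAML file.
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- NULL
  if (!is.null(y$cohort)) {
    cohort <- do.call(rbind, lapply(y$cohort, as.data.frame))
  }
  args <- y[setdiff(names(y), c("cohort", "speckle"))]
  args$cohort <- cohort
  if (!is.null(y$speckle)) args$speckle <- do.call(speckle_config, y$speckle)
  do.call(study_config, args)
}
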