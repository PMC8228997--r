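#' Configuration of an end-to-end pipeline run
#'
#' A run simulates flat mounts for a grid of groups and timepoints,
#' segments both vessel classes, quantifies densities, generates a
#' synthetic cohort table and produces the statistical report -- all
#' reproducible from this configuration and its seed.
#'
#' @param seed integer master seed; every image, mask and table derives
#'   from it.
#' @param out_dir output directory.
#' @param preset image preset, `"test"` (512 x 512) or `"fullsize"`.
#' @param groups,days grid of imaged conditions.
#' @param eyes_per_cell images per group x day cell.
#' @param noise_sd,artifact_count render settings (see [render_params()]).
#' @param n_seeds_by_group named list mapping group to limbal entry-point
#'   counts `c(lymphatic, blood)`; encodes that vessel ingrowth is
#'   strongest in allogeneic recipients.
#' @param cohort a [cohort_design()]; its seed, if unset, derives from
#'   `seed`.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("corneaquant_run_"),
                       preset = c("test", "fullsize"),
                       groups = c("syngeneic", "allogeneic"),
                       days = c(21), eyes_per_cell = 2,
                       noise_sd = 0.02, artifact_count = 5,
                       n_seeds_by_group = list(
                         naive = c(2, 4), syngeneic = c(6, 6),
                         allogeneic = c(14, 8)),
                       cohort = cohort_design(
                         effect_spec = ogvhd_effects())) {
  preset <- match.arg(preset)
  stopifnot(all(groups %in% names(n_seeds_by_group)))
  check_scalar_num(eyes_per_cell, "eyes_per_cell", min = 1)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 preset = preset, groups = groups, days = days,
                 eyes_per_cell = as.integer(eyes_per_cell),
                 noise_sd = noise_sd, artifact_count = artifact_count,
                 n_seeds_by_group = n_seeds_by_group, cohort = cohort),
            class = "run_config")
}

# small deterministic seed stream derived from the master seed
derive_seed <- function(seed, i) (as.integer(seed) * 7919L + i * 104729L) %% 2000000011L

#' Run the full pipeline
#'
#' Simulation, segmentation, quantification, cohort statistics. Writes,
#' under `config$out_dir`: per-eye images (TIFF), ROI JSON, ground-truth
#' and segmentation masks (PNG), `densities.csv`, `validation.csv` (Dice
#' against ground truth per eye and class), `cohort.csv`, `report.json`
#' (statistical results) and `run_metadata.json`.
#'
#' @param config a [run_config()].
#' @param mode one of `"full"`, `"simulate"` (images only), `"validate"`
#'   (images + segmentation + Dice/density tables), `"analyze"` (cohort
#'   statistics only).
#' @return (invisibly) a list with the tables produced.
#' @export
run_full <- function(config = run_config(), mode = c("full", "simulate",
                                                     "validate", "analyze")) {
  stopifnot(inherits(config, "run_config"))
  mode <- match.arg(mode)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  if (mode %in% c("full", "simulate", "validate")) {
    dens <- list(); val <- list()
    i <- 0L
    for (g in config$groups) for (d in config$days)
      for (e in seq_len(config$eyes_per_cell)) {
        i <- i + 1L
        eye_id <- sprintf("%s_d%02d_eye%02d", g, d, e)
        ns <- config$n_seeds_by_group[[g]]
        sim <- simulate_flat_mount(
          seed = derive_seed(config$seed, i), preset = config$preset,
          n_seeds_lymphatic = ns[1], n_seeds_blood = ns[2],
          noise_sd = config$noise_sd,
          artifact_count = config$artifact_count,
          meta = list(eye_id = eye_id, group = g, day = d))
        write_image(sim$image, file.path(config$out_dir,
                                         paste0(eye_id, ".tif")))
        write_roi(sim$roi, file.path(config$out_dir,
                                     paste0(eye_id, "_roi.json")))
        write_mask(sim$gt$lymphatic_mask,
                   file.path(config$out_dir, paste0(eye_id, "_gt_lymph.png")))
        write_mask(sim$gt$blood_mask,
                   file.path(config$out_dir, paste0(eye_id, "_gt_blood.png")))
        if (mode == "simulate") next
        shape <- dim(sim$image$pixels)[1:2]
        pp <- function(cls) pipeline_params(
          vessel_class = cls,
          preset = if (config$preset == "test") "test" else "fullsize")
        seg_l <- segment_vessels(sim$image, sim$roi, pp("lymphatic"))
        seg_b <- segment_vessels(sim$image, sim$roi, pp("blood"))
        write_mask(seg_l$mask,
                   file.path(config$out_dir, paste0(eye_id, "_seg_lymph.png")))
        write_mask(seg_b$mask,
                   file.path(config$out_dir, paste0(eye_id, "_seg_blood.png")))
        dens[[i]] <- density_record(eye_id, g, d, seg_l, seg_b, sim$roi,
                                    shape,
                                    pixel_size_um = sim$image$pixel_size_um)
        val[[i]] <- data.frame(
          eye_id = eye_id,
          dice_lymphatic = dice(seg_l$mask, sim$gt$lymphatic_mask),
          dice_blood = dice(seg_b$mask, sim$gt$blood_mask),
          true_lymphatic_pct = sim$gt$true_density_pct[["lymphatic"]],
          true_blood_pct = sim$gt$true_density_pct[["blood"]],
          stringsAsFactors = FALSE)
      }
    if (mode != "simulate") {
      out$densities <- do.call(rbind, dens)
      out$validation <- do.call(rbind, val)
      write.csv(out$densities, file.path(config$out_dir, "densities.csv"),
                row.names = FALSE)
      write.csv(out$validation, file.path(config$out_dir, "validation.csv"),
                row.names = FALSE)
    }
  }
  if (mode %in% c("full", "analyze")) {
    design <- config$cohort
    if (is.null(design$seed)) design$seed <- derive_seed(config$seed, 9999L)
    cohort <- generate_cohort(design)
    write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
              row.names = FALSE)
    out$cohort <- cohort
    out$report <- analyze_cohort(cohort)
    jsonlite::write_json(out$report,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  meta <- list(seed = config$seed, preset = config$preset,
               groups = config$groups, days = config$days,
               eyes_per_cell = config$eyes_per_cell,
               noise_sd = config$noise_sd,
               artifact_count = config$artifact_count,
               package_version =
                 as.character(utils::packageVersion("corneaquant")))
  jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' Statistical report on a cohort table
#'
#' The standard nonparametric workflow: a Kolmogorov-Smirnov normality
#' screen per variable (advisory), per-timepoint pairwise Mann-Whitney
#' group comparisons of every outcome, a Friedman test (with Bonferroni
#' post hoc) across timepoints within each group, and Pearson
#' correlations of the vessel densities with the clinical scores.
#'
#' @param cohort long-format cohort table ([generate_cohort()] format).
#' @return a nested list (JSON-serializable) of test results.
#' @export
analyze_cohort <- function(cohort) {
  vars <- intersect(cohort_variables()$variable, names(cohort))
  res <- list()
  res$normality <- lapply(setNames(vars, vars), function(v) {
    r <- ks_normality(cohort[[v]], comparison = v)
    list(D = r$statistic, p_value = r$p_value)
  })
  res$group_comparisons <- lapply(setNames(vars, vars), function(v)
    compare_groups(cohort, v))
  # Friedman across days within each group (eyes matched by cell index)
  res$time_course <- list()
  for (g in unique(cohort$group)) {
    sub <- cohort[cohort$group == g, ]
    days <- sort(unique(sub$day))
    if (length(days) < 2) next
    for (v in c("lymphatic_density_pct", "gvhd_score")) {
      if (!v %in% vars) next
      m <- vapply(days, function(d) sub[[v]][sub$day == d],
                  numeric(sum(sub$day == days[1])))
      colnames(m) <- paste0("d", days)
      fr <- friedman_test(m, comparison = sprintf("%s: %s over time", g, v))
      res$time_course[[paste(g, v, sep = ".")]] <-
        list(chisq = fr$statistic, p_value = fr$p_value,
             posthoc = friedman_posthoc(m))
    }
  }
  res$correlations <- list()
  for (dv in c("lymphatic_density_pct", "blood_density_pct")) {
    for (sv in c("gvhd_score", "fluorescein_grade")) {
      if (!all(c(dv, sv) %in% vars)) next
      r <- pearson_corr(cohort[[dv]], cohort[[sv]],
                        comparison = paste(dv, "vs", sv))
      res$correlations[[paste(dv, sv, sep = ".")]] <-
        list(r = r$effect_size, category = r$category, p_value = r$p_value)
    }
  }
  res
}
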