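#' Outcome variables of the synthetic cohort
#'
#' Base distribution of each per-eye outcome: latent normal location and
#' scale, the declared range, and whether values are integer scores.
#' Rows define the variables an `effect_spec` may shift.
#'
#' @return data frame with columns `variable`, `mean`, `sd`, `lo`, `hi`,
#'   `integer`.
#' @export
cohort_variables <- function() {
  data.frame(
    variable = c("gvhd_score", "blepharitis_score", "fluorescein_grade",
                 "tear_mm", "lymphatic_density_pct", "blood_density_pct"),
    mean = c(0.5, 0.3, 0.5, 6, 1.5, 2.5),
    sd = c(0.8, 0.5, 0.7, 1.5, 0.5, 0.8),
    lo = c(0, 0, 0, 0, 0, 0),
    hi = c(10, 4, 5, Inf, 100, 100),
    integer = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Synthetic cohort design
#'
#' Describes a groups-by-timepoints study layout (bone marrow
#' transplantation recipients screened at baseline and days 7, 14, 21 and
#' 28) and the group-by-time location shifts imposed on each outcome
#' variable. The default of 10 eyes per group per timepoint corresponds to
#' 5 mice with both eyes scored, the upper end of typical cohort sizes in
#' this model.
#'
#' @param groups character vector of group labels.
#' @param timepoints numeric vector of days post transplantation (0 =
#'   baseline).
#' @param n_per_group eyes per group per timepoint (>= 3).
#' @param effect_spec `NULL` (all groups exchangeable) or a data frame
#'   with columns `variable`, `group`, `day`, `shift`: the latent mean of
#'   `variable` is shifted by `shift` in that group at that day. See
#'   [effect_spec()].
#' @param seed RNG seed.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(groups = c("naive", "syngeneic", "allogeneic"),
                          timepoints = c(0, 7, 14, 21, 28),
                          n_per_group = 10, effect_spec = NULL,
                          seed = NULL) {
  stopifnot(is.character(groups), length(groups) >= 1,
            is.numeric(timepoints), length(timepoints) >= 1)
  check_scalar_num(n_per_group, "n_per_group", min = 3)
  vars <- cohort_variables()
  if (!is.null(effect_spec)) {
    req <- c("variable", "group", "day", "shift")
    if (!is.data.frame(effect_spec) || !all(req %in% names(effect_spec)))
      stopf("effect_spec must be a data frame with columns %s",
            paste(req, collapse = ", "))
    bad <- setdiff(unique(effect_spec$variable), vars$variable)
    if (length(bad))
      stopf("effect_spec names unknown variable(s): %s",
            paste(bad, collapse = ", "))
    bad <- setdiff(unique(effect_spec$group), groups)
    if (length(bad))
      stopf("effect_spec names unknown group(s): %s",
            paste(bad, collapse = ", "))
  }
  structure(list(groups = groups, timepoints = timepoints,
                 n_per_group = as.integer(n_per_group),
                 effect_spec = effect_spec, seed = seed),
            class = "cohort_design")
}

#' Build an effect specification
#'
#' @param variable outcome variable name (see [cohort_variables()] column
#'   `variable`).
#' @param group group label the shift applies to.
#' @param day timepoint(s) the shift applies to.
#' @param shift latent-mean shift, in the variable's units.
#' @return data frame suitable for [cohort_design()]'s `effect_spec`;
#'   multiple specs can be combined with `rbind()`.
#' @export
effect_spec <- function(variable, group, day, shift) {
  data.frame(variable = variable, group = group, day = day, shift = shift,
             stringsAsFactors = FALSE)
}

#' Disease-course effect preset
#'
#' A stylized ocular GVHD course for the allogeneic group: corneal
#' epitheliopathy and systemic score rising from day 14, blepharitis from
#' day 7, and a lymphatic-density increase confined to days 21 and 28 (the
#' window where lymphangiogenesis separates allogeneic from syngeneic
#' recipients), expressed in units of the baseline standard deviation via
#' `sd_units`.
#'
#' @param sd_units effect size of the late lymphatic-density shift, in
#'   pooled baseline standard deviations (default 1.5).
#' @return an `effect_spec` data frame.
#' @export
ogvhd_effects <- function(sd_units = 1.5) {
  v <- cohort_variables()
  sd_of <- function(name) v$sd[v$variable == name]
  rbind(
    effect_spec("lymphatic_density_pct", "allogeneic", c(21, 28),
                sd_units * sd_of("lymphatic_density_pct")),
    effect_spec("gvhd_score", "allogeneic", c(14, 21, 28), c(2, 4, 4)),
    effect_spec("fluorescein_grade", "allogeneic", c(14, 21, 28), c(1.5, 2, 2)),
    effect_spec("blepharitis_score", "allogeneic", c(7, 14, 21, 28),
                c(0.5, 1, 2, 2)),
    effect_spec("tear_mm", "allogeneic", c(7, 28), c(1.5, -1.5)))
}

#' Generate a synthetic cohort table
#'
#' Draws per-eye outcomes for every group-by-timepoint cell of the design:
#' systemic GVHD score (0-10), blepharitis score (0-4), fluorescein grade
#' (0-5), tear-thread wetting length (mm), and lymphatic/blood vessel
#' densities (percent of cornea area). Scores are integers obtained by
#' rounding and clamping a latent normal draw; densities are clamped to
#' `[0, 100]`. With a `NULL` `effect_spec` all groups are exchangeable at
#' every timepoint.
#'
#' @param design a [cohort_design()].
#' @return long-format data frame with one row per eye per timepoint and
#'   columns `eye_id`, `group`, `day` plus the outcome variables.
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  vars <- cohort_variables()
  es <- design$effect_spec
  with_seed(design$seed, {
    cells <- expand.grid(group = design$groups, day = design$timepoints,
                         stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      g <- cells$group[i]; d <- cells$day[i]; n <- design$n_per_group
      out <- data.frame(
        eye_id = sprintf("%s_d%02d_eye%02d", g, d, seq_len(n)),
        group = g, day = d, stringsAsFactors = FALSE)
      for (j in seq_len(nrow(vars))) {
        v <- vars[j, ]
        shift <- 0
        if (!is.null(es)) {
          sel <- es$variable == v$variable & es$group == g & es$day == d
          if (any(sel)) shift <- sum(es$shift[sel])
        }
        x <- rnorm(n, v$mean + shift, v$sd)
        if (v$integer) x <- round(x)
        x <- pmin(pmax(x, v$lo), v$hi)
        out[[v$variable]] <- x
      }
      out
    })
    do.call(rbind, rows)
  })
}
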