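#' Clinical score panel for one eye/animal
#'
#' Sub-scores of the systemic GVHD assessment (weight loss, posture,
#' activity, skin and fur condition, each graded 0-2), the blepharitis
#' assessment (lid swelling and periocular fur loss, each 0-2), the
#' corneal fluorescein staining grade (0-5) and the phenol-red-thread
#' tear measurement in mm.
#'
#' @param weight_loss,posture,activity,skin,fur integers 0-2.
#' @param lid_swelling,fur_loss_periocular integers 0-2.
#' @param fluorescein_grade integer 0-5.
#' @param tear_mm thread wetting length in mm, >= 0.
#' @return an object of class `score_panel`.
#' @export
score_panel <- function(weight_loss = 0, posture = 0, activity = 0,
                        skin = 0, fur = 0, lid_swelling = 0,
                        fur_loss_periocular = 0, fluorescein_grade = 0,
                        tear_mm = 0) {
  chk <- function(x, name, hi) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        x != as.integer(x) || x < 0 || x > hi)
      stopf("'%s' must be an integer in 0..%d", name, hi)
    as.integer(x)
  }
  check_scalar_num(tear_mm, "tear_mm", min = 0)
  structure(list(
    weight_loss = chk(weight_loss, "weight_loss", 2L),
    posture = chk(posture, "posture", 2L),
    activity = chk(activity, "activity", 2L),
    skin = chk(skin, "skin", 2L),
    fur = chk(fur, "fur", 2L),
    lid_swelling = chk(lid_swelling, "lid_swelling", 2L),
    fur_loss_periocular = chk(fur_loss_periocular, "fur_loss_periocular", 2L),
    fluorescein_grade = chk(fluorescein_grade, "fluorescein_grade", 5L),
    tear_mm = tear_mm), class = "score_panel")
}

#' Systemic GVHD score
#'
#' Sum of the five 0-2 sub-scores (weight loss, posture, activity, skin,
#' fur), giving a 0-10 scale. A total of 6 or more triggers the humane
#' stop criterion.
#'
#' @param panel a [score_panel()].
#' @return list with integer `score` (0-10) and logical `stop` (TRUE when
#'   `score >= 6`).
#' @export
gvhd_score <- function(panel) {
  stopifnot(inherits(panel, "score_panel"))
  s <- panel$weight_loss + panel$posture + panel$activity + panel$skin +
    panel$fur
  list(score = s, stop = s >= 6L)
}

#' Blepharitis score
#'
#' Sum of lid swelling and periocular fur loss (each 0-2), giving a 0-4
#' scale.
#'
#' @param panel a [score_panel()].
#' @return integer score 0-4.
#' @export
blepharitis_score <- function(panel) {
  stopifnot(inherits(panel, "score_panel"))
  panel$lid_swelling + panel$fur_loss_periocular
}

#' Relative expression by the comparative-threshold (delta-delta-Ct) method
#'
#' Per sample, `dCt = mean(ct_target) - mean(ct_reference)` over the
#' triplicate wells; `ddCt = dCt - mean(dCt of the control group)`; fold
#' change `2^(-ddCt)`. In the reference workflow the target is VEGF-C,
#' the endogenous reference gene HPRT, and the naive group the control.
#'
#' @param samples data frame with columns `sample_id`, `group`, and list
#'   or numeric columns `ct_target` and `ct_reference` (each a triplicate
#'   of Ct values, or a single mean Ct).
#' @param control_group group label used as calibrator (default
#'   `"naive"`).
#' @return the input with added columns `d_ct`, `dd_ct` and
#'   `fold_change`.
#' @export
relative_expression <- function(samples, control_group = "naive") {
  stopifnot(is.data.frame(samples),
            all(c("group", "ct_target", "ct_reference") %in% names(samples)))
  mean_ct <- function(col) vapply(col, function(x) {
    x <- unlist(x)
    if (length(x) == 0 || anyNA(x)) stopf("missing Ct values")
    if (any(x <= 0)) stopf("Ct values must be positive")
    mean(x)
  }, numeric(1))
  d_ct <- mean_ct(samples$ct_target) - mean_ct(samples$ct_reference)
  ctrl <- samples$group == control_group
  if (!any(ctrl)) stopf("control group '%s' is empty", control_group)
  dd_ct <- d_ct - mean(d_ct[ctrl])
  samples$d_ct <- d_ct
  samples$dd_ct <- dd_ct
  samples$fold_change <- 2^(-dd_ct)
  samples
}
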