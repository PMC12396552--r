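# Paired baseline -> year-1 change rates, Slow/Rapid Loser stratification at
# the published per-zone thresholds, and Grower x Loser quadrant labels.

#' Per-visit summary feeding change computation
#'
#' A minimal, modality-agnostic view of one eye-visit: total GA area,
#' intact area in each zone, and the integrity index in each zone. Built
#' directly or from an [compute_mtii()] / [compute_ezii()] result via
#' [as_visit_result()].
#'
#' @param participant_id Participant identifier.
#' @param modality `"FAF"` or `"OCT"`.
#' @param ga GA area, mm^2.
#' @param intact_1,intact_3 Intact area per zone, mm^2.
#' @param index_1,index_3 Integrity index per zone, percent.
#' @return An object of class `visit_result`.
#' @export
visit_result <- function(participant_id, modality, ga, intact_1, intact_3,
                         index_1, index_3) {
  modality <- match.arg(modality, c("FAF", "OCT"))
  structure(
    list(participant_id = as.character(participant_id), modality = modality,
         ga = ga, intact_1 = intact_1, intact_3 = intact_3,
         index_1 = index_1, index_3 = index_3),
    class = "visit_result"
  )
}

#' Convert an index result to a visit_result
#'
#' @param x An `mtii_result` or `ezii_result`.
#' @param participant_id Participant identifier.
#' @param ga_area GA area override in mm^2; required for `ezii_result`
#'   objects that carry no OCT GA mask.
#' @return A [visit_result()].
#' @export
as_visit_result <- function(x, participant_id, ga_area = NULL) {
  if (inherits(x, "mtii_result")) {
    visit_result(participant_id, "FAF", ga = ga_area %||% x$ga_total,
                 intact_1 = x$intact_1, intact_3 = x$intact_3,
                 index_1 = x$mtii_1, index_3 = x$mtii_3)
  } else if (inherits(x, "ezii_result")) {
    ga <- ga_area %||% x$ga_area_oct
    visit_result(participant_id, "OCT", ga = ga,
                 intact_1 = x$ez_area_1, intact_3 = x$ez_area_3,
                 index_1 = x$ezii_1, index_3 = x$ezii_3)
  } else {
    stop("cannot convert object of class ", class(x)[1], call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Annualized change between two visits
#'
#' Signs follow the clinical convention: positive `ga_growth` means lesion
#' enlargement, positive `intact_loss` / `index_loss` means tissue decline.
#'
#' @param baseline,year1 Two [visit_result()]s for the same participant and
#'   modality.
#' @param interval_years Time between visits in years (> 0, default 1).
#' @return An object of class `change_record` with fields `ga_growth`,
#'   `intact_loss_1`, `intact_loss_3` (mm^2/yr) and `index_change_1`,
#'   `index_change_3` (percentage points/yr).
#' @export
compute_change <- function(baseline, year1, interval_years = 1) {
  stopifnot(inherits(baseline, "visit_result"), inherits(year1, "visit_result"))
  if (baseline$participant_id != year1$participant_id)
    stop("participant mismatch: ", baseline$participant_id, " vs ",
         year1$participant_id, call. = FALSE)
  if (baseline$modality != year1$modality)
    stop("modality mismatch", call. = FALSE)
  if (!is.finite(interval_years) || interval_years <= 0)
    stop("interval_years must be > 0", call. = FALSE)
  structure(
    list(
      participant_id = baseline$participant_id,
      modality = baseline$modality,
      ga_growth = (year1$ga - baseline$ga) / interval_years,
      intact_loss_1 = (baseline$intact_1 - year1$intact_1) / interval_years,
      intact_loss_3 = (baseline$intact_3 - year1$intact_3) / interval_years,
      index_change_1 = (baseline$index_1 - year1$index_1) / interval_years,
      index_change_3 = (baseline$index_3 - year1$index_3) / interval_years
    ),
    class = "change_record"
  )
}

#' Slow/Rapid Loser stratification
#'
#' Classifies an eye's annual central-tissue loss against the per-zone,
#' per-modality thresholds: 0.10 (1-mm) and 0.75 (3-mm) mm^2/year for FAF
#' intact area, 0.04 and 0.49 mm^2/year for OCT intact-EZ area. A loss rate
#' exactly at the threshold is a Slow Loser (the boundary belongs to the
#' slow stratum).
#'
#' @param loss_rate Annual intact-area loss in mm^2/yr.
#' @param zone `"z1mm"` or `"z3mm"`.
#' @param modality `"FAF"` or `"OCT"`.
#' @param thresholds Named threshold table as in
#'   `default_config()$loser_thresholds`.
#' @return An object of class `stratum_label` with fields `zone`,
#'   `modality`, `label` (`"SlowLoser"` or `"RapidLoser"`).
#' @export
classify_loser <- function(loss_rate, zone = c("z1mm", "z3mm"),
                           modality = c("FAF", "OCT"),
                           thresholds = default_config()$loser_thresholds) {
  zone <- match.arg(zone)
  modality <- match.arg(modality)
  thr <- thresholds[[modality]][[zone]]
  if (is.null(thr) || !is.finite(thr))
    stop("no threshold for ", modality, "/", zone, call. = FALSE)
  structure(
    list(zone = zone, modality = modality,
         label = if (loss_rate <= thr) "SlowLoser" else "RapidLoser"),
    class = "stratum_label"
  )
}

#' Grower x Loser quadrant label
#'
#' Combines the overall GA growth rate (split at the cohort median; an eye
#' at or below the median is a Slow Grower) with the Slow/Rapid Loser label
#' for central-tissue loss. The four quadrants describe the heterogeneous
#' progression patterns: eyes may grow fast overall while losing little
#' central tissue, and vice versa.
#'
#' @param ga_growth This eye's GA growth rate, mm^2/yr.
#' @param central_loss This eye's central intact-area loss rate, mm^2/yr.
#' @param cohort Non-empty list of [compute_change()] records supplying the
#'   growth median, or a numeric vector of cohort growth rates.
#' @param zone,modality Passed to [classify_loser()].
#' @param grower_cutoff Optional absolute growth cutoff in mm^2/yr; when
#'   given it replaces the cohort-median split.
#' @param thresholds Loser thresholds (see [classify_loser()]).
#' @return An object of class `quadrant_label` with field `label`, one of
#'   `"RapidGrowerSlowLoser"`, `"RapidGrowerRapidLoser"`,
#'   `"SlowGrowerSlowLoser"`, `"SlowGrowerRapidLoser"`.
#' @export
classify_quadrant <- function(ga_growth, central_loss, cohort,
                              zone = "z1mm", modality = c("FAF", "OCT"),
                              grower_cutoff = NULL,
                              thresholds = default_config()$loser_thresholds) {
  modality <- match.arg(modality)
  if (is.null(grower_cutoff)) {
    growths <- if (is.numeric(cohort)) cohort
               else vapply(cohort, function(r) r$ga_growth, numeric(1))
    if (length(growths) == 0L)
      stop("cohort must be non-empty to define the growth median",
           call. = FALSE)
    grower_cutoff <- stats::median(growths)
  }
  grower <- if (ga_growth <= grower_cutoff) "SlowGrower" else "RapidGrower"
  loser <- classify_loser(central_loss, zone, modality, thresholds)$label
  structure(list(label = paste0(grower, loser)), class = "quadrant_label")
}

#' Change table for a cohort
#'
#' Applies [compute_change()] across paired visit results and returns a tidy
#' per-eye table of annualized rates.
#'
#' @param baseline,year1 Lists of [visit_result()]s matched by position.
#' @param interval_years Visit spacing in years.
#' @return A data.frame with one row per eye.
#' @export
change_table <- function(baseline, year1, interval_years = 1) {
  stopifnot(length(baseline) == length(year1))
  recs <- Map(compute_change, baseline, year1,
              MoreArgs = list(interval_years = interval_years))
  do.call(rbind, lapply(recs, function(r)
    data.frame(participant_id = r$participant_id, modality = r$modality,
               ga_growth = r$ga_growth,
               intact_loss_1 = r$intact_loss_1,
               intact_loss_3 = r$intact_loss_3,
               index_change_1 = r$index_change_1,
               index_change_3 = r$index_change_3)))
}
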