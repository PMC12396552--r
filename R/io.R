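# Readers and writers for the pipeline's file formats: single-channel
# PNG/TIFF masks, JSON sidecar calibration, per-B-scan intact-EZ interval
# tables, cohort visit tables, tidy result tables, and YAML configuration.
# Readers validate and reject rather than silently coerce.

.modalities <- c("FAF", "OCT_ENFACE")
.eyes <- c("OD", "OS")
.visits <- c("baseline", "year1")

#' Sidecar metadata for an en-face mask
#'
#' Physical calibration and anatomical anchor accompanying every mask file:
#' pixel scale in mm/px and the fovea center in pixel indices (zero-based).
#' The fovea pixel (i, j) maps to the millimetre point
#' ((i + 0.5) scale_x, (j + 0.5) scale_y), the center of that pixel.
#'
#' @param scale_x,scale_y Pixel size in mm/px (> 0).
#' @param fovea_x,fovea_y Fovea center in pixels (zero-based indices).
#' @param modality One of `"FAF"`, `"OCT_ENFACE"`.
#' @param eye One of `"OD"`, `"OS"`.
#' @param visit One of `"baseline"`, `"year1"`.
#' @return An object of class `sidecar_meta`.
#' @export
sidecar_meta <- function(scale_x, scale_y, fovea_x, fovea_y,
                         modality = "FAF", eye = "OD", visit = "baseline") {
  if (!is.finite(scale_x) || !is.finite(scale_y) || scale_x <= 0 || scale_y <= 0)
    stop("sidecar scales must be finite and > 0", call. = FALSE)
  if (!is.finite(fovea_x) || !is.finite(fovea_y) || fovea_x < 0 || fovea_y < 0)
    stop("fovea coordinates must be finite and >= 0", call. = FALSE)
  modality <- match.arg(modality, .modalities)
  eye <- match.arg(eye, .eyes)
  visit <- match.arg(visit, .visits)
  structure(
    list(scale_x = as.numeric(scale_x), scale_y = as.numeric(scale_y),
         fovea_x = as.numeric(fovea_x), fovea_y = as.numeric(fovea_y),
         modality = modality, eye = eye, visit = visit),
    class = "sidecar_meta"
  )
}

#' Fovea center of a sidecar as a millimetre point
#'
#' @param meta A [sidecar_meta()].
#' @return A [point_mm()] at the center of the fovea pixel.
#' @export
fovea_point <- function(meta) {
  stopifnot(inherits(meta, "sidecar_meta"))
  point_mm((meta$fovea_x + 0.5) * meta$scale_x,
           (meta$fovea_y + 0.5) * meta$scale_y)
}

#' Write sidecar metadata as JSON
#'
#' @param meta A [sidecar_meta()].
#' @param path Output path.
#' @export
write_sidecar <- function(meta, path) {
  stopifnot(inherits(meta, "sidecar_meta"))
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read sidecar metadata from JSON
#'
#' @param path Path to a sidecar JSON file.
#' @return A validated [sidecar_meta()].
#' @export
read_sidecar <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("scale_x", "scale_y", "fovea_x", "fovea_y", "modality", "eye", "visit")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("sidecar is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sidecar_meta(x$scale_x, x$scale_y, x$fovea_x, x$fovea_y,
               x$modality, x$eye, x$visit)
}

#' Read a binary mask with its sidecar
#'
#' Accepts single-channel PNG or TIFF; any nonzero pixel is treated as
#' feature-present, which tolerates 8-bit vs 16-bit exports. The sidecar's
#' fovea must fall within the image bounds.
#'
#' @param path Path to the mask image (.png, .tif or .tiff).
#' @param sidecar Path to the JSON sidecar.
#' @return A list with elements `mask` ([binary_mask()]) and
#'   `meta` ([sidecar_meta()]).
#' @export
read_mask <- function(path, sidecar) {
  meta <- read_sidecar(sidecar)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L)
      stop("mask must be single-channel, got ", dim(img)[3], " channels",
           call. = FALSE)
    img <- img[, , 1]
  }
  g <- grid_spec(ncol(img), nrow(img), meta$scale_x, meta$scale_y)
  if (meta$fovea_x >= g$width_px || meta$fovea_y >= g$height_px)
    stop("sidecar fovea lies outside the image bounds", call. = FALSE)
  list(mask = binary_mask(img != 0, g), meta = meta)
}

#' Write a binary mask as a single-channel PNG or TIFF
#'
#' @param mask A [binary_mask()].
#' @param path Output path (.png, .tif or .tiff).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- matrix(as.numeric(mask$pixels), nrow = nrow(mask$pixels))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path),
    stop("unsupported mask format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Read per-B-scan intact-EZ intervals
#'
#' Expects a comma-separated file with header columns `scan_index`, `y_mm`,
#' `start_x_mm`, `end_x_mm`; each row is one intact-EZ run on one B-scan,
#' annotated left to right. Intervals are grouped by scan, sorted, and
#' validated: starts strictly before ends, no overlap within a scan.
#'
#' @param path Path to the CSV file.
#' @param x_extent Lateral extent of the scans in mm; defaults to the
#'   largest end coordinate present (0 for an empty table).
#' @return An `ez_map` (see [ez_map()]).
#' @export
read_ez_intervals <- function(path, x_extent = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_index", "y_mm", "start_x_mm", "end_x_mm")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("EZ interval table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(x_extent))
    x_extent <- if (nrow(d)) max(d$end_x_mm) else 0
  scans <- lapply(split(d, d$scan_index), function(s) {
    ez_scan_line(s$scan_index[1], s$y_mm[1],
                 cbind(s$start_x_mm, s$end_x_mm))
  })
  ez_map(unname(scans), x_extent = x_extent)
}

#' Write per-B-scan intact-EZ intervals
#'
#' @param map An `ez_map`.
#' @param path Output CSV path.
#' @export
write_ez_intervals <- function(map, path) {
  stopifnot(inherits(map, "ez_map"))
  rows <- lapply(map$scans, function(s) {
    if (nrow(s$intervals) == 0L) return(NULL)
    data.frame(scan_index = s$scan_index, y_mm = s$y,
               start_x_mm = s$intervals[, 1], end_x_mm = s$intervals[, 2])
  })
  d <- do.call(rbind, rows)
  if (is.null(d))
    d <- data.frame(scan_index = integer(), y_mm = numeric(),
                    start_x_mm = numeric(), end_x_mm = numeric())
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort visit table
#'
#' One row per (participant, visit). Required columns: `participant_id`,
#' `eye`, `visit`, `bcva_letters`, `llva_letters`, `ga_mask_path`. Optional:
#' `ez_intervals_path`, `rpd_present`, `focality`, `foveal_involvement`.
#' ETDRS letter scores must lie in [0, 100]. Duplicate (participant, visit)
#' pairs are rejected.
#'
#' @param path Path to the cohort CSV.
#' @return A data.frame of validated visit records, with attribute
#'   `complete_pairs`: the number of participants having both a baseline
#'   and a year1 record.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "eye", "visit", "bcva_letters", "llva_letters",
            "ga_mask_path")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("cohort table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!all(d$visit %in% .visits))
    stop("visit must be one of: ", paste(.visits, collapse = ", "),
         call. = FALSE)
  if (!all(d$eye %in% .eyes))
    stop("eye must be one of: ", paste(.eyes, collapse = ", "), call. = FALSE)
  for (col in c("bcva_letters", "llva_letters")) {
    v <- d[[col]]
    if (anyNA(v) || any(v < 0 | v > 100))
      stop(col, " must lie in [0, 100]", call. = FALSE)
  }
  key <- paste(d$participant_id, d$visit, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (participant, visit) record(s): ",
         paste(unique(d$participant_id[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  if ("focality" %in% names(d)) {
    ok <- is.na(d$focality) | d$focality %in% c("unifocal", "multifocal")
    if (!all(ok)) stop("focality must be unifocal or multifocal", call. = FALSE)
  }
  if ("foveal_involvement" %in% names(d)) {
    ok <- is.na(d$foveal_involvement) |
      d$foveal_involvement %in% c("subfoveal", "foveal_sparing")
    if (!all(ok))
      stop("foveal_involvement must be subfoveal or foveal_sparing",
           call. = FALSE)
  }
  tab <- table(d$participant_id)
  has_bl <- unique(d$participant_id[d$visit == "baseline"])
  has_y1 <- unique(d$participant_id[d$visit == "year1"])
  attr(d, "complete_pairs") <- length(intersect(has_bl, has_y1))
  d
}

#' Write results as a tidy long table
#'
#' One row per participant x zone x metric, for downstream regression.
#'
#' @param results A data.frame with at least columns `participant_id`,
#'   `zone`, `metric`, `value`.
#' @param path Output CSV path.
#' @export
write_results <- function(results, path) {
  need <- c("participant_id", "zone", "metric", "value")
  missing <- setdiff(need, names(results))
  if (length(missing))
    stop("results table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default analysis configuration
#'
#' Central knobs of the pipeline with their defaults: annotated FAF circle
#' diameters (1.2, 3.6 mm), nominal OCT circle diameters (1.0, 3.0 mm),
#' boundary supersampling, the lesion minimum-size criteria (250 um smallest
#' diameter or 0.05 mm^2 area), the central-tissue eligibility floor
#' (0.05 mm^2 intact within the small circle), and the Slow/Rapid Loser
#' thresholds per modality and zone in mm^2/year.
#'
#' @return A named list of configuration values.
#' @export
default_config <- function() {
  list(
    faf_diameters_mm = c(1.2, 3.6),
    oct_diameters_mm = c(1.0, 3.0),
    supersample = 8L,
    min_lesion_area_mm2 = 0.05,
    min_lesion_feret_um = 250,
    lesion_filter_rule = "or",
    eligibility_min_intact_mm2 = 0.05,
    loser_thresholds = list(
      FAF = c(z1mm = 0.10, z3mm = 0.75),
      OCT = c(z1mm = 0.04, z3mm = 0.49)
    ),
    seed = 1L
  )
}

#' Read a YAML configuration, filling unset keys with defaults
#'
#' @param path Path to a YAML file; keys override [default_config()].
#' @return A named configuration list.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  for (k in names(user)) cfg[[k]] <- user[[k]]
  if (cfg$supersample < 1L) stop("supersample must be >= 1", call. = FALSE)
  if (!cfg$lesion_filter_rule %in% c("or", "and"))
    stop("lesion_filter_rule must be 'or' or 'and'", call. = FALSE)
  cfg
}
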