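# Inter-grader agreement: signed paired differences in intact area between
# two independent gradings of the same images. The mean difference can be
# near zero while its SD reflects grading variability, which is why signed
# (not absolute) differences are used.

#' Paired-difference agreement statistics
#'
#' Differences are d_i = a_i - b_i over eyes graded by both readers; the
#' mean and sample SD of d are reported. Inputs are named numeric vectors
#' (names are participant keys) or plain vectors matched by position.
#'
#' @param grader_a,grader_b Per-eye areas (mm^2). If both are named, keys
#'   must match as sets and pairing is by key; unnamed vectors must have
#'   equal length and pair by position.
#' @param zone,modality Optional labels carried in the output.
#' @param bland_altman Also report 95% limits of agreement
#'   (mean +/- 1.96 SD).
#' @return An object of class `difference_stats` with fields `mean_diff`,
#'   `sd_diff`, `n`, `zone`, `modality` and, when requested, `loa_lower`,
#'   `loa_upper`.
#' @export
paired_difference_stats <- function(grader_a, grader_b, zone = NA_character_,
                                    modality = NA_character_,
                                    bland_altman = FALSE) {
  if (!is.null(names(grader_a)) && !is.null(names(grader_b))) {
    if (!setequal(names(grader_a), names(grader_b)))
      stop("participant keys differ between graders", call. = FALSE)
    grader_b <- grader_b[names(grader_a)]
  } else if (length(grader_a) != length(grader_b)) {
    stop("graders supplied different numbers of eyes", call. = FALSE)
  }
  d <- as.numeric(grader_a) - as.numeric(grader_b)
  n <- length(d)
  if (n < 1L) stop("no paired gradings", call. = FALSE)
  m <- mean(d)
  s <- if (n == 1L) 0 else stats::sd(d)
  out <- list(mean_diff = m, sd_diff = s, n = n, zone = zone,
              modality = modality)
  if (bland_altman) {
    out$loa_lower <- m - 1.96 * s
    out$loa_upper <- m + 1.96 * s
  }
  structure(out, class = "difference_stats")
}

#' @export
print.difference_stats <- function(x, ...) {
  cat(sprintf("grader agreement: mean difference %.3f mm^2 (SD %.3f), n = %d\n",
              x$mean_diff, x$sd_diff, x$n))
  if (!is.null(x$loa_lower))
    cat(sprintf("95%% limits of agreement: [%.3f, %.3f]\n",
                x$loa_lower, x$loa_upper))
  invisible(x)
}
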