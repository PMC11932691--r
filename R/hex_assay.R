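#' Fit a 4-MU standard curve
#'
#' Ordinary least-squares line through the standard wells
#' (fluorescence on 4-MU amount). At least three distinct standard
#' amounts are required and the fitted slope must be positive; a
#' warning is raised if the fit explains less than 98% of the
#' variance.
#'
#' @param concentration 4-MU amounts of the standard wells.
#' @param fluorescence measured fluorescence of the standard wells.
#' @return A `standard_curve` list: `slope`, `intercept`, `r_squared`.
#' @export
fit_standard_curve <- function(concentration, fluorescence) {
  stopifnot(length(concentration) == length(fluorescence))
  if (length(unique(concentration)) < 3)
    stop("standard curve needs at least 3 distinct concentrations",
         call. = FALSE)
  fit <- stats::lm(fluorescence ~ concentration)
  slope <- unname(stats::coef(fit)["concentration"])
  if (slope <= 0)
    stop("fitted standard-curve slope is not positive", call. = FALSE)
  ss_tot <- sum((fluorescence - mean(fluorescence))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  if (r2 < 0.98)
    warning(sprintf("standard curve R^2 = %.3f (< 0.98)", r2),
            call. = FALSE)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = r2),
            class = "standard_curve")
}

#' Convert sample fluorescence to enzyme activity
#'
#' Blank-corrects the mean replicate fluorescence, converts it to a
#' 4-MU amount through the standard curve, and divides by incubation
#' time and input amount, giving activity in 4-MU amount per minute
#' per input unit. Below-blank signals are clamped to zero activity
#' with a warning.
#'
#' @param fluorescence replicate fluorescence readings of one sample
#'   and substrate.
#' @param curve a [fit_standard_curve()] result.
#' @param blanks blank-well fluorescence readings (required).
#' @param time incubation time, minutes.
#' @param amount input amount per well (ug protein or ul plasma).
#' @return List: `activity`, `cv` (replicate coefficient of variation;
#'   NA with < 2 replicates), `n_replicates`, `clamped`.
#' @export
quantify_activity <- function(fluorescence, curve, blanks, time = 30,
                              amount = 2) {
  stopifnot(inherits(curve, "standard_curve"), time > 0, amount > 0)
  if (missing(blanks) || !length(blanks))
    stop("blank wells are required for blank correction", call. = FALSE)
  signal <- mean(fluorescence) - mean(blanks)
  clamped <- FALSE
  if (signal < 0) {
    warning("blank-corrected signal below zero; activity clamped to 0",
            call. = FALSE)
    signal <- 0
    clamped <- TRUE
  }
  product <- signal / curve$slope
  cv <- if (length(fluorescence) >= 2 && mean(fluorescence) > 0)
    stats::sd(fluorescence) / mean(fluorescence) else NA_real_
  list(activity = product / time / amount, cv = cv,
       n_replicates = length(fluorescence), clamped = clamped)
}

#' HEXB activity proxy
#'
#' The MUG substrate reports total Hex activity and MUGS the
#' HEXA-specific activity, so HEXB activity is proxied by their
#' difference; negative differences are biologically impossible and
#' are clamped to zero with a warning (a signal of assay failure).
#'
#' @param mug,mugs activities measured on the same sample.
#' @return HEXB proxy activity (>= 0).
#' @export
hexb_proxy <- function(mug, mugs) {
  if (is.na(mug) || is.na(mugs))
    stop("both MUG and MUGS activities are required", call. = FALSE)
  if (mugs > mug)
    warning("MUGS exceeds MUG; HEXB proxy clamped to 0", call. = FALSE)
  max(mug - mugs, 0)
}

#' Normalize activities within a plate to the plate controls
#'
#' Divides every activity by the mean (optionally median) activity of
#' the control samples on the same plate, yielding unitless relative
#' activity units comparable across plates.
#'
#' @param activities named numeric vector of per-sample activities on
#'   one plate.
#' @param control_ids sample ids of the plate controls.
#' @param center `"mean"` (default) or `"median"` of the controls.
#' @return Relative activities (controls average to 1 under
#'   `"mean"`).
#' @export
normalize_plate <- function(activities, control_ids,
                            center = c("mean", "median")) {
  center <- match.arg(center)
  ctrl <- activities[names(activities) %in% control_ids]
  if (!length(ctrl)) stop("no control samples on the plate", call. = FALSE)
  ref <- if (center == "mean") mean(ctrl) else stats::median(ctrl)
  if (!is.finite(ref) || ref <= 0)
    stop("control activities give a non-positive normalizer", call. = FALSE)
  activities / ref
}

#' Percent cell viability from absorbance readings
#'
#' Viability of treated cells relative to vehicle-treated cells after
#' blank subtraction.
#'
#' @param abs_treated,abs_vehicle,abs_blank absorbance readings.
#' @return `100 * (treated - blank) / (vehicle - blank)`.
#' @export
viability <- function(abs_treated, abs_vehicle, abs_blank) {
  if (any(abs_vehicle <= abs_blank))
    stop("vehicle absorbance must exceed blank absorbance", call. = FALSE)
  100 * (abs_treated - abs_blank) / (abs_vehicle - abs_blank)
}

#' Process a whole activity plate into per-sample results
#'
#' Runs the full assay chain on a plate table (layout as produced by
#' [generate_plate_readings()]): fits the 4-MU standard curve,
#' quantifies MUG and MUGS activity per sample from replicate wells,
#' forms the HEXB proxy, and normalizes to the plate controls.
#'
#' @param plate plate data.frame with columns `role`, `sample_id`,
#'   `substrate`, `replicate`, `concentration`, `fluorescence`,
#'   `is_control`.
#' @param time incubation time in minutes (default: plate attribute,
#'   else 30).
#' @param amount input amount per well (default: plate attribute,
#'   else 2).
#' @param center control centering for [normalize_plate()].
#' @return Data.frame: `sample_id`, `mug`, `mugs`, `hexb`, `cv_mug`,
#'   `cv_mugs`, `relative_mug`, `relative_hexb`, `is_control`;
#'   attribute `curve`.
#' @export
process_plate <- function(plate, time = NULL, amount = NULL,
                          center = "mean") {
  if (is.null(time)) time <- attr(plate, "time") %||% 30
  if (is.null(amount)) amount <- attr(plate, "amount") %||% 2
  std <- plate[plate$role == "standard", ]
  blanks <- plate$fluorescence[plate$role == "blank"]
  curve <- fit_standard_curve(std$concentration, std$fluorescence)
  samp <- plate[plate$role == "sample", ]
  ids <- unique(samp$sample_id)
  res <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    for (sub in c("MUG", "MUGS")) {
      w <- samp$fluorescence[samp$sample_id == ids[i] &
                               samp$substrate == sub]
      if (!length(w))
        stop("sample ", ids[i], " has no ", sub, " wells", call. = FALSE)
      q <- quantify_activity(w, curve, blanks, time, amount)
      res[i, tolower(sub)] <- q$activity
      res[i, paste0("cv_", tolower(sub))] <- q$cv
    }
    res[i, "hexb"] <- hexb_proxy(res$mug[i], res$mugs[i])
  }
  res$is_control <- samp$is_control[match(ids, samp$sample_id)]
  ctrl_ids <- ids[res$is_control %in% TRUE]
  mug <- stats::setNames(res$mug, res$sample_id)
  hexb <- stats::setNames(res$hexb, res$sample_id)
  res$relative_mug <- unname(normalize_plate(mug, ctrl_ids, center))
  res$relative_hexb <- unname(normalize_plate(hexb, ctrl_ids, center))
  attr(res, "curve") <- curve
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
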