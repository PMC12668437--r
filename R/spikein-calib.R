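#' Fit a qPCR standard curve from spiked calibrator wells
#'
#' Least-squares line `Ct = intercept + slope * log10(concentration)` over the
#' spike dilution series; the amplification efficiency follows from the slope
#' by `efficiency = 10^(-1/slope) - 1` (a slope of -3.32 cycles per decade is
#' 100 percent efficiency). Wells with missing Ct (no amplification) are
#' excluded from the fit.
#'
#' @param spikes data frame of spike wells with columns `known_conc_fM` and
#'   `Ct` (e.g. the `is_spike` rows of a [simulate_qpcr_plate()] plate).
#' @return object of class `standard_curve`: slope, intercept, efficiency,
#'   r_squared, n_points.
#' @export
fit_standard_curve <- function(spikes) {
  ok <- !is.na(spikes$Ct) & !is.na(spikes$known_conc_fM)
  spikes <- spikes[ok, , drop = FALSE]
  if (length(unique(spikes$known_conc_fM)) < 2L) {
    stop("need >= 2 distinct spike concentrations to fit a curve; ",
         "use single_point_delta_ct() for one-point calibration")
  }
  if (any(spikes$known_conc_fM <= 0)) stop("spike concentrations must be > 0")
  fit <- lm(Ct ~ log10(known_conc_fM), data = spikes)
  slope <- unname(coef(fit)[2L])
  if (slope >= 0) {
    stop("fitted slope is non-negative: dilution series appears inverted")
  }
  structure(list(slope = slope, intercept = unname(coef(fit)[1L]),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_points = nrow(spikes)),
            class = "standard_curve")
}

#' Convert a Ct value to absolute concentration
#'
#' `conc = 10^((ct - intercept) / slope)` in the units of the standard curve
#' (femtomolar throughout this package). A missing Ct means no amplification
#' and is reported as below detection (NA), never as zero.
#'
#' @param ct threshold cycle(s); may contain NA.
#' @param curve a [fit_standard_curve()] object.
#' @return concentration(s) in fM; NA where Ct is missing.
#' @export
ct_to_concentration <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  ifelse(is.na(ct), NA_real_, 10^((ct - curve$intercept) / curve$slope))
}

#' Single-point delta-Ct absolute quantification
#'
#' When only one spike concentration is available:
#' `conc = spike_conc * (1 + efficiency)^(spike_ct - sample_ct)`, i.e. each
#' cycle of separation corresponds to one (1+E)-fold difference in template.
#'
#' @param sample_ct,spike_ct threshold cycles (both required).
#' @param spike_conc known spike concentration (fM).
#' @param efficiency amplification efficiency; default 1 (perfect doubling).
#' @return concentration in fM.
#' @export
single_point_delta_ct <- function(sample_ct, spike_ct, spike_conc,
                                  efficiency = 1) {
  if (any(is.na(c(sample_ct, spike_ct)))) stop("both Ct values must be present")
  spike_conc * (1 + efficiency)^(spike_ct - sample_ct)
}

#' Fold change of calibrated concentrations versus control
#'
#' @param concentrations named numeric vector (or single-assay list) of
#'   concentrations by condition; must contain the `control` name.
#' @param control name of the control condition.
#' @return data frame (condition, conc_fM, fold_change); fold change is NA
#'   (flagged below detection) when the control concentration is missing, and
#'   an error is raised when it is zero or negative.
#' @export
fold_change_vs_control <- function(concentrations, control = "control") {
  if (!control %in% names(concentrations)) {
    stop("no '", control, "' condition among concentrations")
  }
  ref <- concentrations[[control]]
  if (is.na(ref)) {
    warning("control concentration below detection: fold changes undefined")
    fc <- rep(NA_real_, length(concentrations))
  } else {
    if (ref <= 0) stop("control concentration must be > 0")
    fc <- unname(concentrations) / ref
  }
  data.frame(condition = names(concentrations),
             conc_fM = unname(concentrations), fold_change = fc,
             stringsAsFactors = FALSE)
}
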