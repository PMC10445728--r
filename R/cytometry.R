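#' @title Flow-cytometry scalar metrics
#'
#' @description
#' Two background-corrected mean-fluorescence metrics used around the
#' proteomics experiment: the detergent resistance index (DRI), which
#' quantifies how much of a membrane marker's fluorescence survives Triton
#' X-100 extraction (1 = fully detergent-resistant, raft-like; 0 = fully
#' solubilized), and the surface-receptor internalization fraction over a
#' stimulation time course.
#'
#' @name cytometry
NULL

#' Detergent resistance index
#'
#' \deqn{DRI = (FL_{det} - FLBg_{det}) / (FL_{max} - FLBg)}
#' where `fl_det` is the fluorescence of detergent-treated labeled cells,
#' `flbg_det` the autofluorescence of detergent-treated unlabeled cells,
#' `fl_max` the fluorescence of labeled untreated cells, and `flbg` the
#' autofluorescence of unlabeled untreated cells. All inputs are mean
#' fluorescence values in arbitrary units. With noisy measurements the index
#' may fall outside \[0, 1\]; it is deliberately not clipped (an attribute
#' `out_of_range` flags such values).
#'
#' The index is invariant under a common rescaling of all four channels.
#'
#' @param fl_det,flbg_det,fl_max,flbg non-negative mean fluorescence values;
#'   vectors are accepted (one measurement set per element).
#' @return numeric DRI value(s) with logical attribute `out_of_range`.
#' @export
detergent_resistance_index <- function(fl_det, flbg_det, fl_max, flbg) {
  if (any(c(fl_det, flbg_det, fl_max, flbg) < 0)) {
    stop("fluorescence values must be non-negative")
  }
  if (any(fl_max <= flbg)) {
    stop("fl_max must exceed flbg (labeled cells brighter than background)")
  }
  dri <- (fl_det - flbg_det) / (fl_max - flbg)
  attr(dri, "out_of_range") <- dri < 0 | dri > 1
  dri
}

#' Summarize replicate DRI measurements
#'
#' @param measurements `data.frame` with columns `fl_det`, `flbg_det`,
#'   `fl_max`, `flbg` (one replicate per row).
#' @return list with per-replicate `dri`, plus `mean` and `sd`.
#' @export
dri_summary <- function(measurements) {
  dri <- detergent_resistance_index(measurements$fl_det,
                                    measurements$flbg_det,
                                    measurements$fl_max,
                                    measurements$flbg)
  list(dri = as.numeric(dri), mean = mean(dri), sd = stats::sd(dri),
       out_of_range = attr(dri, "out_of_range"))
}

#' Surface-receptor internalization fraction
#'
#' The background-corrected fraction of initially surface-labeled receptor
#' no longer detectable at the surface at time `t`:
#' \deqn{1 - (MFI(t) - bg) / (MFI(0) - bg)}
#' This is the standard surface-remaining complement; 0 at `t = 0`, 1 when
#' surface staining has decayed to background.
#'
#' @param surface_mfi_t surface mean fluorescence at time `t`.
#' @param surface_mfi_0 surface mean fluorescence at time 0 (cells kept on
#'   ice).
#' @param background_mfi unstained-background mean fluorescence.
#' @return internalized fraction (vectorized over `surface_mfi_t`).
#' @export
internalization_fraction <- function(surface_mfi_t, surface_mfi_0,
                                     background_mfi) {
  if (any(c(surface_mfi_t, surface_mfi_0, background_mfi) < 0)) {
    stop("fluorescence values must be non-negative")
  }
  if (any(surface_mfi_0 <= background_mfi)) {
    stop("surface_mfi_0 must exceed background_mfi")
  }
  1 - (surface_mfi_t - background_mfi) / (surface_mfi_0 - background_mfi)
}
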