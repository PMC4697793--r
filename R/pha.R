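#' PHA percent modification from band intensities
#'
#' In a PHA ("positive hybridization in the absence of modification")
#' northern assay, the probe spanning the modified position anneals poorly
#' when the modification is present, while a body probe on the same tRNA
#' serves as internal control. Percent modification of an experimental
#' lane is computed against a lane from a modification-null strain:
#'
#' `percent = (1 - (acl_exp/bp_exp) / (acl_unmod/bp_unmod)) * 100`
#'
#' Values can fall below 0 or exceed 100 with noisy blots; they are
#' reported as-is with a warning, never clamped. Intensities must already
#' be background-subtracted; negative inputs are clipped to 0 with a
#' warning.
#'
#' @param acl_exp,bp_exp modification-sensitive (anticodon-loop) and
#'   control (body) probe intensities of the experimental lane.
#' @param acl_unmod,bp_unmod the same probes on the unmodified-strain lane.
#' @return percent modification (numeric, vectorized).
#' @export
pha_percent_modification <- function(acl_exp, bp_exp, acl_unmod, bp_unmod) {
  v <- c(acl_exp, bp_exp, acl_unmod, bp_unmod)
  if (any(v < 0)) {
    warning("negative intensity clipped to 0 (background over-subtraction?)")
    acl_exp <- pmax(acl_exp, 0); bp_exp <- pmax(bp_exp, 0)
    acl_unmod <- pmax(acl_unmod, 0); bp_unmod <- pmax(bp_unmod, 0)
  }
  if (any(bp_exp <= 0)) stop("zero control-probe intensity in experimental lane")
  if (any(bp_unmod <= 0)) stop("zero control-probe intensity in unmodified lane")
  if (any(acl_unmod <= 0)) stop("zero sensitive-probe intensity in unmodified lane")
  out <- (1 - (acl_exp / bp_exp) / (acl_unmod / bp_unmod)) * 100
  if (any(out < 0))
    warning("negative percent modification: experimental lane more probe-reactive than the unmodified control")
  out
}

#' PHA modification index relative to a control lane
#'
#' For the G26 flavor of the assay the modification-sensitive probe spans
#' the D-arm/anticodon-stem region and the control probe the T-loop of the
#' same tRNA. The index is the control-normalized ratio
#' `(tloop/dac) / (tloop_ctrl/dac_ctrl)`; the control lane maps to 1.0 by
#' construction, and higher values mean more modification (the sensitive
#' probe signal falls as modification rises).
#'
#' @param tloop,dac T-loop (control) and D-arm/anticodon-stem (sensitive)
#'   probe intensities of the sample lane.
#' @param tloop_ctrl,dac_ctrl the same probes on the control lane.
#' @return modification index (numeric, vectorized).
#' @export
pha_mod_index <- function(tloop, dac, tloop_ctrl, dac_ctrl) {
  if (any(c(dac, dac_ctrl, tloop_ctrl) <= 0))
    stop("zero intensity in a ratio denominator lane")
  (tloop / dac) / (tloop_ctrl / dac_ctrl)
}

#' PHA quantification of a lane table
#'
#' Convenience wrapper over the two formulas for TSV-style input.
#'
#' @param lanes data.frame with columns `lane_id`, `sensitive`, `control`
#'   (background-subtracted intensities).
#' @param reference_lane lane_id of the unmodified-strain (mode
#'   `"percent"`) or control (mode `"index"`) lane.
#' @param mode `"percent"` or `"index"`.
#' @return data.frame `lane_id`, `metric`, `value`.
#' @export
pha_quantify <- function(lanes, reference_lane, mode = c("percent", "index")) {
  mode <- match.arg(mode)
  stopifnot(all(c("lane_id", "sensitive", "control") %in% names(lanes)))
  ref <- lanes[lanes$lane_id == reference_lane, ]
  if (nrow(ref) != 1L) stop(sprintf("reference lane '%s' not found", reference_lane))
  value <- if (mode == "percent")
    pha_percent_modification(lanes$sensitive, lanes$control,
                             ref$sensitive, ref$control)
  else
    pha_mod_index(lanes$control, lanes$sensitive, ref$control, ref$sensitive)
  data.frame(lane_id = lanes$lane_id,
             metric = if (mode == "percent") "percent_modification"
                      else "modification_index",
             value = value, stringsAsFactors = FALSE)
}
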