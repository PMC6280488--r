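#' A per-arm sample of measured blood-loss volumes
#'
#' Container for the volumes recorded in one treatment arm. Volumes must be
#' positive and finite; the measurement unit (mL, or grams for trials that
#' weighed a collection drape — numerically interchangeable for blood, 1 g
#' of blood occupying about 1 mL) is carried through to all outputs but never
#' converted.
#'
#' @param volumes numeric vector of positive blood-loss measurements.
#' @param arm_label label of the treatment arm.
#' @param unit `"mL"` or `"g"`.
#' @return An object of class `"blood_loss_sample"` with fields `volumes`,
#'   `arm_label`, `unit`, `n`.
#' @export
blood_loss_sample <- function(volumes, arm_label = "arm", unit = c("mL", "g")) {
  unit <- match.arg(unit)
  if (!is.numeric(volumes) || length(volumes) < 1L)
    stop("`volumes` must be a non-empty numeric vector", call. = FALSE)
  bad <- which(!is.finite(volumes) | volumes <= 0)
  if (length(bad))
    stop(sprintf(
      "all volumes must be positive and finite; offending index %d (value %s)",
      bad[1L], format(volumes[bad[1L]])), call. = FALSE)
  structure(
    list(volumes = as.numeric(volumes), arm_label = as.character(arm_label),
         unit = unit, n = length(volumes)),
    class = "blood_loss_sample")
}

as_blood_loss_sample <- function(x, arm_label = "arm", unit = "mL") {
  if (inherits(x, "blood_loss_sample")) return(x)
  if (is.numeric(x)) return(blood_loss_sample(x, arm_label, unit))
  stop("expected a blood_loss_sample or a numeric vector of volumes",
       call. = FALSE)
}

#' @export
print.blood_loss_sample <- function(x, ...) {
  cat(sprintf("blood-loss sample '%s': n = %d, median %.0f %s, range [%.0f, %.0f]\n",
              x$arm_label, x$n, stats::median(x$volumes), x$unit,
              min(x$volumes), max(x$volumes)))
  invisible(x)
}
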