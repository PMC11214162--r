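#' Construct a set of fetal biometry measurements
#'
#' Bundles the four standard fetal biometry measurements — biparietal
#' diameter (BPD), head circumference (HC), abdominal circumference (AC)
#' and femur length (FL) — in millimetres. Each argument may be omitted
#' (`NULL`) or given as a numeric vector; vectors are recycled to a common
#' length so a `biometry_set` can represent one scan or a whole column of
#' scans.
#'
#' @param bpd,hc,ac,fl numeric vectors of measurements in millimetres, or
#'   `NULL` when the measurement was not taken. At least one must be present.
#' @return An object of class `biometry_set`: a data frame with one row per
#'   scan and one column per present measurement.
#' @examples
#' biometry_set(hc = 250, fl = 50)
#' @export
biometry_set <- function(bpd = NULL, hc = NULL, ac = NULL, fl = NULL) {
  vals <- list(bpd = bpd, hc = hc, ac = ac, fl = fl)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (length(vals) == 0L) {
    stopf("at least one of bpd, hc, ac, fl must be provided",
          class = "gaguard_missing_measurement")
  }
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v)) stopf("measurement '%s' must be numeric", nm)
    if (any(!is.finite(v)) || any(v <= 0)) {
      stopf("measurement '%s' must be finite and strictly positive", nm)
    }
  }
  n <- max(vapply(vals, length, integer(1)))
  vals <- lapply(vals, rep_len, n)
  if (!is.null(vals$hc) && !is.null(vals$bpd) && any(vals$hc <= vals$bpd)) {
    stopf("head circumference must exceed biparietal diameter")
  }
  structure(as.data.frame(vals), class = c("biometry_set", "data.frame"))
}

#' @export
print.biometry_set <- function(x, ...) {
  cat("<biometry_set> ", nrow(x), " scan(s), measurements: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

# Coerce a data frame (e.g. cohort columns) to the measurement list the
# formula evaluator expects, without re-validating row by row.
as_biometry_df <- function(x) {
  if (inherits(x, "biometry_set")) return(as.data.frame(x))
  as.data.frame(x)[intersect(c("bpd", "hc", "ac", "fl"), names(x))]
}
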