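# Tumor caliper arithmetic: the ellipsoid-style volume formula and
# per-tumor growth normalization to baseline.

#' Tumor volume from caliper measurements
#'
#' `volume = width^2 * length / 2` (mm^3). By convention the larger
#' dimension is the length; swapped inputs are corrected with a warning,
#' since the formula squares the smaller dimension.
#'
#' @param width_mm,length_mm positive caliper dimensions (vectorized).
#' @return volume in mm^3.
#' @examples
#' tumor_volume(4, 8)  # 64
#' @export
tumor_volume <- function(width_mm, length_mm) {
  if (any(!is.finite(width_mm)) || any(!is.finite(length_mm)) ||
      any(width_mm <= 0) || any(length_mm <= 0))
    stop("caliper dimensions must be positive")
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning("width > length for some measurements; dimensions swapped")
    tmp <- width_mm[swap]
    width_mm[swap] <- length_mm[swap]
    length_mm[swap] <- tmp
  }
  width_mm^2 * length_mm / 2
}

#' Per-tumor growth normalized to baseline
#'
#' For each tumor, volume at every day divided by the volume at the
#' baseline day (treatment start), so growth at baseline is exactly 1.
#'
#' @param measurements data.frame with columns tumor_id, day, width_mm,
#'   length_mm (and optionally group).
#' @param baseline_day the normalization day; must be present for every
#'   tumor. Default: the earliest day in the table.
#' @return data.frame: tumor_id, (group,) day, volume_mm3, growth_ratio,
#'   ordered by tumor then day.
#' @export
tumor_growth <- function(measurements, baseline_day = NULL) {
  need <- c("tumor_id", "day", "width_mm", "length_mm")
  if (!all(need %in% names(measurements)))
    stop("measurements need columns tumor_id, day, width_mm, length_mm")
  baseline_day <- baseline_day %||% min(measurements$day)
  measurements$volume_mm3 <- tumor_volume(measurements$width_mm,
                                          measurements$length_mm)
  out <- lapply(split(measurements, measurements$tumor_id), function(m) {
    m <- m[order(m$day), , drop = FALSE]
    b <- m$volume_mm3[m$day == baseline_day]
    if (length(b) != 1L)
      stop("missing or duplicated baseline day for tumor ", m$tumor_id[1])
    if (b == 0) stop("zero baseline volume for tumor ", m$tumor_id[1])
    m$growth_ratio <- m$volume_mm3 / b
    m
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  keep <- intersect(c("tumor_id", "group", "day", "volume_mm3",
                      "growth_ratio"), names(out))
  out[, keep, drop = FALSE]
}
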