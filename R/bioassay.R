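#' CCK-8 cell viability percentage
#'
#' Plate-reader viability ratio:
#' `viability = 100 * sample / control`. An optional blank-well
#' absorbance is subtracted from both terms first. Values may exceed
#' 100 (proliferation relative to control); values above 120 are
#' flagged with a warning. Vectorized over `sample_absorbance`.
#'
#' @param sample_absorbance Absorbance of treated wells, >= 0.
#' @param control_absorbance Absorbance of untreated control wells;
#'   must exceed the blank.
#' @param blank_absorbance Optional blank-well absorbance subtracted
#'   from both; default 0.
#' @return Viability in percent, same length as `sample_absorbance`.
#' @examples
#' cell_viability(0.38, 1.0)  # 38
#' @export
cell_viability <- function(sample_absorbance, control_absorbance,
                           blank_absorbance = 0) {
  stop_if_not_scalar(control_absorbance, "control_absorbance")
  stop_if_not_scalar(blank_absorbance, "blank_absorbance")
  if (!is.numeric(sample_absorbance) || length(sample_absorbance) == 0 ||
      anyNA(sample_absorbance))
    stop("`sample_absorbance` must be numeric", call. = FALSE)
  s <- sample_absorbance - blank_absorbance
  ctrl <- control_absorbance - blank_absorbance
  if (ctrl <= 0)
    stop("control absorbance must exceed the blank", call. = FALSE)
  if (any(s < 0))
    stop("sample absorbance below the blank", call. = FALSE)
  v <- 100 * s / ctrl
  if (any(v > 120))
    warning("viability above 120% flagged (check wells)", call. = FALSE)
  v
}

#' Relative tumor volume summaries per group and day
#'
#' Per-animal relative tumor volume (RTV) is the volume normalized to
#' that animal's day-0 baseline, `RTV = V(day) / V(0)`; the table
#' reports the per-group mean and standard deviation for each
#' measurement day.
#'
#' @param records Data frame with columns `group`, `animal_id`, `day`
#'   (days since treatment start, >= 0) and `volume_mm3` (>= 0). Every
#'   animal needs a positive day-0 baseline.
#' @return A data frame with columns `group`, `day`, `mean_rtv`,
#'   `sd_rtv`, `n` (animals measured), sorted by group then day.
#' @export
relative_tumor_volume <- function(records) {
  need <- c("group", "animal_id", "day", "volume_mm3")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("`records` needs columns group, animal_id, day, volume_mm3",
         call. = FALSE)
  if (any(records$day < 0) || any(records$volume_mm3 < 0))
    stop("days and volumes must be non-negative", call. = FALSE)
  key <- interaction(records$group, records$animal_id, drop = TRUE)
  base <- tapply(ifelse(records$day == 0, records$volume_mm3, NA_real_),
                 key, function(v) {
                   v <- v[!is.na(v)]
                   if (length(v) == 0) NA_real_ else v[1]
                 })
  if (anyNA(base) || any(base <= 0))
    stop("every animal needs a positive day-0 baseline volume",
         call. = FALSE)
  rtv <- records$volume_mm3 / as.numeric(base[as.character(key)])
  agg <- stats::aggregate(
    rtv, by = list(group = records$group, day = records$day),
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                        n = length(v)))
  out <- data.frame(group = agg$group, day = agg$day,
                    mean_rtv = agg$x[, "mean"], sd_rtv = agg$x[, "sd"],
                    n = as.integer(agg$x[, "n"]))
  out <- out[order(out$group, out$day), ]
  rownames(out) <- NULL
  out
}
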