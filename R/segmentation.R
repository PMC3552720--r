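# Region handling for the mid-LV short-axis slice: cavity + myocardial annulus
# masks, a 4-sector angular partition of the myocardium (anterior, lateral,
# inferior, septal), region-mean curve extraction, and Simpson-disk volumetry.

SECTOR_NAMES_4 <- c("anterior", "lateral", "inferior", "septal")

#' Partition the myocardium into angular sectors
#'
#' Assigns each myocardial pixel, by its polar angle about the LV center, to
#' one of `n_sectors` equal wedges of width `2*pi/n_sectors`. Wedge 1 is
#' centered on `reference_angle` and is labeled `anterior`; labels proceed
#' counter-clockwise in the order anterior, lateral, inferior, septal (for
#' other sector counts, generic `sector1..k` labels are used).
#'
#' @param myocardium Logical matrix marking myocardial pixels.
#' @param cavity Logical matrix marking LV cavity pixels (disjoint from the
#'   myocardium); may be all-`FALSE` if only the ring is of interest.
#' @param center Numeric length-2 LV center in pixel coordinates `(x, y)`
#'   where `x` is the first array index.
#' @param reference_angle Angle (radians, counter-clockwise) on which the
#'   anterior wedge is centered.
#' @param n_sectors Number of equal wedges (>= 1).
#' @return A [segmentation_mask()].
#' @export
partition_sectors <- function(myocardium, cavity = NULL, center,
                              reference_angle = 0, n_sectors = 4L) {
  if (!is.matrix(myocardium) || !is.logical(myocardium))
    geometry_error("'myocardium' must be a logical matrix")
  if (!any(myocardium))
    geometry_error("the myocardium mask is empty")
  check_scalar(n_sectors, "n_sectors", lower = 1, integer = TRUE)
  check_scalar(reference_angle, "reference_angle")
  if (is.null(cavity))
    cavity <- matrix(FALSE, nrow(myocardium), ncol(myocardium))
  if (!identical(dim(cavity), dim(myocardium)))
    geometry_error("cavity and myocardium masks must share dimensions")
  if (any(cavity & myocardium))
    geometry_error("cavity and myocardium masks overlap")
  idx <- which(myocardium, arr.ind = TRUE)
  sector <- matrix(NA_integer_, nrow(myocardium), ncol(myocardium))
  sector[myocardium] <- sector_of_angle(
    atan2(idx[, 2] - center[2], idx[, 1] - center[1]),
    reference_angle, n_sectors
  )
  sector_names <- if (n_sectors == 4L) SECTOR_NAMES_4 else
    paste0("sector", seq_len(n_sectors))
  segmentation_mask(cavity = cavity, myocardium = myocardium, sector = sector,
                    sector_names = sector_names, center = center,
                    reference_angle = reference_angle)
}

# Wedge index (1-based) of an angle: wedge 1 spans
# reference_angle +/- pi/n_sectors, subsequent wedges counter-clockwise.
sector_of_angle <- function(theta, reference_angle, n_sectors) {
  w <- 2 * pi / n_sectors
  as.integer(floor(((theta - reference_angle + w / 2) %% (2 * pi)) / w)) + 1L
}

#' Segmentation mask container
#'
#' @param cavity,myocardium Logical matrices (same dimensions, disjoint).
#' @param sector Integer matrix of per-pixel sector labels (`NA` outside the
#'   myocardium).
#' @param sector_names Character labels indexed by sector code.
#' @param center LV center in pixel coordinates.
#' @param reference_angle Anterior reference angle (radians).
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(cavity, myocardium, sector, sector_names,
                              center, reference_angle = 0) {
  if (!identical(dim(cavity), dim(myocardium)) ||
      !identical(dim(cavity), dim(sector)))
    geometry_error("mask components must share dimensions")
  if (any(cavity & myocardium))
    geometry_error("cavity and myocardium masks overlap")
  if (any(is.na(sector[myocardium])))
    geometry_error("every myocardial pixel needs a sector label")
  if (any(!is.na(sector[!myocardium])))
    geometry_error("sector labels outside the myocardium")
  structure(
    list(dim = dim(cavity), cavity = cavity, myocardium = myocardium,
         sector = sector, sector_names = sector_names,
         center = center, reference_angle = reference_angle),
    class = "segmentation_mask"
  )
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation mask> %dx%d, cavity %d px, myocardium %d px, %d sectors\n",
              x$dim[1], x$dim[2], sum(x$cavity), sum(x$myocardium),
              length(x$sector_names)))
  invisible(x)
}

#' Region-mean time-intensity curve from an image series
#'
#' @param series Numeric array `(x, y, frame)`.
#' @param region Logical matrix selecting the region (non-empty, same in-plane
#'   dimensions as the series).
#' @param region_label,state Labels attached to the returned curve.
#' @return A [tic()] whose value at frame `t` is the arithmetic mean of the
#'   region's pixels in that frame.
#' @export
extract_time_intensity <- function(series, region, region_label = NA_character_,
                                   state = NA_character_) {
  if (!is.array(series) || length(dim(series)) != 3L)
    input_error("'series' must be a 3-D array (x, y, frame)")
  if (!is.matrix(region) || !is.logical(region) ||
      !identical(dim(region), dim(series)[1:2]))
    geometry_error("'region' must be a logical matrix matching the frame grid")
  if (!any(region))
    geometry_error("the region is empty")
  flat <- matrix(series, nrow = prod(dim(series)[1:2]))
  vals <- colMeans(flat[which(region), , drop = FALSE])
  tic(seq_len(dim(series)[3]) - 1, vals, region = region_label, state = state)
}

#' Blood-pool and sector curves for one state
#'
#' Convenience wrapper applying [extract_time_intensity()] to the cavity and to
#' each myocardial sector of a mask.
#'
#' @param series Numeric array `(x, y, frame)`.
#' @param mask A [segmentation_mask()].
#' @param state State label attached to the curves.
#' @return Named list: `blood` plus one curve per sector.
#' @export
extract_state_curves <- function(series, mask, state = NA_character_) {
  stopifnot(inherits(mask, "segmentation_mask"))
  out <- list(blood = extract_time_intensity(series, mask$cavity, "blood", state))
  for (k in seq_along(mask$sector_names)) {
    reg <- !is.na(mask$sector) & mask$sector == k
    out[[mask$sector_names[k]]] <-
      extract_time_intensity(series, reg, mask$sector_names[k], state)
  }
  out
}

#' Contour stack for Simpson volumetry
#'
#' Per-slice endocardial and epicardial areas from a base-to-apex short-axis
#' stack.
#'
#' @param endo_area_mm2,epi_area_mm2 Numeric vectors of per-slice areas (mm^2).
#' @param thickness_mm Slice thickness (mm, > 0).
#' @param gap_mm Inter-slice gap (mm, >= 0).
#' @return An object of class `contour_stack`.
#' @export
contour_stack <- function(endo_area_mm2, epi_area_mm2 = endo_area_mm2,
                          thickness_mm = 8, gap_mm = 2) {
  if (length(endo_area_mm2) < 1L)
    input_error("a contour stack needs at least one slice")
  if (length(endo_area_mm2) != length(epi_area_mm2))
    input_error("endocardial and epicardial areas must have equal length")
  if (any(!is.finite(endo_area_mm2)) || any(endo_area_mm2 < 0) ||
      any(!is.finite(epi_area_mm2)) || any(epi_area_mm2 < 0))
    input_error("slice areas must be finite and non-negative")
  check_scalar(thickness_mm, "thickness_mm", lower = 0, strict_lower = TRUE)
  check_scalar(gap_mm, "gap_mm", lower = 0)
  structure(list(endo_area_mm2 = as.numeric(endo_area_mm2),
                 epi_area_mm2 = as.numeric(epi_area_mm2),
                 thickness_mm = thickness_mm, gap_mm = gap_mm),
            class = "contour_stack")
}

#' Simpson method-of-disks volume
#'
#' Sums per-slice areas times the disk height (slice thickness plus gap, the
#' usual clinical convention for gapped stacks) and converts mm^3 to mL.
#'
#' @param stack A [contour_stack()].
#' @param which `"endocardial"` (cavity volume) or `"epicardial"`.
#' @return Volume in mL.
#' @examples
#' simpson_volume(contour_stack(rep(100, 10), thickness_mm = 8, gap_mm = 2))
#' @export
simpson_volume <- function(stack, which = c("endocardial", "epicardial")) {
  stopifnot(inherits(stack, "contour_stack"))
  which <- match.arg(which)
  areas <- if (which == "endocardial") stack$endo_area_mm2 else stack$epi_area_mm2
  sum(areas) * (stack$thickness_mm + stack$gap_mm) / 1000
}

#' Ejection fraction from end-diastolic and end-systolic stacks
#'
#' @param ed_stack,es_stack [contour_stack()]s at end diastole and end systole.
#' @return List with `edv_ml`, `esv_ml`, `ef` (fraction of EDV ejected).
#' @export
lv_ejection_fraction <- function(ed_stack, es_stack) {
  edv <- simpson_volume(ed_stack, "endocardial")
  esv <- simpson_volume(es_stack, "endocardial")
  if (edv <= 0) domain_error("end-diastolic volume must be positive")
  list(edv_ml = edv, esv_ml = esv, ef = (edv - esv) / edv)
}
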