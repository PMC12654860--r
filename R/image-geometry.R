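#' Micrograph container
#'
#' A single bright-field-like frame: a 2-D intensity array plus the
#' pixel pitch and the orientation of the compression axis. Pixel
#' indices are 0-based with intensities sampled at pixel centers
#' (index + 0.5); all measurements are converted to micrometers via
#' `pixel_size`.
#'
#' @param intensities Numeric matrix (rows x cols), non-empty.
#' @param pixel_size Pixel pitch in um/px, > 0.
#' @param compression_axis `"horizontal"` (plates are vertical bands,
#'   default) or `"vertical"`.
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(intensities, pixel_size,
                       compression_axis = c("horizontal", "vertical")) {
  if (!is.matrix(intensities) || !is.numeric(intensities) ||
      length(intensities) == 0)
    stopf("`intensities` must be a non-empty numeric matrix")
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  compression_axis <- match.arg(compression_axis)
  structure(list(intensities = intensities, pixel_size = pixel_size,
                 compression_axis = compression_axis),
            class = "micrograph")
}

# Orient the frame so the compression axis runs along columns.
axis_matrix <- function(image) {
  m <- image$intensities
  if (image$compression_axis == "vertical") t(m) else m
}

#' Locate the two plate inner edges
#'
#' Averages intensity across the transverse direction to get a 1-D
#' profile along the compression axis, then takes the strongest rising
#' gradient (dark plate to bright interior) as the left inner edge and
#' the strongest falling gradient right of it as the right inner edge.
#' Both gradients must exceed 25% of the profile's dynamic range, which
#' makes detection invariant to affine intensity rescaling.
#'
#' @param image A [micrograph()].
#' @return A list with `left_um`, `right_um` (inner-edge positions along
#'   the axis, um from the frame edge), `separation_um`, and the pixel
#'   boundaries `left_px`, `right_px`.
#' @export
locate_plates <- function(image) {
  stopifnot(inherits(image, "micrograph"))
  m <- axis_matrix(image)
  profile <- colMeans(m)
  g <- diff(profile)
  rng <- max(profile) - min(profile)
  if (rng <= .Machine$double.eps || length(g) < 3)
    stopf("plate detection failed: image has no intensity structure")
  iL <- which.max(g)                        # boundary after last left-plate col
  right_region <- seq(iL + 1, length(g))
  iR <- right_region[which.min(g[right_region])]
  if (g[iL] < 0.25 * rng || -g[iR] < 0.25 * rng)
    stopf("plate detection failed: fewer than two strong band edges")
  # boundary between columns i and i+1 sits at i px (0-based geometry)
  list(left_um = iL * image$pixel_size,
       right_um = iR * image$pixel_size,
       separation_um = (iR - iL) * image$pixel_size,
       left_px = iL, right_px = iR)
}

# Segment the cell between the plates: automatic (Otsu) threshold on the
# interior region, keep the largest connected component. Returns a
# logical matrix in axis orientation (interior columns only) plus the
# column offset of the interior region.
segment_cell <- function(image, plates) {
  m <- axis_matrix(image)
  cols <- seq(plates$left_px + 1, plates$right_px)
  sub <- m[, cols, drop = FALSE]
  rng <- range(sub)
  if (diff(rng) <= .Machine$double.eps)
    stopf("cell segmentation failed: empty mask (uniform interior)")
  thr <- EBImage::otsu(sub, range = rng)
  mask <- sub < thr                          # cell darker than background
  if (!any(mask))
    stopf("cell segmentation failed: empty mask")
  lab <- EBImage::bwlabel(mask)
  counts <- tabulate(lab[lab > 0])
  mask <- lab == which.max(counts)
  list(mask = mask, col_offset = plates$left_px)
}

# Per-side contact analysis. For each plate the transverse mask extent
# is profiled over the first `band_px` interior columns. A squashed
# convex cell is narrowest right at the plate (a flat contact collar),
# so the contact length is the minimum extent in the band; a profile
# that widens sharply away from the plate indicates tangent
# (sub-resolution) contact and is reported as no contact.
side_contact <- function(mask, side, band_px, pixel_size) {
  nc <- ncol(mask)
  cols_of <- function(d) if (side == "left") d else nc - d + 1L
  extent_at <- function(d) {
    col <- mask[, cols_of(d)]
    if (!any(col)) return(NA_real_)
    (max(which(col)) - min(which(col)) + 1L) * pixel_size
  }
  e_band <- vapply(seq_len(band_px), extent_at, numeric(1))
  if (all(is.na(e_band)) || is.na(e_band[1]))
    return(list(Dt = 0, contact = FALSE))
  e_min <- min(e_band, na.rm = TRUE)
  d_ref <- min(band_px + 2L, nc)
  e_ref <- extent_at(d_ref)
  if (!is.na(e_ref) && e_ref > e_min + 2 * pixel_size)
    return(list(Dt = 0, contact = FALSE))   # widening: tangent contact
  list(Dt = e_min, contact = TRUE)
}

#' Measure cell width along the compression axis
#'
#' While the cell touches both plates its width equals the plate
#' inner-edge separation; before contact the width is the axial extent
#' of the segmented cell mask.
#'
#' @param image A [micrograph()].
#' @param plates A [locate_plates()] result; located automatically when
#'   omitted.
#' @param band_px Width (px) of the plate-adjacent band used for contact
#'   detection.
#' @return A list with `Lt_um` and logical `contact`.
#' @export
measure_width <- function(image, plates = NULL, band_px = 2) {
  stopifnot(inherits(image, "micrograph"))
  plates <- plates %||% locate_plates(image)
  seg <- segment_cell(image, plates)
  left <- side_contact(seg$mask, "left", band_px, image$pixel_size)
  right <- side_contact(seg$mask, "right", band_px, image$pixel_size)
  if (left$contact && right$contact)
    return(list(Lt_um = plates$separation_um, contact = TRUE))
  cols <- which(colSums(seg$mask) > 0)
  list(Lt_um = (max(cols) - min(cols) + 1L) * image$pixel_size,
       contact = FALSE)
}

#' Measure the contact length at the plates
#'
#' The contact length is the transverse extent of the segmented cell
#' mask immediately adjacent to each plate inner edge (within a
#' `band_px`-pixel band), averaged over the plates in contact. A cell
#' not reaching a plate, or touching it only tangentially (the mask
#' widens away from the plate faster than a flat contact collar), is
#' scored as no contact on that side; with no contact on either side the
#' function returns 0 with `contact = FALSE`.
#'
#' @inheritParams measure_width
#' @return A list with `Dt_um`, logical `contact`, and the per-side
#'   values `Dt_left_um`, `Dt_right_um`.
#' @export
measure_contact_length <- function(image, plates = NULL, band_px = 2) {
  stopifnot(inherits(image, "micrograph"))
  plates <- plates %||% locate_plates(image)
  seg <- segment_cell(image, plates)
  left <- side_contact(seg$mask, "left", band_px, image$pixel_size)
  right <- side_contact(seg$mask, "right", band_px, image$pixel_size)
  sides <- c(if (left$contact) left$Dt, if (right$contact) right$Dt)
  list(Dt_um = if (length(sides)) mean(sides) else 0,
       contact = length(sides) > 0,
       Dt_left_um = left$Dt, Dt_right_um = right$Dt)
}

#' Contact area from contact length
#'
#' The cell-plate contact patch is approximated as a circle of diameter
#' `Dt`, so \eqn{S_t = \pi D_t^2 / 4}.
#'
#' @param Dt Contact length(s) in um, >= 0.
#' @return Contact area(s) in um^2.
#' @examples
#' contact_area(10)  # 78.5398 um^2
#' @export
contact_area <- function(Dt) {
  stopifnot(is.numeric(Dt))
  if (any(Dt < 0)) stopf("`Dt` must be >= 0")
  pi * Dt^2 / 4
}

#' Measure a full frame or stack
#'
#' `measure_frame()` runs plate location, width, and contact-length
#' measurement on one frame; `measure_stack()` maps it over a list of
#' frames and returns a per-frame geometry table.
#'
#' @param image A [micrograph()].
#' @param frame_index Frame number recorded in the output row.
#' @inheritParams measure_width
#' @return A one-row (or per-frame) data.frame with columns `frame`,
#'   `Dt_um`, `Lt_um`, `contact`.
#' @export
measure_frame <- function(image, frame_index = 1L, band_px = 2) {
  plates <- locate_plates(image)
  w <- measure_width(image, plates, band_px)
  d <- measure_contact_length(image, plates, band_px)
  data.frame(frame = frame_index, Dt_um = d$Dt_um, Lt_um = w$Lt_um,
             contact = w$contact & d$contact)
}

#' @rdname measure_frame
#' @param frames A list of [micrograph()] frames.
#' @export
measure_stack <- function(frames, band_px = 2) {
  stopifnot(is.list(frames), length(frames) > 0)
  do.call(rbind, lapply(seq_along(frames), function(i) {
    measure_frame(frames[[i]], frame_index = i, band_px = band_px)
  }))
}

#' Read / write micrograph stacks as TIFF
#'
#' `write_stack_tiff()` stores a list of frames as a multi-page float
#' TIFF; `read_stack_tiff()` reads one back given the pixel pitch
#' (TIFF files do not carry it reliably).
#'
#' @param frames List of [micrograph()] frames.
#' @param path TIFF path.
#' @export
write_stack_tiff <- function(frames, path) {
  stopifnot(is.list(frames), length(frames) > 0)
  imgs <- lapply(frames, function(f) {
    m <- f$intensities
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param pixel_size Pixel pitch (um/px) to attach to the frames.
#' @param compression_axis Orientation to attach to the frames.
#' @return `read_stack_tiff()` returns a list of [micrograph()] frames.
#' @export
read_stack_tiff <- function(path, pixel_size,
                            compression_axis = "horizontal") {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    micrograph(m, pixel_size = pixel_size,
               compression_axis = compression_axis)
  })
}
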