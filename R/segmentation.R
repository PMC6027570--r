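#' @name aha6
#' @title AHA 6-segment model of the mid-ventricular short-axis slice
#'
#' @description
#' A mid-ventricular short-axis slice is divided into six 60-degree angular
#' segments about the LV center, anchored at the anterior RV insertion point:
#' anterior, anteroseptal, inferoseptal, inferior, inferolateral,
#' anterolateral (labels 1-6). The anteroseptal segment is the infarcted
#' region in the LAD occlusion model used here; inferior, inferolateral and
#' anterolateral form the remote region; anterior and inferoseptal are
#' adjacent ("other").
NULL

#' Segment names in label order
#' @export
aha6_segment_names <- function() {
  c("anterior", "anteroseptal", "inferoseptal",
    "inferior", "inferolateral", "anterolateral")
}

.region_map <- c(anterior = "other", anteroseptal = "infarct",
                 inferoseptal = "other", inferior = "remote",
                 inferolateral = "remote", anterolateral = "remote")

#' Region (infarct/remote/other) of an AHA segment
#'
#' In the LAD occlusion/reperfusion model the anteroseptal segment is the
#' infarcted region; inferior, inferolateral and anterolateral are remote;
#' the remaining two segments border the infarct and are grouped as "other".
#'
#' @param segment_index Integer 1-6 (order of [aha6_segment_names()]), or a
#'   segment name.
#' @return Character: "infarct", "remote" or "other".
#' @examples
#' region_of(2)  # anteroseptal -> infarct
#' region_of("inferior")
#' @export
region_of <- function(segment_index) {
  if (is.character(segment_index)) {
    idx <- match(segment_index, aha6_segment_names())
    if (any(is.na(idx))) stop("unknown segment name")
  } else {
    idx <- as.integer(segment_index)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > 6L))
      stop("segment index must be in 1..6")
  }
  unname(.region_map[aha6_segment_names()[idx]])
}

# Pixel polar angles about a center, degrees CCW from +col in display
# orientation (row index increases downward, hence the sign flip).
.pixel_angles <- function(dims, lv_center) {
  rows <- matrix(0:(dims[1] - 1), dims[1], dims[2])
  cols <- matrix(0:(dims[2] - 1), dims[1], dims[2], byrow = TRUE)
  (atan2(-(rows - lv_center[1]), cols - lv_center[2]) * 180 / pi) %% 360
}

#' Partition a myocardial mask into the six AHA segments
#'
#' Every mask pixel is assigned by its polar angle about the LV center into
#' one of six half-open 60-degree wedges. The anterior/anteroseptal boundary
#' lies at the anterior RV insertion angle; segments proceed counter-clockwise
#' from that boundary through the septum: anteroseptal, inferoseptal,
#' inferior, inferolateral, anterolateral, anterior.
#'
#' @param mask A [myocardial_mask()].
#' @return An object of class `segment_labels`: list with `labels` (integer
#'   matrix, 0 background, 1-6 segments), `regions` (named character vector
#'   mapping segment name to region), and the mask geometry.
#' @export
aha6_labels <- function(mask) {
  if (!inherits(mask, "myocardial_mask"))
    stop("`mask` must be a myocardial_mask")
  m <- mask$mask
  if (!any(m)) stop("myocardial mask is empty")
  theta <- .pixel_angles(dim(m), mask$lv_center)
  # wedge 0 starts at the RV insertion angle going CCW (through the septum)
  k <- floor(((theta - mask$rv_insertion_angle) %% 360) / 60)
  seg <- ifelse(k == 5, 1L, as.integer(k) + 2L)  # k=0 -> anteroseptal (2)
  lab <- matrix(0L, nrow(m), ncol(m))
  lab[m] <- seg[m]
  structure(list(labels = lab,
                 regions = .region_map,
                 lv_center = mask$lv_center,
                 rv_insertion_angle = mask$rv_insertion_angle),
            class = "segment_labels")
}

#' @export
print.segment_labels <- function(x, ...) {
  counts <- tabulate(x$labels[x$labels > 0L], 6L)
  cat("<segment_labels> ", sum(counts), " myocardial pixels\n", sep = "")
  print(stats::setNames(counts, aha6_segment_names()))
  invisible(x)
}

#' Spatial-temporal averaging filter
#'
#' Replaces each myocardial pixel by the mean of its in-mask neighbours
#' within a Euclidean radius (pixels outside the mask never contribute, so no
#' blood-pool or background signal is pulled into the myocardium). With
#' `temporal = TRUE` each frame is additionally replaced by the mean across
#' the frames of the stack, so like frames must be passed together (controls
#' with controls, labels with labels). Background pixels are left untouched.
#'
#' @param image_stack Numeric matrix (one frame) or 3-D array (frames along
#'   the third dimension) on the mask grid.
#' @param mask Logical matrix or a [myocardial_mask()].
#' @param spatial_radius Neighbourhood radius in pixels (>= 0). Radius 0
#'   disables spatial averaging.
#' @param temporal Average across frames as well? Default FALSE.
#' @return Filtered stack with the input's dimensions.
#' @export
spatial_temporal_filter <- function(image_stack, mask, spatial_radius = 1,
                                    temporal = FALSE) {
  if (spatial_radius < 0) stop("`spatial_radius` must be >= 0")
  if (inherits(mask, "myocardial_mask")) mask <- mask$mask
  mask <- as.matrix(mask)
  one_frame <- is.matrix(image_stack)
  stack <- if (one_frame) array(image_stack, c(dim(image_stack), 1L)) else image_stack
  if (!identical(dim(stack)[1:2], dim(mask)))
    stop("image stack and mask grids differ")
  nf <- dim(stack)[3]

  if (spatial_radius > 0) {
    r <- floor(spatial_radius)
    offs <- expand.grid(dr = -r:r, dc = -r:r)
    offs <- offs[offs$dr^2 + offs$dc^2 <= spatial_radius^2, ]
    nr <- nrow(mask); nc <- ncol(mask)
    for (f in seq_len(nf)) {
      frame <- stack[, , f]
      acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
      for (i in seq_len(nrow(offs))) {
        dr <- offs$dr[i]; dc <- offs$dc[i]
        sr <- max(1, 1 - dr):min(nr, nr - dr)
        sc <- max(1, 1 - dc):min(nc, nc - dc)
        mshift <- mask[sr + dr, sc + dc, drop = FALSE]
        acc[sr, sc] <- acc[sr, sc] + frame[sr + dr, sc + dc, drop = FALSE] * mshift
        cnt[sr, sc] <- cnt[sr, sc] + mshift
      }
      out <- frame
      out[mask] <- acc[mask] / cnt[mask]  # cnt >= 1: the pixel itself is in-mask
      stack[, , f] <- out
    }
  }
  if (temporal && nf > 1L) {
    tm <- apply(stack, c(1, 2), mean)
    for (f in seq_len(nf)) {
      frame <- stack[, , f]
      frame[mask] <- tm[mask]
      stack[, , f] <- frame
    }
  }
  if (one_frame) stack[, , 1] else stack
}
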