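#' Segment a raster image of a cell layout
#'
#' Extracts cell geometries from a single-channel (or RGB, averaged)
#' raster by Gaussian smoothing, intensity thresholding and
#' connected-component labelling, returning one closed contour per
#' component plus an equivalent-circle layout. The largest component is
#' classified as the tumor; the rest are immune cells, optionally
#' subdivided by radius thresholds.
#'
#' @param image numeric matrix in [0,1] (first index x, second y), or a
#'   3-D array whose channels are averaged, or a path to a PNG file.
#' @param sigma Gaussian smoothing standard deviation in pixels
#'   (0 disables smoothing).
#' @param threshold intensity threshold; pixels with intensity >
#'   \code{threshold} are foreground. Use \code{invert = TRUE} for dark
#'   shapes on a light background.
#' @param invert logical; invert intensities before thresholding.
#' @param scale metres per pixel used to convert the result to physical
#'   coordinates (default 1, i.e. pixel units).
#' @param min_area_px components smaller than this many pixels are
#'   discarded as noise.
#' @param type_radius optional named numeric vector of radius upper
#'   bounds (m) classifying non-tumor components by equivalent radius,
#'   e.g. \code{c(tcell = 5e-6, macrophage = 9e-6)}; larger components
#'   get the last name. Default labels every non-tumor cell "immune".
#' @return a list of class \code{exo_segmentation}: \code{layout} (an
#'   [cellLayout()] of equivalent circles), \code{contours} (list of
#'   closed pixel-coordinate polygon matrices), \code{areas_px},
#'   \code{centers_px}.
#' @export
segmentImage <- function(image, sigma = 2, threshold = 0.5, invert = FALSE,
                         scale = 1, min_area_px = 9,
                         type_radius = NULL) {
  if (is.character(image)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("segmentImage: reading PNG files requires the png package",
           call. = FALSE)
    image <- png::readPNG(image)
  }
  if (length(dim(image)) == 3) image <- apply(image, c(1, 2), mean)
  if (!is.matrix(image) || !is.numeric(image))
    stop("segmentImage: image must be a numeric matrix", call. = FALSE)
  if (invert) image <- max(image) - image
  if (sigma > 0) image <- EBImage::gblur(image, sigma = sigma)
  fg <- image > threshold
  if (!any(fg))
    stop("segmentImage: no foreground pixels above threshold ", threshold,
         " (max smoothed intensity ", signif(max(image), 3), ")",
         call. = FALSE)
  lab <- EBImage::bwlabel(fg)
  labv <- as.integer(EBImage::imageData(lab))
  nlab <- max(labv)
  if (nlab == 0)
    stop("segmentImage: no connected components found", call. = FALSE)
  nxp <- nrow(image); nyp <- ncol(image)
  ix <- rep.int(seq_len(nxp), nyp)
  iy <- rep(seq_len(nyp), each = nxp)
  keepv <- labv > 0L
  areas <- tabulate(labv[keepv], nbins = nlab)
  cx <- rowsum(ix[keepv], labv[keepv])[, 1] / areas
  cy <- rowsum(iy[keepv], labv[keepv])[, 1] / areas
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0)
    stop("segmentImage: all components below min_area_px = ", min_area_px,
         call. = FALSE)
  contours <- EBImage::ocontour(lab)
  ord <- keep[order(areas[keep], decreasing = TRUE)]
  radii <- sqrt(areas / pi)
  # pixel centers at (i - 0.5) * scale
  tum_id <- ord[1]
  tumor <- shapeCircle(c(cx[tum_id] - 0.5, cy[tum_id] - 0.5) * scale,
                       radii[tum_id] * scale)
  immune <- lapply(ord[-1], function(id) {
    r <- radii[id] * scale
    ty <- "immune"
    if (!is.null(type_radius)) {
      hit <- which(r <= type_radius)
      ty <- if (length(hit)) names(type_radius)[hit[1]]
            else names(type_radius)[length(type_radius)]
    }
    list(center = c(cx[id] - 0.5, cy[id] - 0.5) * scale, radius = r, type = ty)
  })
  structure(list(layout = cellLayout(tumor, immune),
                 contours = contours[ord],
                 areas_px = areas[ord],
                 centers_px = cbind(x = cx[ord], y = cy[ord])),
            class = "exo_segmentation")
}

#' @export
print.exo_segmentation <- function(x, ...) {
  cat(sprintf("<exo_segmentation> %d components (tumor area %d px)\n",
              length(x$areas_px), x$areas_px[1]))
  invisible(x)
}
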