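#' Specify a structured finite-volume grid
#'
#' Defines a uniform cell-centered Cartesian (or axisymmetric r-z) grid.
#' All lengths are in metres. 2-D Cartesian runs carry an explicit
#' out-of-plane \code{depth} so that concentrations integrate to absolute
#' exosome counts; axisymmetric grids integrate over the full revolution
#' and ignore \code{depth}.
#'
#' @param nx,ny number of cells along x (or r) and y (or z); at least 4.
#' @param dx,dy cell sizes (m), positive.
#' @param origin coordinates of the domain lower-left corner (m). For
#'   axisymmetric grids \code{origin[1]} is the radius of the inner edge
#'   and must be >= 0.
#' @param depth out-of-plane thickness (m) for Cartesian 2-D runs
#'   (default 1 m).
#' @param coord \code{"cartesian"} or \code{"axisymmetric"} (x plays the
#'   role of r, y of z).
#' @return an object of class \code{exo_grid_spec}.
#' @export
gridSpec <- function(nx, ny, dx, dy, origin = c(0, 0), depth = 1,
                     coord = c("cartesian", "axisymmetric")) {
  coord <- match.arg(coord)
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 4 || ny < 4 ||
      nx != round(nx) || ny != round(ny))
    stop("gridSpec: nx and ny must be integers >= 4", call. = FALSE)
  if (!is.numeric(dx) || !is.numeric(dy) || dx <= 0 || dy <= 0)
    stop("gridSpec: dx and dy must be positive", call. = FALSE)
  if (depth <= 0) stop("gridSpec: depth must be positive", call. = FALSE)
  if (length(origin) != 2 || !is.numeric(origin))
    stop("gridSpec: origin must be a numeric pair", call. = FALSE)
  if (coord == "axisymmetric" && origin[1] < 0)
    stop("gridSpec: axisymmetric origin[1] (inner radius) must be >= 0",
         call. = FALSE)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 dx = dx, dy = dy, origin = as.numeric(origin),
                 depth = depth, coord = coord),
            class = "exo_grid_spec")
}

#' Build a grid from its specification
#'
#' Computes cell-center and face coordinates, per-face areas and per-cell
#' volumes. For Cartesian grids areas/volumes include the out-of-plane
#' depth; axisymmetric volumes are full bodies of revolution
#' (V = pi (r_e^2 - r_w^2) dz).
#'
#' @param spec an \code{exo_grid_spec} from [gridSpec()].
#' @return an object of class \code{exo_grid} with fields \code{xc, yc}
#'   (cell-center coordinates), \code{xf, yf} (face coordinates),
#'   \code{V} (nx x ny cell volumes, m^3), \code{Ax} ((nx+1) x ny x-face
#'   areas, m^2), \code{Ay} (nx x (ny+1) y-face areas, m^2).
#' @export
buildGrid <- function(spec) {
  if (!inherits(spec, "exo_grid_spec")) spec <- do.call(gridSpec, spec)
  nx <- spec$nx; ny <- spec$ny; dx <- spec$dx; dy <- spec$dy
  xf <- spec$origin[1] + dx * (0:nx)
  yf <- spec$origin[2] + dy * (0:ny)
  xc <- xf[-1] - dx / 2
  yc <- yf[-1] - dy / 2
  if (spec$coord == "cartesian") {
    V  <- matrix(dx * dy * spec$depth, nx, ny)
    Ax <- matrix(dy * spec$depth, nx + 1, ny)
    Ay <- matrix(dx * spec$depth, nx, ny + 1)
  } else {
    # axisymmetric: x == r, y == z, full 2*pi revolution
    ring <- pi * (xf[-1]^2 - xf[-(nx + 1)]^2)        # annulus area per column
    V  <- matrix(ring * dy, nx, ny)
    Ax <- matrix(2 * pi * xf * dy, nx + 1, ny)
    Ay <- matrix(ring, nx, ny + 1)
  }
  structure(c(spec, list(xc = xc, yc = yc, xf = xf, yf = yf,
                         V = V, Ax = Ax, Ay = Ay)),
            class = "exo_grid")
}

#' @export
print.exo_grid <- function(x, ...) {
  cat(sprintf("<exo_grid> %s %d x %d cells, dx = %.4g m, dy = %.4g m\n",
              x$coord, x$nx, x$ny, x$dx, x$dy))
  cat(sprintf("  extent x: [%.4g, %.4g] m, y: [%.4g, %.4g] m, depth %.3g m\n",
              x$xf[1], x$xf[x$nx + 1], x$yf[1], x$yf[x$ny + 1], x$depth))
  invisible(x)
}

## ---- shapes and cell layouts ------------------------------------------------

#' Geometric shape constructors for cell layouts
#'
#' Circles and axis-aligned ellipses in physical coordinates (m).
#' @param center numeric pair (m).
#' @param radius circle radius (m).
#' @name shapes
#' @export
shapeCircle <- function(center, radius) {
  stopifnot(length(center) == 2, radius > 0)
  structure(list(kind = "circle", center = as.numeric(center),
                 radius = radius), class = "exo_shape")
}

#' @rdname shapes
#' @param a,b ellipse semi-axes along x and y (m).
#' @export
shapeEllipse <- function(center, a, b) {
  stopifnot(length(center) == 2, a > 0, b > 0)
  structure(list(kind = "ellipse", center = as.numeric(center),
                 a = a, b = b), class = "exo_shape")
}

pointInShape <- function(shape, x, y) {
  cx <- shape$center[1]; cy <- shape$center[2]
  if (shape$kind == "circle") {
    (x - cx)^2 + (y - cy)^2 <= shape$radius^2
  } else {
    ((x - cx) / shape$a)^2 + ((y - cy) / shape$b)^2 <= 1
  }
}

shapeArea <- function(shape) {
  if (shape$kind == "circle") pi * shape$radius^2 else pi * shape$a * shape$b
}

shapeBBox <- function(shape) {
  cx <- shape$center[1]; cy <- shape$center[2]
  if (shape$kind == "circle") {
    r <- shape$radius
    c(cx - r, cx + r, cy - r, cy + r)
  } else c(cx - shape$a, cx + shape$a, cy - shape$b, cy + shape$b)
}

#' Construct a cell layout for a tumor microenvironment
#'
#' A layout holds one tumor shape plus a list of immune cells (circles
#' with a type label: macrophage, tcell or mdsc), in physical metres.
#'
#' @param tumor an \code{exo_shape} (circle or ellipse).
#' @param immune list of immune-cell records; each a list with fields
#'   \code{center}, \code{radius}, \code{type}.
#' @param stage \code{"early"} or \code{"late"} tumor growth stage.
#' @return object of class \code{exo_layout}.
#' @export
cellLayout <- function(tumor, immune = list(), stage = c("early", "late")) {
  stage <- match.arg(stage)
  stopifnot(inherits(tumor, "exo_shape"))
  for (im in immune) {
    stopifnot(is.list(im), length(im$center) == 2, im$radius > 0,
              im$type %in% c("macrophage", "tcell", "mdsc", "immune"))
  }
  structure(list(tumor = tumor, immune = immune, stage = stage),
            class = "exo_layout")
}

layoutShapes <- function(layout) {
  c(list(layout$tumor),
    lapply(layout$immune, function(im) shapeCircle(im$center, im$radius)))
}

#' @export
print.exo_layout <- function(x, ...) {
  cat(sprintf("<exo_layout> stage %s: tumor %s (area %.3g m^2), %d immune cells\n",
              x$stage, x$tumor$kind, shapeArea(x$tumor), length(x$immune)))
  invisible(x)
}

## ---- rasterization ----------------------------------------------------------

#' Rasterize a cell layout onto a grid
#'
#' Cells whose centers fall inside any layout shape are marked SOLID
#' (blocked-cell method; no cut cells). Faces separating a FLUID cell
#' from a tumor SOLID cell are flagged as SOURCE faces: exosome release
#' is later distributed over them so the prescribed total rate is
#' honoured exactly regardless of rasterization error.
#'
#' @param layout an \code{exo_layout} (or \code{NULL} for an all-fluid mask).
#' @param grid an \code{exo_grid}.
#' @return object of class \code{exo_mask} with integer \code{label}
#'   matrix (0 fluid, 1 tumor, 2 immune), logical \code{solid}, and
#'   logical face matrices \code{source_fx} ((nx+1) x ny) and
#'   \code{source_fy} (nx x (ny+1)).
#' @export
rasterizeLayout <- function(layout, grid) {
  nx <- grid$nx; ny <- grid$ny
  label <- matrix(0L, nx, ny)
  if (!is.null(layout)) {
    xmin <- grid$xf[1]; xmax <- grid$xf[nx + 1]
    ymin <- grid$yf[1]; ymax <- grid$yf[ny + 1]
    for (s in layoutShapes(layout)) {
      bb <- shapeBBox(s)
      if (bb[1] < xmin || bb[2] > xmax || bb[3] < ymin || bb[4] > ymax)
        stop("rasterizeLayout: layout shape extends outside the grid",
             call. = FALSE)
    }
    X <- matrix(grid$xc, nx, ny)
    Y <- matrix(grid$yc, nx, ny, byrow = TRUE)
    inside_t <- pointInShape(layout$tumor, X, Y)
    label[inside_t] <- 1L
    for (im in layout$immune) {
      s <- shapeCircle(im$center, im$radius)
      label[pointInShape(s, X, Y) & label == 0L] <- 2L
    }
  }
  solid <- label > 0L
  if (!any(!solid)) stop("rasterizeLayout: no FLUID cells", call. = FALSE)
  tum <- label == 1L
  # interior x-faces between fluid and tumor cells
  source_fx <- matrix(FALSE, nx + 1, ny)
  source_fy <- matrix(FALSE, nx, ny + 1)
  fx <- (tum[-nx, , drop = FALSE] & !solid[-1, , drop = FALSE]) |
        (!solid[-nx, , drop = FALSE] & tum[-1, , drop = FALSE])
  source_fx[2:nx, ] <- fx
  fy <- (tum[, -ny, drop = FALSE] & !solid[, -1, drop = FALSE]) |
        (!solid[, -ny, drop = FALSE] & tum[, -1, drop = FALSE])
  source_fy[, 2:ny] <- fy
  structure(list(nx = nx, ny = ny, label = label, solid = solid,
                 source_fx = source_fx, source_fy = source_fy,
                 membrane = NULL),
            class = "exo_mask")
}

#' All-fluid mask for a grid
#' @param grid an \code{exo_grid}.
#' @export
emptyMask <- function(grid) rasterizeLayout(NULL, grid)

#' @export
print.exo_mask <- function(x, ...) {
  cat(sprintf("<exo_mask> %d x %d: %d SOLID (%d tumor), %d SOURCE faces\n",
              x$nx, x$ny, sum(x$solid), sum(x$label == 1L),
              sum(x$source_fx) + sum(x$source_fy)))
  invisible(x)
}

## ---- synthetic TME layout generator -----------------------------------------

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic two-stage TME layout
#'
#' Places a central tumor and non-overlapping immune cells (macrophages,
#' T cells, optionally MDSCs) uniformly at random in the free space of a
#' square domain, reproducibly from a seed. The late stage scales the
#' tumor radius by \code{late_scale} (default 1.8, i.e. 3.24x the area)
#' while keeping every immune cell position drawn from the same stream,
#' emulating tumor growth with increased obstruction to interstitial
#' flow. This is a synthetic stand-in for drawn/segmented TME geometries;
#' it reproduces their qualitative structure (one dominant obstacle plus
#' scattered small cells), not any particular published figure.
#'
#' @param stage \code{"early"} or \code{"late"}.
#' @param n_macrophages,n_tcells,n_mdsc immune cell counts (>= 0).
#' @param seed integer RNG seed; the layout is a pure function of
#'   (stage, counts, seed).
#' @param domain square side length (m); default 400 um.
#' @param tumor_radius early-stage tumor radius (m); default 40 um.
#' @param late_scale late/early tumor radius ratio (default 1.8).
#' @param immune_radius immune cell radius (m); default 6 um.
#' @param margin wall/inter-cell clearance (m).
#' @param max_tries placement retries before failing.
#' @return an \code{exo_layout}.
#' @export
generateTmeLayout <- function(stage = c("early", "late"),
                              n_macrophages = 6, n_tcells = 8, n_mdsc = 0,
                              seed = 1L,
                              domain = 400e-6,
                              tumor_radius = 40e-6,
                              late_scale = 1.8,
                              immune_radius = 6e-6,
                              margin = 8e-6,
                              max_tries = 4000L) {
  stage <- match.arg(stage)
  stopifnot(n_macrophages >= 0, n_tcells >= 0, n_mdsc >= 0)
  rt <- if (stage == "late") tumor_radius * late_scale else tumor_radius
  # late-stage placement uses the late tumor footprint so that the same
  # seed yields valid (non-overlapping) layouts at both stages
  r_excl <- tumor_radius * late_scale
  center <- c(domain / 2, domain / 2)
  tumor <- shapeCircle(center, rt)
  types <- c(rep("macrophage", n_macrophages), rep("tcell", n_tcells),
             rep("mdsc", n_mdsc))
  immune <- withSeed(seed, {
    placed <- list()
    for (ty in types) {
      ok <- FALSE
      for (k in seq_len(max_tries)) {
        lo <- immune_radius + margin
        p <- c(stats::runif(1, lo, domain - lo),
               stats::runif(1, lo, domain - lo))
        if (sqrt(sum((p - center)^2)) < r_excl + immune_radius + margin) next
        clash <- FALSE
        for (q in placed) {
          if (sqrt(sum((p - q$center)^2)) < q$radius + immune_radius + margin) {
            clash <- TRUE; break
          }
        }
        if (!clash) {
          placed[[length(placed) + 1L]] <-
            list(center = p, radius = immune_radius, type = ty)
          ok <- TRUE; break
        }
      }
      if (!ok)
        stop("generateTmeLayout: could not place immune cells without ",
             "overlap after ", max_tries, " tries", call. = FALSE)
    }
    placed
  })
  cellLayout(tumor, immune, stage)
}

#' Render a layout to a raster image
#'
#' Produces a single-channel intensity matrix (background 0, shape
#' interiors 1) at a requested pixel resolution; used to exercise the
#' image-segmentation pathway on ground-truth layouts.
#'
#' @param layout an \code{exo_layout}.
#' @param px pixels per side (square image).
#' @param domain physical side length (m) the image spans, lower-left at
#'   the origin.
#' @return list with \code{img} (px x px matrix, first index = x),
#'   \code{scale} (m per pixel).
#' @export
renderLayout <- function(layout, px = 256L, domain = 400e-6) {
  scale <- domain / px
  xs <- (seq_len(px) - 0.5) * scale
  X <- matrix(xs, px, px)
  Y <- matrix(xs, px, px, byrow = TRUE)
  img <- matrix(0, px, px)
  for (s in layoutShapes(layout)) img[pointInShape(s, X, Y)] <- 1
  list(img = img, scale = scale)
}
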