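# Ink-based contact area quantification: ROI-gated colour thresholding of the
# stamped fingerprint, connected-component cleaning, Moore-neighbour boundary
# tracing of the exterior outline, reference-bar pixel scaling, and the
# shoelace (Gauss) area formula in squared centimetres.

#' Ink image container
#'
#' @param raster RGB array (rows x cols x 3, values in 0-1) or a grayscale
#'   matrix.
#' @param bar_pixels length of the reference bar in pixels (> 0).
#' @param bar_length physical bar length (cm, default 5.0).
#' @return An \code{ink_image} list.
#' @export
ink_image <- function(raster, bar_pixels, bar_length = 5.0) {
  if (length(dim(raster)) == 2) {
    raster <- array(rep(raster, 3), dim = c(dim(raster), 3))
  }
  stopifnot(length(dim(raster)) == 3, dim(raster)[3] >= 3)
  if (prod(dim(raster)[1:2]) < 1) stop("raster must be non-empty")
  if (!is.finite(bar_pixels) || bar_pixels <= 0) {
    stop("scaling error: bar_pixels must be positive")
  }
  structure(list(raster = raster, bar_pixels = bar_pixels,
                 bar_length = bar_length),
            class = "ink_image")
}

#' Read an ink-stamped fingerprint image with its sidecar annotation
#'
#' Loads a PNG image and a JSON sidecar holding the reference-bar pixel length
#' and the analyst's region of interest (centre, radius).  If the sidecar
#' lacks \code{bar_pixels}, the bar is auto-detected as the longest dark
#' horizontal pixel run.
#'
#' @param path PNG file path.
#' @param sidecar JSON sidecar path (default \code{<path>.json}).
#' @return An \code{ink_image} with attribute \code{roi}
#'   (\code{c(row, col, radius)}).
#' @export
read_ink_image <- function(path, sidecar = paste0(path, ".json")) {
  raster <- png::readPNG(path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  bar <- meta$bar_pixels
  if (is.null(bar)) bar <- detect_reference_bar(raster)
  img <- ink_image(raster, bar_pixels = as.numeric(bar),
                   bar_length = if (!is.null(meta$bar_length_cm))
                     as.numeric(meta$bar_length_cm) else 5.0)
  if (!is.null(meta$roi)) {
    attr(img, "roi") <- as.numeric(unlist(meta$roi))
  }
  img
}

#' Auto-detect the reference bar
#'
#' Longest horizontal run of near-black pixels anywhere in the image.
#'
#' @param raster RGB array.
#' @param dark_max maximum mean channel value counted as bar ink.
#' @return Bar length in pixels.
#' @export
detect_reference_bar <- function(raster, dark_max = 0.15) {
  gray <- (raster[, , 1] + raster[, , 2] + raster[, , 3]) / 3
  best <- 0
  for (i in seq_len(nrow(gray))) {
    r <- rle(gray[i, ] < dark_max)
    runs <- r$lengths[r$values]
    if (length(runs)) best <- max(best, max(runs))
  }
  if (best < 2) stop("scaling error: reference bar not found")
  best
}

#' Pixel scale from the reference bar
#'
#' @param image an [ink_image()].
#' @return Scale in cm per pixel (\code{bar_length / bar_pixels}).
#' @examples
#' img <- ink_image(array(1, c(10, 10, 3)), bar_pixels = 500)
#' pixel_scale(img)  # 0.01 cm/px
#' @export
pixel_scale <- function(image) {
  stopifnot(inherits(image, "ink_image"))
  image$bar_length / image$bar_pixels
}

#' Threshold the inked contact region inside an analyst ROI
#'
#' Marks ink-coloured pixels (distance from paper white above
#' \code{color_threshold}) inside the circular region of interest, then cleans
#' the mask: speckle components below \code{min_component} pixels are dropped
#' and interior holes of the same size filled.
#'
#' @param image an [ink_image()].
#' @param roi_center \code{c(row, col)} centre of the region of interest.
#' @param roi_radius ROI radius in pixels.
#' @param color_threshold minimum RGB distance from white (0-1 scale,
#'   default 0.35).
#' @param min_component speckle/hole size threshold in pixels (default 25).
#' @return Logical mask matrix; warns (area 0) when empty.
#' @export
threshold_contact_region <- function(image, roi_center, roi_radius,
                                     color_threshold = 0.35,
                                     min_component = 25L) {
  stopifnot(inherits(image, "ink_image"))
  dm <- dim(image$raster)
  if (roi_center[1] < 1 || roi_center[1] > dm[1] ||
      roi_center[2] < 1 || roi_center[2] > dm[2]) {
    stop("ROI centre outside the raster")
  }
  dist_white <- sqrt((1 - image$raster[, , 1])^2 +
                     (1 - image$raster[, , 2])^2 +
                     (1 - image$raster[, , 3])^2)
  ri <- matrix(seq_len(dm[1]), dm[1], dm[2])
  ci <- matrix(seq_len(dm[2]), dm[1], dm[2], byrow = TRUE)
  roi <- (ri - roi_center[1])^2 + (ci - roi_center[2])^2 <= roi_radius^2
  mask <- roi & (dist_white > color_threshold)
  if (!any(mask)) {
    warning("no-contact: empty mask (area 0)")
    return(mask)
  }
  # drop small speckle components
  lab <- cc_label(mask)
  keep <- which(tabulate(lab[lab > 0]) >= min_component)
  mask <- matrix(lab %in% keep, dm[1], dm[2])
  # fill small interior holes (background components away from the ROI border)
  bg <- cc_label(!mask & roi)
  if (max(bg) > 0) {
    sizes <- tabulate(bg[bg > 0])
    fill <- which(sizes < min_component)
    if (length(fill)) mask[bg %in% fill] <- TRUE
  }
  mask
}

#' Trace the exterior outline of the contact region
#'
#' Moore-neighbour boundary tracing of the largest 8-connected component of
#' the mask (a warning is issued when several components exist).  Interior
#' holes are ignored: only the exterior outline is traced.
#'
#' @param mask logical matrix (TRUE = contact).
#' @param scale cm per pixel (default 1).
#' @param simplify drop collinear vertices (default TRUE).
#' @return A \code{contact_outline}: \code{polygon} (k x 2 matrix of (x, y) =
#'   (col, row) pixel coordinates) and \code{scale}.
#' @export
trace_outline <- function(mask, scale = 1, simplify = TRUE) {
  if (!any(mask)) stop("no-outline error: empty mask")
  lab <- cc_label(mask)
  ncomp <- max(lab)
  if (ncomp > 1) {
    warning(ncomp, " connected components; tracing the largest")
    big <- which.max(tabulate(lab[lab > 0]))
    mask <- lab == big
  }
  poly <- moore_trace(mask)
  if (simplify && nrow(poly) > 3) poly <- drop_collinear(poly)
  if (nrow(poly) < 3) {
    # single-pixel or line-like blob: expand to the pixel footprint
    px <- which(mask, arr.ind = TRUE)
    poly <- cbind(x = c(min(px[, 2]) - 0.5, max(px[, 2]) + 0.5,
                        max(px[, 2]) + 0.5, min(px[, 2]) - 0.5),
                  y = c(min(px[, 1]) - 0.5, min(px[, 1]) - 0.5,
                        max(px[, 1]) + 0.5, max(px[, 1]) + 0.5))
  }
  structure(list(polygon = poly, scale = scale), class = "contact_outline")
}

# Moore-neighbour tracing (Jacob's stopping criterion); returns the ordered
# boundary pixel centres (x = col, y = row) of a single 8-connected component.
moore_trace <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  at <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc && mask[i, j]
  # scan order: column-major; start = first TRUE pixel
  start <- which(mask)[1]
  si <- (start - 1) %% nr + 1
  sj <- (start - 1) %/% nr + 1
  # Moore neighbourhood, clockwise starting from W
  di <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dj <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  path_i <- si
  path_j <- sj
  ci <- si
  cj <- sj
  entry <- 1L # came from the west
  first_dir <- NA_integer_
  repeat {
    found <- FALSE
    for (s in 0:7) {
      k <- ((entry - 1L + s) %% 8L) + 1L
      ni <- ci + di[k]
      nj <- cj + dj[k]
      if (at(ni, nj)) {
        if (ci == si && cj == sj) {
          if (is.na(first_dir)) {
            first_dir <- k
          } else if (k == first_dir && length(path_i) > 1) {
            return(cbind(x = path_j, y = path_i))
          }
        }
        ci <- ni
        cj <- nj
        path_i <- c(path_i, ci)
        path_j <- c(path_j, cj)
        # restart the clockwise scan just after the backtrack direction
        entry <- (((k - 1L) + 5L) %% 8L) + 1L
        found <- TRUE
        break
      }
    }
    if (!found) return(cbind(x = sj, y = si)) # isolated pixel
    if (length(path_i) > 8L * sum(mask) + 8L) {
      return(cbind(x = path_j, y = path_i))
    }
  }
}

drop_collinear <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(poly)
  # closed polygon: drop last vertex if equal to first
  if (all(poly[n, ] == poly[1, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1
  }
  keep <- logical(n)
  for (i in seq_len(n)) {
    p <- poly[(i - 2) %% n + 1, ]
    q <- poly[i, ]
    r <- poly[i %% n + 1, ]
    cross <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    keep[i] <- abs(cross) > 1e-9
  }
  if (sum(keep) >= 3) poly[keep, , drop = FALSE] else poly
}

#' Polygon area by the shoelace (Gauss) formula
#'
#' \eqn{A = |\sum_i (x_i y_{i+1} - x_{i+1} y_i)| / 2 \times scale^2}, in
#' squared centimetres.  Invariant to the starting vertex and to orientation.
#'
#' @param outline a [trace_outline()] result, or a list with \code{polygon}
#'   (k x 2) and \code{scale}.
#' @param check_simple verify the polygon is simple (non-self-intersecting);
#'   skipped for polygons with more than \code{max_check} vertices (tracer
#'   output is simple by construction).
#' @param max_check vertex-count cap for the quadratic simplicity check.
#' @return Area in cm^2.
#' @examples
#' tri <- structure(list(polygon = cbind(c(0, 4, 0), c(0, 0, 3)), scale = 1),
#'                  class = "contact_outline")
#' polygon_area(tri)  # 6
#' @export
polygon_area <- function(outline, check_simple = TRUE, max_check = 400L) {
  poly <- outline$polygon
  scale <- outline$scale
  if (is.null(scale) || !is.finite(scale) || scale <= 0) {
    stop("outline scale must be positive")
  }
  if (is.null(dim(poly)) || nrow(poly) < 3) {
    stop("polygon needs at least 3 vertices")
  }
  if (all(poly[nrow(poly), ] == poly[1, ])) poly <- poly[-nrow(poly), , drop = FALSE]
  n <- nrow(poly)
  if (n < 3) stop("polygon needs at least 3 vertices")
  if (check_simple && n <= max_check && !is_simple_polygon(poly)) {
    stop("polygon is self-intersecting")
  }
  x <- poly[, 1]
  y <- poly[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2 * scale^2
}

is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[i %% n + 1, ])
  inter <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next # adjacent via wrap
      s1 <- seg(i)
      s2 <- seg(j)
      if (inter(s1[1, ], s1[2, ], s2[1, ], s2[2, ])) return(FALSE)
    }
  }
  TRUE
}

#' Measure contact area from an ink image (end-to-end)
#'
#' Thresholds the contact region inside the ROI, traces the exterior outline
#' of the largest component, scales pixels by the reference bar, and applies
#' the shoelace formula.
#'
#' @param image an [ink_image()].
#' @param roi_center,roi_radius analyst region of interest (pixels); defaults
#'   to the sidecar ROI stored on the image, if any.
#' @param ... passed to [threshold_contact_region()].
#' @return List: \code{area_cm2}, \code{outline}, \code{mask},
#'   \code{scale_cm_px}.
#' @export
measure_contact_area <- function(image, roi_center = NULL, roi_radius = NULL,
                                 ...) {
  roi <- attr(image, "roi")
  if (is.null(roi_center) && !is.null(roi)) roi_center <- roi[1:2]
  if (is.null(roi_radius) && !is.null(roi)) roi_radius <- roi[3]
  if (is.null(roi_center) || is.null(roi_radius)) {
    stop("an ROI (centre, radius) is required")
  }
  sc <- pixel_scale(image)
  mask <- threshold_contact_region(image, roi_center, roi_radius, ...)
  if (!any(mask)) {
    return(list(area_cm2 = 0, outline = NULL, mask = mask, scale_cm_px = sc))
  }
  outline <- trace_outline(mask, scale = sc)
  list(area_cm2 = polygon_area(outline, check_simple = FALSE),
       outline = outline, mask = mask, scale_cm_px = sc)
}
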