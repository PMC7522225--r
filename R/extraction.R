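# Heatmap decoding, ETDRS grid placement, laterality handling and
# pixel-sample extraction.

#' Thickness map container
#'
#' @param values numeric matrix of thickness in um.
#' @param missing logical matrix of the same shape flagging unmeasured
#'   pixels; defaults to non-finite entries of `values`.
#' @param pixel_spacing mm per pixel.
#' @param center fovea position as (row, col) in 1-based pixel coordinates
#'   (row 1 at the top); defaults to the middle of the grid.
#' @param laterality `"left"` or `"right"`.
#' @return an object of class `thickness_map`.
#' @export
thickness_map <- function(values, missing = NULL, pixel_spacing = 0.05,
                          center = NULL, laterality = "right") {
  values <- as.matrix(values)
  if (is.null(missing)) missing <- !is.finite(values)
  missing <- as.matrix(missing)
  if (!identical(dim(values), dim(missing)))
    stop_invalid("`values` and `missing` must have the same shape")
  if (pixel_spacing <= 0) stop_invalid("`pixel_spacing` must be > 0")
  if (!laterality %in% c("left", "right"))
    stop_invalid("`laterality` must be \"left\" or \"right\"")
  if (any(!is.finite(values[!missing])) || any(values[!missing] < 0))
    stop_invalid("non-missing thickness values must be finite and >= 0")
  if (is.null(center))
    center <- c((nrow(values) + 1) / 2, (ncol(values) + 1) / 2)
  structure(list(values = values, missing = missing,
                 pixel_spacing = pixel_spacing, center = center,
                 laterality = laterality, flipped = FALSE),
            class = "thickness_map")
}

#' Colorbar definition for heatmap encoding/decoding
#'
#' @param values strictly increasing thickness values (um), one per entry.
#' @param colors integer matrix (entries x 3) of 8-bit RGB colours; rows
#'   must be distinct.
#' @param background reserved RGB triple painted for missing pixels.
#' @return an object of class `colorbar`.
#' @export
colorbar <- function(values, colors, background = c(0L, 0L, 0L)) {
  colors <- as.matrix(colors)
  if (length(values) == 0) stop_invalid("empty colorbar")
  if (any(diff(values) <= 0))
    stop_invalid("colorbar values must be strictly increasing")
  if (ncol(colors) != 3 || nrow(colors) != length(values))
    stop_invalid("`colors` must be an (entries x 3) matrix")
  if (anyDuplicated(colors) > 0)
    stop_invalid("colorbar colours must be distinct")
  structure(list(values = values, colors = colors,
                 background = as.integer(background)),
            class = "colorbar")
}

#' Default viridis-style colorbar over a thickness range
#'
#' @param range thickness range covered, um.
#' @param n number of entries.
#' @return a [colorbar()] with black background.
#' @export
default_colorbar <- function(range = c(0, 160), n = 128) {
  cols <- t(col2rgb(hcl.colors(n, "viridis")))
  colorbar(seq(range[1], range[2], length.out = n), cols,
           background = c(0L, 0L, 0L))
}

#' Place the ETDRS grid on a pixel raster
#'
#' Labels every pixel by the ETDRS annulus containing its centre: the
#' central disc (diameter 1 mm), inner ring (1-3 mm) or outer ring
#' (3-6 mm); pixels at 3 mm radius or beyond are outside the grid.
#'
#' @param shape integer (rows, cols) of the raster.
#' @param center fovea position, 1-based (row, col).
#' @param pixel_spacing mm per pixel; > 0.
#' @return an object of class `etdrs_mask` with an integer `labels` matrix
#'   (0 outside, 1 centre disc, 2 inner ring, 3 outer ring).
#' @export
build_etdrs_mask <- function(shape, center, pixel_spacing) {
  if (pixel_spacing <= 0) stop_invalid("`pixel_spacing` must be > 0")
  nr <- shape[1]; nc <- shape[2]
  r_mm <- pixel_spacing * sqrt(
    outer((seq_len(nr) - center[1])^2, (seq_len(nc) - center[2])^2, `+`))
  labels <- matrix(0L, nr, nc)
  labels[r_mm < 3.0] <- 3L
  labels[r_mm < 1.5] <- 2L
  labels[r_mm < 0.5] <- 1L
  structure(list(labels = labels, pixel_spacing = pixel_spacing,
                 center = center),
            class = "etdrs_mask")
}

#' Decode an RGB heatmap into a thickness map
#'
#' Each pixel is assigned the thickness of the colorbar entry with minimum
#' Euclidean colour distance (ties towards the lower-valued entry).  Pixels
#' whose nearest colour is the background, or whose colour distance exceeds
#' the tolerance, are flagged missing.
#'
#' @param rgb numeric or integer array (rows x cols x 3); either 8-bit
#'   values in 0..255 or normalised values in \[0, 1\].
#' @param cbar a [colorbar()].
#' @param tolerance maximum accepted colour distance (8-bit units); default
#'   3 times the minimum distance between adjacent colorbar colours.
#' @param pixel_spacing,center,laterality metadata for the returned map
#'   (from the cohort manifest; fovea detection is out of scope).
#' @return a [thickness_map()].
#' @export
decode_thickness_image <- function(rgb, cbar, tolerance = NULL,
                                   pixel_spacing = 0.05, center = NULL,
                                   laterality = "right") {
  stopifnot(inherits(cbar, "colorbar"))
  if (length(dim(rgb)) != 3 || dim(rgb)[3] < 3)
    stop_invalid("`rgb` must be a (rows x cols x 3) array")
  if (max(rgb, na.rm = TRUE) <= 1) rgb <- rgb * 255
  nr <- dim(rgb)[1]; nc <- dim(rgb)[2]
  px <- cbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
              as.vector(rgb[, , 3]))
  pal <- rbind(cbar$colors, cbar$background)
  K <- nrow(pal)
  best <- rep.int(1L, nrow(px))
  bestd <- rowSums((px - matrix(pal[1, ], nrow(px), 3, byrow = TRUE))^2)
  for (k in seq_len(K)[-1]) {
    d <- rowSums((px - matrix(pal[k, ], nrow(px), 3, byrow = TRUE))^2)
    upd <- d < bestd          # strict: ties keep the earlier (lower) entry
    best[upd] <- k
    bestd[upd] <- d[upd]
  }
  if (is.null(tolerance)) {
    gaps <- sqrt(rowSums((cbar$colors[-1, , drop = FALSE] -
                          cbar$colors[-nrow(cbar$colors), , drop = FALSE])^2))
    tolerance <- 3 * min(gaps)
  }
  is_bg <- best == K
  miss <- is_bg | sqrt(bestd) > tolerance
  vals <- cbar$values[pmin(best, K - 1L)]
  vals[miss] <- NA_real_
  thickness_map(matrix(vals, nr, nc), missing = matrix(miss, nr, nc),
                pixel_spacing = pixel_spacing, center = center,
                laterality = laterality)
}

#' Orient a thickness map to right-eye convention
#'
#' Left-eye maps are mirrored about the vertical axis (columns reversed,
#' fovea column remapped) so every oriented map is in right-eye coordinates;
#' right-eye maps pass through unchanged.  Applying the function to an
#' already-oriented (flipped) map undoes the flip, so the operation is an
#' involution on flipped maps.  The multiset of non-missing values is
#' always preserved.
#'
#' @param map a [thickness_map()].
#' @return the oriented map.
#' @export
orient_map <- function(map) {
  stopifnot(inherits(map, "thickness_map"))
  flip <- function(m) {
    nc <- ncol(m$values)
    m$values <- m$values[, nc:1, drop = FALSE]
    m$missing <- m$missing[, nc:1, drop = FALSE]
    m$center[2] <- nc + 1 - m$center[2]
    m
  }
  if (map$laterality == "left" && !map$flipped) {
    map <- flip(map)
    map$laterality <- "right"
    map$flipped <- TRUE
  } else if (map$flipped) {
    map <- flip(map)
    map$laterality <- "left"
    map$flipped <- FALSE
  }
  map
}

#' Pixel-thickness sample for one subject and layer
#'
#' @param values numeric vector of thickness values (um), no missing.
#' @param subject_id,layer provenance labels.
#' @param n_excluded_missing count of in-grid pixels dropped as missing.
#' @return an object of class `pixel_sample`.
#' @export
pixel_sample <- function(values, subject_id = NA_character_,
                         layer = NA_character_, n_excluded_missing = 0L) {
  if (any(!is.finite(values)) || any(values < 0))
    stop_invalid("pixel sample values must be finite and >= 0")
  structure(list(values = as.numeric(values), subject_id = subject_id,
                 layer = layer,
                 n_excluded_missing = as.integer(n_excluded_missing)),
            class = "pixel_sample")
}

#' Extract the in-grid pixel sample from a thickness map
#'
#' Returns thickness values at every pixel inside the 6 mm ETDRS disc that
#' is not flagged missing, and records how many in-grid pixels were
#' excluded as missing.
#'
#' @param map a [thickness_map()].
#' @param mask an [build_etdrs_mask()] result of matching shape.
#' @param subject_id,layer provenance labels carried into the sample.
#' @return a [pixel_sample()].
#' @export
extract_pixels <- function(map, mask, subject_id = NA_character_,
                           layer = NA_character_) {
  stopifnot(inherits(map, "thickness_map"), inherits(mask, "etdrs_mask"))
  if (!identical(dim(map$values), dim(mask$labels)))
    stop_invalid("map and mask shapes disagree")
  in_grid <- mask$labels > 0L
  keep <- in_grid & !map$missing
  pixel_sample(map$values[keep], subject_id = subject_id, layer = layer,
               n_excluded_missing = sum(in_grid & map$missing))
}
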