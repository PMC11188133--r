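#' @include wsi-prep.R
NULL

#' Heatmap rendering specification
#'
#' @param mode `"attention"` (continuous colormap over normalized attention
#'   weights) or `"contribution"` (binary painting: excitatory patches red,
#'   inhibitory patches blue).
#' @param colormap colormap name for attention mode, passed to
#'   [grDevices::hcl.colors()] (default `"viridis"`, perceptually uniform).
#' @param alpha overlay opacity in \[0, 1\].
#' @param normalization `"minmax"` (per-slide, the default: raw attention
#'   scales with bag size) or `"none"` for attention mode.
#' @return a spec list of class `"HeatmapSpec"`.
#' @export
heatmapSpec <- function(mode = c("attention", "contribution"),
                        colormap = "viridis", alpha = 0.6,
                        normalization = c("minmax", "none")) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  structure(list(mode = mode, colormap = colormap, alpha = alpha,
                 normalization = normalization),
            class = "HeatmapSpec")
}

#' Rasterize per-tile scores onto the thumbnail grid
#'
#' Fills each tile's footprint at thumbnail resolution with its score;
#' overlapping tiles are resolved by the mean of their scores; pixels covered
#' by no tile are NA (no-data).
#'
#' @param scores numeric vector, one score per tile.
#' @param coords integer matrix of tile origins (columns x, y; 0-based, at
#'   the tiles' magnification).
#' @param ratio downsample factor from the tile magnification to the
#'   thumbnail.
#' @param thumbDim thumbnail dimensions c(width, height) in pixels.
#' @param tileSize tile side at the tile magnification (default 512).
#' @return numeric height x width matrix with NA where no tile painted.
#' @export
scoresToGrid <- function(scores, coords, ratio, thumbDim,
                         tileSize = TILE_SIDE) {
  if (length(scores) != nrow(coords))
    stop("one score per tile coordinate required")
  W <- thumbDim[1L]; H <- thumbDim[2L]
  acc <- matrix(0, H, W); cnt <- matrix(0L, H, W)
  for (i in seq_len(nrow(coords))) {
    x0 <- coords[i, 1L]; y0 <- coords[i, 2L]
    if (x0 < 0 || y0 < 0 || x0 / ratio >= W || y0 / ratio >= H)
      stop("tile ", i, " at origin (", x0, ", ", y0,
           ") lies outside the thumbnail bounds")
    xs <- (floor(x0 / ratio) + 1L):min(ceiling((x0 + tileSize) / ratio), W)
    ys <- (floor(y0 / ratio) + 1L):min(ceiling((y0 + tileSize) / ratio), H)
    acc[ys, xs] <- acc[ys, xs] + scores[i]
    cnt[ys, xs] <- cnt[ys, xs] + 1L
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  out
}

#' Render an attention heatmap overlay
#'
#' Min-max normalizes the painted pixels (unless disabled), maps them through
#' the colormap and returns an RGBA overlay; no-data pixels are fully
#' transparent. A constant grid maps to the colormap midpoint.
#'
#' @param grid score raster from [scoresToGrid()].
#' @param spec a [heatmapSpec()] with mode `"attention"`.
#' @return height x width x 4 RGBA array with values in \[0, 1\].
#' @export
renderAttention <- function(grid, spec = heatmapSpec("attention")) {
  if (spec$mode != "attention") stop("spec mode must be 'attention'")
  data <- !is.na(grid)
  if (!any(data)) stop("grid contains no painted pixels")
  v <- grid
  if (spec$normalization == "minmax") {
    rng <- range(v[data])
    v[data] <- if (diff(rng) == 0) 0.5 else (v[data] - rng[1L]) / diff(rng)
  } else {
    v[data] <- pmin(pmax(v[data], 0), 1)
  }
  pal <- grDevices::hcl.colors(256L, spec$colormap)
  rgb <- grDevices::col2rgb(pal) / 255
  idx <- matrix(NA_integer_, nrow(grid), ncol(grid))
  idx[data] <- pmin(floor(v[data] * 256) + 1L, 256L)
  out <- array(0, dim = c(nrow(grid), ncol(grid), 4L))
  for (ch in 1:3) {
    plane <- matrix(0, nrow(grid), ncol(grid))
    plane[data] <- rgb[ch, idx[data]]
    out[, , ch] <- plane
  }
  alpha <- matrix(0, nrow(grid), ncol(grid))
  alpha[data] <- spec$alpha
  out[, , 4L] <- alpha
  out
}

#' Render an excitatory/inhibitory contribution overlay
#'
#' Paints each tile footprint red when its sigmoid-bounded contribution is in
#' \[0.5, 1) (excitatory) and blue when it is in (0, 0.5) (inhibitory); the
#' boundary value 0.5 is excitatory. Scores must lie strictly inside (0, 1).
#'
#' @param grid bounded-score raster from [scoresToGrid()].
#' @param spec a [heatmapSpec()] with mode `"contribution"`.
#' @return height x width x 4 RGBA array with values in \[0, 1\].
#' @export
renderContribution <- function(grid, spec = heatmapSpec("contribution")) {
  if (spec$mode != "contribution") stop("spec mode must be 'contribution'")
  data <- !is.na(grid)
  if (!any(data)) stop("grid contains no painted pixels")
  vals <- grid[data]
  if (any(vals <= 0) || any(vals >= 1))
    stop("bounded contribution scores must lie strictly in (0, 1)")
  out <- array(0, dim = c(nrow(grid), ncol(grid), 4L))
  red <- data & grid >= 0.5
  blue <- data & grid < 0.5
  r <- matrix(0, nrow(grid), ncol(grid)); r[red] <- 1
  b <- matrix(0, nrow(grid), ncol(grid)); b[blue] <- 1
  out[, , 1L] <- r
  out[, , 3L] <- b
  alpha <- matrix(0, nrow(grid), ncol(grid))
  alpha[data] <- spec$alpha
  out[, , 4L] <- alpha
  out
}

#' Alpha-composite an RGBA overlay onto a slide thumbnail
#'
#' @param thumbnail height x width x 3 RGB array (0-255).
#' @param overlay height x width x 4 RGBA array in \[0, 1\] from
#'   [renderAttention()] or [renderContribution()].
#' @return height x width x 3 RGB array (0-255).
#' @export
paintSlide <- function(thumbnail, overlay) {
  if (!all(dim(thumbnail)[1:2] == dim(overlay)[1:2]))
    stop("thumbnail and overlay dimensions differ")
  out <- thumbnail
  a <- overlay[, , 4L]
  for (ch in 1:3)
    out[, , ch] <- (1 - a) * thumbnail[, , ch] + a * overlay[, , ch] * 255
  out
}

#' Write an RGBA overlay as PNG bytes
#'
#' Rendering is pure: identical inputs produce byte-identical PNGs.
#'
#' @param overlay RGBA array in \[0, 1\].
#' @param path output path, or NULL to return the raw bytes.
#' @return the path (invisibly) or a raw vector.
#' @export
writeOverlayPng <- function(overlay, path = NULL) {
  if (is.null(path)) return(png::writePNG(overlay))
  png::writePNG(overlay, path)
  invisible(path)
}

#' Per-tile score table for one bag prediction
#'
#' @param bag a [MILBag-class] with tile coordinates.
#' @param prediction the [BagPrediction-class] for that bag.
#' @param mag magnification tag.
#' @return data.frame with slide_id, mag, x, y, attention and (for additive
#'   architectures) contribution_bounded.
#' @export
tileScoresTable <- function(bag, prediction, mag = "5x") {
  co <- tileCoords(bag)
  if (nrow(co) == 0L) stop("bag has no tile coordinates")
  out <- data.frame(slide_id = bagId(bag), mag = mag,
                    x = co[, 1L], y = co[, 2L],
                    attention = prediction@attentionWeights)
  if (length(prediction@bounded))
    out$contribution_bounded <- prediction@bounded
  out
}
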