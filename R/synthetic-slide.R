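#' @include utils.R
NULL

#' Specification of a synthetic slide image
#'
#' Describes a slide thumbnail-like RGB image: dark tissue blobs on a light
#' background, optionally crossed by pen-colored artifact strokes (emulating
#' the marker annotations and preparation artifacts found on real slides).
#' Ground-truth tissue and artifact masks are returned alongside the image so
#' the preprocessing filters can be validated exactly.
#'
#' @param width,height canvas size in pixels (>= 32).
#' @param nTissueBlobs number of tissue blobs.
#' @param blobRadiusRange pixel interval (min, max) for blob radii; blobs lie
#'   fully inside the canvas.
#' @param backgroundColor,tissueColor,penColor RGB triples in \[0, 255\].
#' @param artifactStrokes number of pen strokes.
#' @param strokeWidth stroke half-width in pixels.
#' @param noiseSd per-pixel Gaussian color noise (0-255 units).
#' @param seed integer seed.
#' @return a validated spec of class `"SyntheticSlideSpec"`.
#' @export
slideSimSpec <- function(width = 1024L, height = 1024L, nTissueBlobs = 5L,
                         blobRadiusRange = c(60L, 140L),
                         backgroundColor = c(235, 233, 231),
                         tissueColor = c(150, 90, 140),
                         artifactStrokes = 0L, penColor = c(30, 110, 60),
                         strokeWidth = 3L, noiseSd = 4, seed = 1L) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 32L || height < 32L)
    stop("degenerate canvas: each side must be >= 32 px")
  for (cc in list(backgroundColor, tissueColor, penColor))
    if (length(cc) != 3L || any(cc < 0) || any(cc > 255))
      stop("colors must be RGB triples in [0, 255]")
  blobRadiusRange <- as.integer(round(blobRadiusRange))
  if (blobRadiusRange[1L] < 1L || blobRadiusRange[2L] < blobRadiusRange[1L])
    stop("blobRadiusRange must be an increasing interval with min >= 1")
  if (2L * blobRadiusRange[2L] >= min(width, height))
    stop("largest blob radius does not fit inside the canvas")
  structure(list(width = width, height = height,
                 nTissueBlobs = as.integer(nTissueBlobs),
                 blobRadiusRange = blobRadiusRange,
                 backgroundColor = backgroundColor,
                 tissueColor = tissueColor,
                 artifactStrokes = as.integer(artifactStrokes),
                 penColor = penColor, strokeWidth = as.integer(strokeWidth),
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "SyntheticSlideSpec")
}

## filled-disk pixel mask (height x width logical), center/radius in pixels
diskMask <- function(height, width, cx, cy, r) {
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

#' Generate a synthetic slide with ground-truth masks
#'
#' @param spec a [slideSimSpec()] object.
#' @return list with `image` (height x width x 3 array, values 0-255),
#'   `tissueMask` and `artifactMask` (logical height x width matrices, exact
#'   by construction).
#' @export
generateSyntheticSlide <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSlideSpec"))
  H <- spec$height; W <- spec$width
  withSeed(spec$seed, {
    tissue <- matrix(FALSE, H, W)
    for (i in seq_len(spec$nTissueBlobs)) {
      r <- if (spec$blobRadiusRange[1L] == spec$blobRadiusRange[2L])
        spec$blobRadiusRange[1L]
      else sample(spec$blobRadiusRange[1L]:spec$blobRadiusRange[2L], 1L)
      cx <- sample((r + 1L):(W - r), 1L)
      cy <- sample((r + 1L):(H - r), 1L)
      tissue <- tissue | diskMask(H, W, cx, cy, r)
    }
    artifact <- matrix(FALSE, H, W)
    if (spec$artifactStrokes > 0L) {
      xs <- matrix(seq_len(W), H, W, byrow = TRUE)
      ys <- matrix(seq_len(H), H, W)
      for (i in seq_len(spec$artifactStrokes)) {
        ## a straight stroke between two random border-ish points
        p0 <- c(stats::runif(1, 1, W), stats::runif(1, 1, H))
        p1 <- c(stats::runif(1, 1, W), stats::runif(1, 1, H))
        v <- p1 - p0
        len2 <- sum(v^2)
        if (len2 < 1) next
        t <- ((xs - p0[1]) * v[1] + (ys - p0[2]) * v[2]) / len2
        t <- pmin(pmax(t, 0), 1)
        d2 <- (xs - (p0[1] + t * v[1]))^2 + (ys - (p0[2] + t * v[2]))^2
        artifact <- artifact | (d2 <= spec$strokeWidth^2)
      }
    }
    img <- array(0, dim = c(H, W, 3L))
    for (ch in 1:3) {
      plane <- matrix(spec$backgroundColor[ch], H, W)
      plane[tissue] <- spec$tissueColor[ch]
      plane[artifact] <- spec$penColor[ch]
      if (spec$noiseSd > 0)
        plane <- plane + matrix(stats::rnorm(H * W, sd = spec$noiseSd), H, W)
      img[, , ch] <- pmin(pmax(round(plane), 0), 255)
    }
    list(image = img, tissueMask = tissue, artifactMask = artifact)
  })
}
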