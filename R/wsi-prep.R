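#' @include utils.R
NULL

TILE_SIDE <- 512L

#' Preprocessing configuration
#'
#' Thresholds of the tile preprocessing pipeline. The color-distance and
#' tissue-fraction thresholds, the closing kernel and the sampling limits are
#' deliberately configurable; the defaults are sane for the synthetic
#' fixtures and every run records the values used.
#'
#' @param closeKernelRadius disk radius (px) of the morphological closing
#'   applied to the Otsu tissue mask.
#' @param colorDistanceThreshold Euclidean RGB distance (0-255 units) beyond
#'   which a tissue pixel is treated as an artifact.
#' @param tissueFractionThreshold minimum fraction of tissue pixels a tile
#'   must contain to be kept, in \[0, 1\].
#' @param sampleFraction5x fraction of filtered 5x tiles sampled when their
#'   count exceeds `tileCountLimit5x` (default 0.6).
#' @param tileCountLimit5x tile-count limit that triggers 5x sampling.
#' @param kmeansK number of K-means clusters for hierarchical sampling.
#' @param tilesPerCluster maximum tiles sampled per cluster (default 20).
#' @param thumbnailMaxSide maximum thumbnail side in pixels.
#' @param seed integer seed for all sampling.
#' @return a config list of class `"PrepConfig"`.
#' @export
prepConfig <- function(closeKernelRadius = 2L, colorDistanceThreshold = 60,
                       tissueFractionThreshold = 0.25, sampleFraction5x = 0.6,
                       tileCountLimit5x = 500L, kmeansK = 8L,
                       tilesPerCluster = 20L, thumbnailMaxSide = 1024L,
                       seed = 1L) {
  if (tissueFractionThreshold < 0 || tissueFractionThreshold > 1)
    stop("tissueFractionThreshold must lie in [0, 1]")
  if (sampleFraction5x <= 0 || sampleFraction5x > 1)
    stop("sampleFraction5x must lie in (0, 1]")
  if (colorDistanceThreshold < 0) stop("colorDistanceThreshold must be >= 0")
  if (kmeansK < 1L) stop("kmeansK must be >= 1")
  structure(list(closeKernelRadius = as.integer(closeKernelRadius),
                 colorDistanceThreshold = colorDistanceThreshold,
                 tissueFractionThreshold = tissueFractionThreshold,
                 sampleFraction5x = sampleFraction5x,
                 tileCountLimit5x = as.integer(tileCountLimit5x),
                 kmeansK = as.integer(kmeansK),
                 tilesPerCluster = as.integer(tilesPerCluster),
                 thumbnailMaxSide = as.integer(thumbnailMaxSide),
                 seed = as.integer(seed)),
            class = "PrepConfig")
}

#' Slide metadata record
#'
#' @param slideId slide identifier.
#' @param label binary slide label.
#' @param slideType `"flash_frozen"` or `"ffpe"`.
#' @param mpp microns per pixel at scan magnification (> 0).
#' @param levelDownsamples per-level downsample factors, nondecreasing,
#'   starting at 1 for the base level.
#' @param baseMag scan magnification of the base level (e.g. 20 for 20x).
#' @return a list of class `"SlideMetadata"`.
#' @export
slideMetadata <- function(slideId, label, slideType = c("flash_frozen", "ffpe"),
                          mpp = 1.0, levelDownsamples = 1, baseMag = 20) {
  slideType <- match.arg(slideType)
  if (mpp <= 0) stop("mpp must be positive")
  if (any(levelDownsamples < 1) || is.unsorted(levelDownsamples))
    stop("level downsamples must be >= 1 and nondecreasing toward thumbnail")
  structure(list(slideId = as.character(slideId), label = as.integer(label),
                 slideType = slideType, mpp = mpp,
                 levelDownsamples = levelDownsamples, baseMag = baseMag),
            class = "SlideMetadata")
}

#' Extract slide metadata and append it to a CSV
#'
#' Collects id, label, slide type, microns-per-pixel and pyramid levels for
#' each slide and writes one CSV row per slide. Re-runs are idempotent:
#' rows are keyed by `slide_id` and overwritten. Unreadable sources are
#' recorded as skipped with a reason.
#'
#' @param slides list of slide descriptors; each a list with `slideId`,
#'   `label`, `slideType`, `mpp` and either `image` (array) or `path` (PNG
#'   or TIFF file).
#' @param csvPath path of the metadata CSV (created if missing).
#' @return data.frame of the rows written; skipped slides are attached as the
#'   `"skipped"` attribute.
#' @export
extractMetadata <- function(slides, csvPath = NULL) {
  rows <- list(); skipped <- list()
  for (s in slides) {
    img <- s$image
    if (is.null(img) && !is.null(s$path)) {
      img <- tryCatch(readSlideImage(s$path), error = function(e) NULL)
      if (is.null(img)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(slide_id = s$slideId, reason = "unreadable file")
        next
      }
    }
    if (is.null(img)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(slide_id = s$slideId, reason = "no image source")
      next
    }
    ds <- s$levelDownsamples
    if (is.null(ds)) ds <- 1          # plain images get a single-level pyramid
    rows[[length(rows) + 1L]] <- data.frame(
      slide_id = as.character(s$slideId), label = as.integer(s$label),
      slide_type = if (is.null(s$slideType)) "flash_frozen" else s$slideType,
      mpp = if (is.null(s$mpp)) 1.0 else s$mpp,
      levels = paste(ds, collapse = ";"),
      width = ncol(img), height = nrow(img))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slide_id = character(0), label = integer(0),
               slide_type = character(0), mpp = numeric(0),
               levels = character(0), width = integer(0), height = integer(0))
  if (!is.null(csvPath)) {
    if (file.exists(csvPath)) {
      old <- utils::read.csv(csvPath, colClasses = c(slide_id = "character"))
      old <- old[!old$slide_id %in% out$slide_id, , drop = FALSE]
      out <- rbind(old, out)
    }
    utils::write.csv(out, csvPath, row.names = FALSE)
  }
  if (length(skipped)) {
    warning(length(skipped), " slide(s) skipped")
    attr(out, "skipped") <- do.call(rbind, skipped)
  }
  out
}

#' Read a plain slide image (PNG or TIFF) as a 0-255 RGB array
#'
#' @param path image file.
#' @return height x width x 3 numeric array with values in 0-255.
#' @export
readSlideImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)        # width x height (x channels), 0-1
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  aperm(a, c(2L, 1L, 3L)) * 255
}

#' Write a 0-255 RGB array as a PNG file
#'
#' @param img height x width x 3 array, values 0-255.
#' @param path output path.
#' @export
writeSlideImage <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}

## block-mean downsample of an RGB array by an integer factor (deterministic)
downsampleImage <- function(img, factor) {
  if (factor == 1L) return(img)
  H <- nrow(img); W <- ncol(img)
  stopifnot(H %% factor == 0L, W %% factor == 0L)
  rb <- (seq_len(H) - 1L) %/% factor + 1L
  cb <- (seq_len(W) - 1L) %/% factor + 1L
  out <- array(0, dim = c(H %/% factor, W %/% factor, 3L))
  for (ch in 1:3)
    out[, , ch] <- t(rowsum(t(rowsum(img[, , ch], rb)), cb)) / factor^2
  out
}

#' Tissue mask of a slide thumbnail
#'
#' Converts the thumbnail to grayscale (luminance), applies Otsu's threshold
#' and keeps the pixels darker than the threshold (tissue is darker than the
#' glass background), then applies a morphological closing with a disk
#' structuring element to fill small holes and remove speckle noise.
#'
#' @param img height x width x 3 RGB array, values 0-255.
#' @param closeKernelRadius disk radius in pixels (0 disables closing).
#' @return logical height x width matrix (TRUE = tissue).
#' @export
tissueMask <- function(img, closeKernelRadius = 2L) {
  gray <- (0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] +
             0.0722 * img[, , 3L]) / 255
  if (diff(range(gray)) == 0) {
    warning("constant image: Otsu threshold undefined, returning empty mask")
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  }
  ## EBImage works width x height; transpose in and out
  thr <- EBImage::otsu(EBImage::Image(t(gray)), range = c(0, 1))
  mask <- gray < thr
  if (closeKernelRadius > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(closeKernelRadius) + 1L,
                                shape = "disc")
    closed <- EBImage::closing(EBImage::Image(t(mask) * 1), brush)
    mask <- t(EBImage::imageData(closed)) > 0.5
  }
  mask
}

#' Remove artifact pixels by color distance from the mean tissue color
#'
#' Each pixel of the tissue pixel set is compared with the mean RGB color of
#' the whole set (computed once, not iteratively); pixels whose Euclidean
#' color distance exceeds the threshold (pen marks, scanner artifacts,
#' background leaks) are dropped.
#'
#' @param P integer matrix of 0-based pixel coordinates (columns x, y).
#' @param img the thumbnail RGB array (0-255).
#' @param threshold color distance threshold in RGB units.
#' @return the reduced pixel set (same format); the mean color is attached as
#'   attribute `"meanColor"`.
#' @export
filterArtifactPixels <- function(P, img, threshold) {
  if (nrow(P) == 0L) {
    warning("empty pixel set: nothing to filter")
    return(P)
  }
  cols <- cbind(img[cbind(P[, 2L] + 1L, P[, 1L] + 1L, 1L)],
                img[cbind(P[, 2L] + 1L, P[, 1L] + 1L, 2L)],
                img[cbind(P[, 2L] + 1L, P[, 1L] + 1L, 3L)])
  meanColor <- colMeans(cols)
  d <- sqrt(rowSums((cols - matrix(meanColor, nrow(cols), 3L,
                                   byrow = TRUE))^2))
  keep <- d <= threshold
  out <- P[keep, , drop = FALSE]
  attr(out, "meanColor") <- meanColor
  out
}

## logical mask -> 0-based pixel-set matrix (columns x, y)
maskToPixelSet <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L)
}

## 0-based pixel set -> logical mask
pixelSetToMask <- function(P, height, width) {
  m <- matrix(FALSE, height, width)
  if (nrow(P)) m[cbind(P[, 2L] + 1L, P[, 1L] + 1L)] <- TRUE
  m
}

#' Map surviving thumbnail pixels to candidate tile origins
#'
#' Each thumbnail pixel (x, y) covers the half-open region
#' \[x*ratio, (x+1)*ratio) x \[y*ratio, (y+1)*ratio) at the target
#' magnification, where `ratio` is the downsample factor between the
#' thumbnail and the target level. The candidate tiles are the distinct
#' 512-aligned tiles intersecting those regions. All coordinates are 0-based
#' with half-open tile spans.
#'
#' @param P 0-based thumbnail pixel set (columns x, y).
#' @param ratio thumbnail-to-target downsample factor (>= 1).
#' @param tileSize tile side in pixels (default 512).
#' @return integer matrix of distinct tile origins (columns x, y), sorted.
#' @export
mapMaskToTiles <- function(P, ratio, tileSize = TILE_SIDE) {
  if (ratio < 1) stop("target magnification finer than the mapped level")
  if (nrow(P) == 0L)
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
  tileRange <- function(p) {
    lo <- floor(p * ratio / tileSize)
    hi <- floor(((p + 1) * ratio - 1) / tileSize)
    list(lo = lo, hi = hi)
  }
  rx <- tileRange(P[, 1L]); ry <- tileRange(P[, 2L])
  keys <- unique(unlist(lapply(seq_len(nrow(P)), function(i) {
    tx <- rx$lo[i]:rx$hi[i]; ty <- ry$lo[i]:ry$hi[i]
    as.vector(outer(tx, ty * 2^26, "+"))   # pack (tx, ty)
  })))
  ty <- floor(keys / 2^26); tx <- keys - ty * 2^26
  out <- cbind(x = as.integer(tx * tileSize), y = as.integer(ty * tileSize))
  out[order(out[, 2L], out[, 1L]), , drop = FALSE]
}

#' Pad a tile to 512 x 512 with the background color
#'
#' Edge tiles smaller than 512 px are padded on the right/bottom (content
#' anchored top-left) with the average background color of the slide.
#'
#' @param tile RGB array with each side <= 512.
#' @param bgColor RGB triple (0-255), typically the mean color of the
#'   non-tissue thumbnail pixels.
#' @param tileSize output side (default 512).
#' @return tileSize x tileSize x 3 array.
#' @export
padTile <- function(tile, bgColor, tileSize = TILE_SIDE) {
  h <- nrow(tile); w <- ncol(tile)
  if (h > tileSize || w > tileSize)
    stop("tile larger than ", tileSize, " px cannot be padded")
  if (h == tileSize && w == tileSize) return(tile)
  out <- array(rep(bgColor, each = tileSize * tileSize),
               dim = c(tileSize, tileSize, 3L))
  out[seq_len(h), seq_len(w), ] <- tile
  out
}

#' Average background color of a thumbnail
#'
#' Mean RGB color of the pixels outside the tissue mask; falls back to white
#' when the mask covers everything.
#'
#' @param img thumbnail RGB array (0-255).
#' @param mask logical tissue mask.
#' @return RGB triple.
#' @export
backgroundColor <- function(img, mask) {
  if (all(mask)) return(c(255, 255, 255))
  vapply(1:3, function(ch) mean(img[, , ch][!mask]), numeric(1))
}

#' Tissue fraction of candidate tiles from the thumbnail pixel set
#'
#' The tissue fraction of a tile is the fraction of its 512 x 512 footprint
#' covered by surviving tissue pixels, measured on the thumbnail grid: each
#' surviving thumbnail pixel contributes `ratio^2` target pixels. Regions
#' outside the slide count as non-tissue.
#'
#' @param origins integer matrix of tile origins (columns x, y) at the target
#'   level.
#' @param P surviving 0-based thumbnail pixel set.
#' @param ratio thumbnail-to-target downsample factor.
#' @param slideDim target-level dimensions c(width, height) used to clip
#'   footprints, or NULL for no clipping.
#' @param tileSize tile side (default 512).
#' @return numeric vector of tissue fractions in \[0, 1\].
#' @export
tileTissueFractions <- function(origins, P, ratio, slideDim = NULL,
                                tileSize = TILE_SIDE) {
  if (nrow(origins) == 0L) return(numeric(0))
  ## thumbnail-resolution mask of surviving pixels, looked up per footprint
  if (nrow(P)) {
    W <- max(P[, 1L]) + 1L; H <- max(P[, 2L]) + 1L
  } else {
    W <- 1L; H <- 1L
  }
  if (!is.null(slideDim)) {
    W <- max(W, ceiling(slideDim[1L] / ratio))
    H <- max(H, ceiling(slideDim[2L] / ratio))
  }
  m <- pixelSetToMask(P, H, W)
  aligned <- tileSize %% ratio == 0 &&
    all(origins[, 1L] %% ratio == 0) && all(origins[, 2L] %% ratio == 0)
  vapply(seq_len(nrow(origins)), function(i) {
    x0 <- origins[i, 1L]; y0 <- origins[i, 2L]
    if (aligned) {
      ## tile footprint is a whole block of thumbnail pixels
      x1 <- x0 / ratio + 1L; y1 <- y0 / ratio + 1L
      if (x1 > W || y1 > H) return(0)
      cx <- x1:min((x0 + tileSize) / ratio, W)
      cy <- y1:min((y0 + tileSize) / ratio, H)
      return(sum(m[cy, cx]) * ratio^2 / tileSize^2)
    }
    ## general case: accumulate per-pixel overlaps
    cx <- seq.int(floor(x0 / ratio), ceiling((x0 + tileSize) / ratio) - 1L)
    cy <- seq.int(floor(y0 / ratio), ceiling((y0 + tileSize) / ratio) - 1L)
    tot <- 0
    for (px in cx) for (py in cy) {
      ## overlap of pixel footprint with the tile, in target pixels
      ox <- min((px + 1) * ratio, x0 + tileSize) - max(px * ratio, x0)
      oy <- min((py + 1) * ratio, y0 + tileSize) - max(py * ratio, y0)
      if (ox <= 0 || oy <= 0) next
      inside <- px >= 0 && py >= 0 && px < W && py < H &&
        m[py + 1L, px + 1L]
      if (inside) tot <- tot + ox * oy
    }
    tot / tileSize^2
  }, numeric(1))
}

#' Keep or reject tiles by tissue fraction
#'
#' @param tiles data.frame with columns `x`, `y`, `tissue_fraction`.
#' @param threshold minimum tissue fraction; a tile is kept iff its fraction
#'   is `>= threshold`.
#' @return the data.frame with `kept` (logical) and `reason` columns added.
#' @export
tissueFractionFilter <- function(tiles, threshold) {
  tiles$kept <- tiles$tissue_fraction >= threshold
  tiles$reason <- ifelse(tiles$kept, "", "low_tissue_fraction")
  tiles
}

#' Fractional sampling of low-magnification tiles
#'
#' When the number of filtered tiles exceeds `limit`, a uniform sample
#' without replacement of `round(fraction * n)` tiles is drawn; otherwise all
#' tiles are used.
#'
#' @param tiles data.frame of tiles (one row each).
#' @param fraction sampling fraction in (0, 1].
#' @param limit tile-count limit triggering sampling.
#' @param seed integer seed.
#' @return the sampled data.frame (row order preserved).
#' @export
sampleTilesLowMag <- function(tiles, fraction = 0.6, limit = 500L, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  n <- nrow(tiles)
  if (n <= limit) return(tiles)
  keep <- withSeed(seed, sort(sample(n, round(fraction * n))))
  tiles[keep, , drop = FALSE]
}

## k-means++ center initialization (stats::kmeans has none built in)
kmeansPlusPlusCenters <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample(n, 1L), ]
  if (k > 1L) for (j in 2:k) {
    d2 <- vapply(seq_len(n), function(i)
      min(rowSums((centers[seq_len(j - 1L), , drop = FALSE] -
                     matrix(X[i, ], j - 1L, ncol(X), byrow = TRUE))^2)),
      numeric(1))
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- X[sample(n, 1L, prob = p), ]
  }
  centers
}

#' Hierarchical cluster sampling of child tiles
#'
#' K-means clusters the parent tiles (on their embedding vectors, seeded
#' k-means++ initialization, Lloyd iterations capped), samples at most
#' `nPerCluster` parents per cluster, and expands every sampled parent to its
#' 2 x 2 block of child tiles at the next magnification by coordinate
#' doubling: parent origin (x, y) yields children (2x, 2y), (2x+512, 2y),
#' (2x, 2y+512), (2x+512, 2y+512).
#'
#' @param parents data.frame of parent tiles with columns `x`, `y`.
#' @param parentEmbeddings numeric matrix, one row per parent (defaults to
#'   parent mean-RGB features if you have no embeddings; any numeric features
#'   work).
#' @param k number of clusters (<= number of parents).
#' @param nPerCluster maximum parents sampled per cluster (default 20).
#' @param seed integer seed.
#' @param tileSize tile side (default 512).
#' @return data.frame of child tiles with columns `x`, `y`, `parent_x`,
#'   `parent_y`, `cluster`.
#' @export
clusterSampleChildren <- function(parents, parentEmbeddings, k,
                                  nPerCluster = 20L, seed = 1L,
                                  tileSize = TILE_SIDE) {
  n <- nrow(parents)
  if (k > n) stop("k must not exceed the number of parent tiles")
  if (nrow(parentEmbeddings) != n)
    stop("one embedding row per parent tile required")
  withSeed(seed, {
    cl <- if (k == 1L) rep(1L, n) else {
      centers <- kmeansPlusPlusCenters(parentEmbeddings, k)
      stats::kmeans(parentEmbeddings, centers = centers, iter.max = 25L,
                    algorithm = "Lloyd")$cluster
    }
    sampled <- unlist(lapply(seq_len(k), function(j) {
      idx <- which(cl == j)
      if (length(idx) <= nPerCluster) idx
      else sort(sample(idx, nPerCluster))
    }))
    sampled <- sort(sampled)
    do.call(rbind, lapply(sampled, function(i) {
      px <- parents$x[i]; py <- parents$y[i]
      data.frame(x = 2L * px + c(0L, tileSize, 0L, tileSize),
                 y = 2L * py + c(0L, 0L, tileSize, tileSize),
                 parent_x = px, parent_y = py, cluster = cl[i])
    }))
  })
}

#' Run the thumbnail-level preprocessing of one slide
#'
#' Full pipeline for one magnification: thumbnail construction (block-mean
#' downsampling to at most `thumbnailMaxSide`), Otsu tissue masking with
#' closing, artifact color filtering, mapping of surviving pixels to
#' candidate 512-px tiles at the target level, tissue-fraction filtering,
#' and (optionally) fractional sampling.
#'
#' @param img slide image at the target magnification (RGB array, 0-255).
#' @param meta a [slideMetadata()] record.
#' @param config a [prepConfig()].
#' @param mag magnification tag recorded in the manifest (e.g. `"5x"`).
#' @param sample apply the 5x fractional sampling step to the kept tiles.
#' @return list with `manifest` (data.frame slide_id, mag, x, y,
#'   tissue_fraction, kept, reason), `mask` (thumbnail tissue mask),
#'   `pixelSet` (surviving pixels), `ratio`, `background` (RGB triple) and
#'   `thumbnail`.
#' @export
prepSlide <- function(img, meta, config = prepConfig(), mag = "5x",
                      sample = FALSE) {
  stopifnot(inherits(meta, "SlideMetadata"), inherits(config, "PrepConfig"))
  H <- nrow(img); W <- ncol(img)
  factor <- 1L
  while (max(H, W) / factor > config$thumbnailMaxSide) factor <- factor * 2L
  thumb <- downsampleImage(img, factor)
  mask <- tissueMask(thumb, config$closeKernelRadius)
  P <- maskToPixelSet(mask)
  P2 <- if (nrow(P)) filterArtifactPixels(P, thumb,
                                          config$colorDistanceThreshold) else P
  origins <- mapMaskToTiles(P2, ratio = factor)
  frac <- tileTissueFractions(origins, P2, ratio = factor,
                              slideDim = c(W, H))
  manifest <- data.frame(slide_id = meta$slideId, mag = mag,
                         x = if (nrow(origins)) origins[, 1L] else integer(0),
                         y = if (nrow(origins)) origins[, 2L] else integer(0),
                         tissue_fraction = frac)
  manifest <- tissueFractionFilter(manifest, config$tissueFractionThreshold)
  if (sample) {
    kept <- manifest[manifest$kept, , drop = FALSE]
    kept <- sampleTilesLowMag(kept, config$sampleFraction5x,
                              config$tileCountLimit5x, seed = config$seed)
    manifest <- rbind(kept, manifest[!manifest$kept, , drop = FALSE])
  }
  rownames(manifest) <- NULL
  list(manifest = manifest, mask = mask, pixelSet = P2, ratio = factor,
       background = backgroundColor(thumb, mask), thumbnail = thumb)
}

#' Extract one 512-px tile from a slide image, padding at the edges
#'
#' @param img slide RGB array (0-255) at the tile's magnification.
#' @param x,y 0-based tile origin.
#' @param bgColor padding color (RGB triple).
#' @param tileSize tile side (default 512).
#' @return tileSize x tileSize x 3 array.
#' @export
extractTile <- function(img, x, y, bgColor = c(255, 255, 255),
                        tileSize = TILE_SIDE) {
  H <- nrow(img); W <- ncol(img)
  if (x < 0 || y < 0 || x >= W || y >= H)
    stop("tile origin (", x, ", ", y, ") outside the slide")
  xs <- (x + 1L):min(x + tileSize, W)
  ys <- (y + 1L):min(y + tileSize, H)
  padTile(img[ys, xs, , drop = FALSE], bgColor, tileSize)
}
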