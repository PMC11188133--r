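test_that("metadata extraction writes idempotent CSV rows", {
  s <- smallSlide(seed = 12L)
  csv <- tempfile(fileext = ".csv")
  slides <- list(
    list(slideId = "A", label = 1L, slideType = "flash_frozen", mpp = 1.0,
         image = s$image),
    list(slideId = "B", label = 0L, slideType = "ffpe", mpp = 0.25,
         image = s$image))
  out <- extractMetadata(slides, csv)
  expect_identical(nrow(out), 2L)
  got <- read.csv(csv, colClasses = c(slide_id = "character"))
  expect_identical(got$mpp[got$slide_id == "A"], 1.0)
  ## re-run: still one row per slide
  extractMetadata(slides[1L], csv)
  got2 <- read.csv(csv, colClasses = c(slide_id = "character"))
  expect_identical(nrow(got2), 2L)
  expect_identical(sum(got2$slide_id == "A"), 1L)
  ## unreadable file recorded as skipped
  expect_warning(
    bad <- extractMetadata(list(list(slideId = "C", label = 0L,
                                     path = "/nonexistent.png")), csv),
    "skipped")
  expect_identical(attr(bad, "skipped")$reason, "unreadable file")
  unlink(csv)
})

test_that("slide images round-trip through PNG", {
  s <- generateSyntheticSlide(slideSimSpec(width = 64L, height = 48L,
                                           nTissueBlobs = 1L,
                                           blobRadiusRange = c(10L, 10L),
                                           noiseSd = 0, seed = 3L))
  f <- tempfile(fileext = ".png")
  writeSlideImage(s$image, f)
  back <- readSlideImage(f)
  expect_identical(dim(back), dim(s$image))
  expect_equal(round(back), s$image, tolerance = 1e-8)
  unlink(f)
})

test_that("Otsu tissue mask recovers the generated tissue", {
  s <- smallSlide(seed = 5L)
  mask <- tissueMask(s$image, closeKernelRadius = 2L)
  inter <- sum(mask & s$tissueMask)
  union <- sum(mask | s$tissueMask)
  expect_gte(inter / union, 0.95)
  ## all-white image: empty mask with a warning
  white <- array(255, dim = c(64L, 64L, 3L))
  expect_warning(m0 <- tissueMask(white), "constant")
  expect_false(any(m0))
  ## closing fills single-pixel interior holes
  img <- array(240, dim = c(64L, 64L, 3L))
  img[20:40, 20:40, ] <- 60
  img[30L, 30L, ] <- 240      # pinhole
  m <- tissueMask(img, closeKernelRadius = 2L)
  expect_true(m[30L, 30L])
  m_open <- tissueMask(img, closeKernelRadius = 0L)
  expect_false(m_open[30L, 30L])
})

test_that("artifact color filter removes deviant pixels, single pass", {
  ## uniform-color pixel set: everything kept for any positive threshold
  img <- array(100, dim = c(32L, 32L, 3L))
  P <- cbind(x = c(0L, 5L, 10L), y = c(0L, 3L, 7L))
  kept <- filterArtifactPixels(P, img, threshold = 1)
  expect_identical(nrow(kept), 3L)
  ## threshold 0: only pixels exactly at the mean survive
  img2 <- img; img2[1L, 1L, ] <- 0    # pixel (x=0, y=0) black
  kept0 <- filterArtifactPixels(P, img2, threshold = 0)
  expect_identical(nrow(kept0), 0L)   # mean is shifted, nobody matches it
  ## a strongly deviant pen stroke crossing tissue is removed
  s <- smallSlide(seed = 21L, strokes = 2L)
  mask <- tissueMask(s$image, 2L)
  P2 <- wsiMIL:::maskToPixelSet(mask)
  kept2 <- filterArtifactPixels(P2, s$image, threshold = 60)
  keptMask <- wsiMIL:::pixelSetToMask(kept2, nrow(mask), ncol(mask))
  strokeInMask <- s$artifactMask & mask
  if (sum(strokeInMask) > 20L) {
    removed <- sum(strokeInMask & !keptMask) / sum(strokeInMask)
    expect_gte(removed, 0.9)
  }
  ## empty input warns
  expect_warning(filterArtifactPixels(P[0, , drop = FALSE], img, 10),
                 "empty")
})

test_that("thumbnail pixels map to deduplicated 512-aligned tiles", {
  ## downsample ratio 64: pixel (3,5) covers [192,256) x [320,384) -> (0,0)
  P <- cbind(x = 3L, y = 5L)
  tiles <- mapMaskToTiles(P, ratio = 64)
  expect_identical(tiles, sortTiles(cbind(x = 0L, y = 0L)))
  ## pixel further out: (8,0) covers [512,576) -> tile (512, 0)
  expect_identical(mapMaskToTiles(cbind(x = 8L, y = 0L), 64)[1L, ],
                   c(x = 512L, y = 0L))
  ## a pixel straddling a tile boundary yields both tiles
  t2 <- mapMaskToTiles(cbind(x = 3L, y = 0L), ratio = 160)
  expect_identical(t2[, "x"], c(0L, 512L))   # [480, 640) spans two tiles
  ## adjacent pixels mapping into one tile are deduplicated
  t3 <- mapMaskToTiles(cbind(x = c(0L, 1L), y = c(0L, 0L)), ratio = 64)
  expect_identical(nrow(t3), 1L)
  ## empty set, error cases
  expect_identical(nrow(mapMaskToTiles(P[0, , drop = FALSE], 64)), 0L)
  expect_error(mapMaskToTiles(P, ratio = 0.5), "finer")
})

test_that("coordinate mapping round trips on a full grid", {
  ## every tile of a 4096-wide level maps back to itself through the
  ## thumbnail: thumb pixel = origin / ratio maps to a tile set containing
  ## the original tile
  ratio <- 64
  for (x in seq(0L, 3584L, by = 512L)) for (y in c(0L, 1024L)) {
    px <- cbind(x = x %/% 64L, y = y %/% 64L)
    tiles <- mapMaskToTiles(px, ratio)
    expect_true(any(tiles[, 1L] == x & tiles[, 2L] == y))
  }
})

test_that("tiles pad to 512 with the background color, content top-left", {
  bg <- c(250, 245, 240)
  tile <- array(7, dim = c(512L, 500L, 3L))
  out <- padTile(tile, bg)
  expect_identical(dim(out), c(512L, 512L, 3L))
  expect_true(all(out[, 1:500, ] == 7))
  for (ch in 1:3) expect_true(all(out[, 501:512, ch] == bg[ch]))
  ## identity on full tiles
  full <- array(1, dim = c(512L, 512L, 3L))
  expect_identical(padTile(full, bg), full)
  ## 1x1 input: 512^2 - 1 background pixels
  one <- array(9, dim = c(1L, 1L, 3L))
  out1 <- padTile(one, bg)
  expect_identical(out1[1L, 1L, ], c(9, 9, 9))
  expect_identical(sum(out1[, , 1L] == bg[1L]), 512L * 512L - 1L)
  expect_error(padTile(array(0, dim = c(513L, 512L, 3L)), bg), "padded")
})

test_that("tissue-fraction filter keeps tiles at or above the threshold", {
  tiles <- data.frame(x = c(0L, 512L, 1024L),
                      y = 0L, tissue_fraction = c(1.0, 0.20, 0.25))
  out <- tissueFractionFilter(tiles, 0.25)
  expect_identical(out$kept, c(TRUE, FALSE, TRUE))
  expect_identical(out$reason, c("", "low_tissue_fraction", ""))
  ## monotonicity: raising the threshold never keeps more tiles
  set.seed(8)
  fr <- data.frame(x = 0L, y = 0L, tissue_fraction = runif(50))
  kept <- vapply(seq(0, 1, by = 0.1), function(th)
    sum(tissueFractionFilter(fr, th)$kept), integer(1))
  expect_true(all(diff(kept) <= 0L))
})

test_that("5x fractional sampling follows the limit rule and the seed", {
  tiles <- data.frame(x = seq_len(100L) * 512L, y = 0L)
  s1 <- sampleTilesLowMag(tiles, fraction = 0.6, limit = 50L, seed = 3L)
  expect_identical(nrow(s1), 60L)
  expect_identical(sampleTilesLowMag(tiles, 0.6, 50L, seed = 3L), s1)
  expect_false(identical(sampleTilesLowMag(tiles, 0.6, 50L, seed = 4L), s1))
  ## below the limit: identity
  small <- tiles[1:30, ]
  expect_identical(sampleTilesLowMag(small, 0.6, 50L, seed = 3L), small)
  expect_error(sampleTilesLowMag(tiles, 0, 50L), "fraction")
})

test_that("cluster sampling expands parents into coordinate-doubled children", {
  parents <- data.frame(x = c(512L, 1024L, 0L), y = c(1024L, 0L, 0L))
  emb <- matrix(rnorm(9), 3L, 3L)
  ch <- clusterSampleChildren(parents, emb, k = 1L, nPerCluster = 20L,
                              seed = 2L)
  ## cap at min(cluster size, nPerCluster): all 3 parents sampled
  expect_identical(nrow(ch), 12L)
  kid <- ch[ch$parent_x == 512L & ch$parent_y == 1024L, ]
  expect_identical(sortTiles(kid[, c("x", "y")]),
                   sortTiles(data.frame(x = c(1024L, 1536L, 1024L, 1536L),
                                        y = c(2048L, 2048L, 2560L, 2560L))))
  ## child -> parent round trip: floor(child/2) lands inside the parent tile
  expect_true(all(ch$x %/% 2L %/% 512L * 512L == ch$parent_x))
  expect_true(all(ch$y %/% 2L %/% 512L * 512L == ch$parent_y))
  ## k-means path with a cap
  set.seed(6)
  parents2 <- data.frame(x = rep(seq(0L, 4608L, by = 512L), 4L)[1:30],
                         y = rep(0:3 * 512L, each = 10L)[1:30])
  emb2 <- rbind(matrix(rnorm(45), 15L), matrix(rnorm(45, mean = 8), 15L))
  ch2 <- clusterSampleChildren(parents2, emb2, k = 2L, nPerCluster = 5L,
                               seed = 2L)
  expect_identical(nrow(ch2), 2L * 5L * 4L)
  expect_identical(clusterSampleChildren(parents2, emb2, 2L, 5L, seed = 2L),
                   ch2)
  expect_error(clusterSampleChildren(parents, emb, k = 4L), "exceed")
})

test_that("full prep pipeline matches the exhaustive brute-force rescan", {
  s <- generateSyntheticSlide(slideSimSpec(width = 2048L, height = 2048L,
                                           nTissueBlobs = 5L,
                                           blobRadiusRange = c(100L, 260L),
                                           artifactStrokes = 1L, seed = 31L))
  meta <- slideMetadata("oracle_slide", 1L, "flash_frozen", mpp = 2.0)
  cfg <- prepConfig(seed = 7L)
  prep <- prepSlide(s$image, meta, cfg, mag = "5x")
  kept <- prep$manifest[prep$manifest$kept, c("x", "y")]
  brute <- bruteForceKeptTiles(prep$pixelSet, prep$ratio, 2048L, 2048L,
                               cfg$tissueFractionThreshold)
  expect_identical(sortTiles(kept), sortTiles(brute))
  ## mask quality against the generator ground truth at thumbnail scale
  gtThumb <- s$tissueMask[seq(1L, 2048L, by = prep$ratio),
                          seq(1L, 2048L, by = prep$ratio)]
  iou <- sum(prep$mask & gtThumb) / sum(prep$mask | gtThumb)
  expect_gte(iou, 0.95)
  ## determinism of the whole pipeline
  prep2 <- prepSlide(s$image, meta, cfg, mag = "5x")
  expect_identical(prep$manifest, prep2$manifest)
})

test_that("extractTile pads edge tiles with the background color", {
  s <- generateSyntheticSlide(slideSimSpec(width = 600L, height = 600L,
                                           nTissueBlobs = 1L,
                                           blobRadiusRange = c(100L, 100L),
                                           noiseSd = 0, seed = 2L))
  bg <- c(250, 250, 250)
  t00 <- extractTile(s$image, 0L, 0L, bg)
  expect_identical(dim(t00), c(512L, 512L, 3L))
  tEdge <- extractTile(s$image, 512L, 512L, bg)   # only 88 px remain
  expect_identical(dim(tEdge), c(512L, 512L, 3L))
  expect_true(all(tEdge[, 89:512, 1L] == bg[1L]))
  expect_error(extractTile(s$image, 600L, 0L, bg), "outside")
})
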