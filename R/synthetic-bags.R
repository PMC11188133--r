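#' @include accessors.R
NULL

#' Bag label under the standard MIL assumption
#'
#' A bag is positive iff it contains at least one positive instance; negative
#' bags contain only negative instances.
#'
#' @param y binary vector of per-instance labels.
#' @return integer 0 or 1.
#' @examples
#' bagLabelFromInstances(c(0, 1, 0))  # 1
#' bagLabelFromInstances(c(0, 0, 0))  # 0
#' @export
bagLabelFromInstances <- function(y) {
  if (length(y) == 0L) stop("instance label vector must be nonempty")
  if (!isBinaryVector(y)) stop("instance labels must be binary (0/1)")
  as.integer(sum(y) > 0)
}

#' Configuration for the synthetic bag generator
#'
#' Describes a population of MIL bags: negative instances are drawn from an
#' isotropic Gaussian at the origin, witnesses (positive instances inside
#' positive bags) from an isotropic Gaussian displaced by
#' `separation` along a fixed unit direction. Each positive bag receives
#' `ceiling(witnessRate * bagSize)` witnesses, so every positive bag has at
#' least one.
#'
#' @param nBags number of bags.
#' @param bagSizeRange integer interval (min, max) of instances per bag.
#' @param witnessRate fraction in (0, 1] of positive instances within a
#'   positive bag.
#' @param dim embedding dimensionality.
#' @param separation nonnegative distance between the negative and witness
#'   class means (in units of the noise standard deviation when
#'   `noiseSd = 1`).
#' @param noiseSd positive per-coordinate standard deviation.
#' @param posFraction fraction of bags that are positive.
#' @param seed integer seed; generation is bit-reproducible.
#' @return a validated config list of class `"SyntheticBagConfig"`.
#' @export
bagSimConfig <- function(nBags = 200L, bagSizeRange = c(20L, 20L),
                         witnessRate = 0.2, dim = 32L, separation = 3,
                         noiseSd = 1, posFraction = 0.5, seed = 1L) {
  bagSizeRange <- as.integer(round(bagSizeRange))
  if (length(bagSizeRange) != 2L || bagSizeRange[1L] < 1L ||
      bagSizeRange[2L] < bagSizeRange[1L])
    stop("bagSizeRange must be an increasing integer interval with min >= 1")
  if (witnessRate <= 0 || witnessRate > 1)
    stop("witnessRate must lie in (0, 1]: a positive bag needs >= 1 witness")
  if (ceiling(witnessRate * bagSizeRange[1L]) < 1L)
    stop("witnessRate too small: rounds to 0 witnesses for a positive bag")
  if (nBags < 1L) stop("nBags must be >= 1")
  if (dim < 1L) stop("dim must be >= 1")
  if (separation < 0) stop("separation must be nonnegative")
  if (noiseSd <= 0) stop("noiseSd must be positive")
  if (posFraction < 0 || posFraction > 1) stop("posFraction must be in [0,1]")
  structure(list(nBags = as.integer(nBags), bagSizeRange = bagSizeRange,
                 witnessRate = witnessRate, dim = as.integer(dim),
                 separation = separation, noiseSd = noiseSd,
                 posFraction = posFraction, seed = as.integer(seed)),
            class = "SyntheticBagConfig")
}

#' Generate synthetic MIL bags with known witness structure
#'
#' Negative bags contain only negative instances; positive bags contain
#' exactly `ceiling(witnessRate * K)` witnesses among their K instances. The
#' hidden instance labels are attached to each bag in a side channel that the
#' training code never reads.
#'
#' @param cfg a [bagSimConfig()] object.
#' @return a [MILBagSet-class] with hidden instance labels attached.
#' @export
generateBags <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticBagConfig"))
  ## fixed unit witness direction, deterministic in the dimension
  u <- rep(1, cfg$dim) / sqrt(cfg$dim)
  nPos <- round(cfg$posFraction * cfg$nBags)
  labels <- c(rep(1L, nPos), rep(0L, cfg$nBags - nPos))
  withSeed(cfg$seed, {
    labels <- sample(labels)
    bags <- vector("list", cfg$nBags)
    for (b in seq_len(cfg$nBags)) {
      K <- if (cfg$bagSizeRange[1L] == cfg$bagSizeRange[2L])
        cfg$bagSizeRange[1L]
      else sample(cfg$bagSizeRange[1L]:cfg$bagSizeRange[2L], 1L)
      yi <- rep(0L, K)
      if (labels[b] == 1L) {
        nw <- ceiling(cfg$witnessRate * K)
        yi[sample(K, nw)] <- 1L
      }
      H <- matrix(stats::rnorm(K * cfg$dim, sd = cfg$noiseSd), K, cfg$dim)
      if (any(yi == 1L))
        H[yi == 1L, ] <- H[yi == 1L, , drop = FALSE] +
          matrix(cfg$separation * u, sum(yi), cfg$dim, byrow = TRUE)
      bags[[b]] <- new("MILBag", embeddings = H,
                       label = bagLabelFromInstances(yi),
                       bagId = sprintf("synthetic_bag_%03d", b),
                       instanceLabels = yi)
    }
    new("MILBagSet", bags = bags)
  })
}

#' Deterministic toy tile feature extractor
#'
#' A stand-in feature extractor honoring the 1024-dimensional embedding
#' contract: the 512 x 512 RGB tile is mean-pooled to 16 x 16 per channel
#' (768 values), passed through a fixed random projection (frozen internal
#' seed) and a tanh nonlinearity. Identical tiles map to identical
#' embeddings; any single-pixel change perturbs its pooled cell and hence the
#' embedding.
#'
#' @param dim output dimension (default 1024).
#' @return a [FeatureExtractor-class].
#' @export
toyFeatureExtractor <- function(dim = 1024L) {
  dim <- as.integer(dim)
  nIn <- 16L * 16L * 3L
  proj <- withSeed(190248L, {
    list(W = matrix(stats::rnorm(dim * nIn, sd = 1 / sqrt(nIn)), dim, nIn),
         b = stats::rnorm(dim, sd = 0.1))
  })
  fun <- function(tile) {
    if (length(base::dim(tile)) != 3L || !all(base::dim(tile) == c(512L, 512L, 3L)))
      stop("tile must be a 512 x 512 x 3 array")
    x <- tile / 255
    ## 32x32 block mean-pool each channel to 16x16
    pooled <- vapply(1:3, function(ch) {
      m <- x[, , ch]
      block <- (seq_len(512L) - 1L) %/% 32L + 1L
      rowsum(t(rowsum(m, block)), block) / (32 * 32)
    }, matrix(0, 16L, 16L))
    drop(tanh(proj$W %*% as.vector(pooled) + proj$b))
  }
  new("FeatureExtractor", name = "toy", dim = dim, fun = fun)
}
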