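#' @include wsi-prep.R synthetic-bags.R
NULL

## Ruifrok-Johnston H&E-DAB stain optical-density vectors (rows normalized)
hedStainMatrix <- function() {
  M <- rbind(c(0.65, 0.70, 0.29),
             c(0.07, 0.99, 0.11),
             c(0.27, 0.57, 0.78))
  M / sqrt(rowSums(M^2))
}

#' RGB to HED color deconvolution
#'
#' Separates hematoxylin, eosin and DAB stain densities with the
#' Ruifrok-Johnston matrix. Pixels as an n x 3 matrix (0-255); optical
#' density is `-log10(I/255)` with intensities floored away from zero.
#'
#' @param rgb n x 3 matrix of RGB values (0-255).
#' @return n x 3 matrix of stain densities.
#' @export
rgb2hed <- function(rgb) {
  od <- -log10(pmax(rgb / 255, 1e-6))
  od %*% solve(hedStainMatrix())
}

#' @rdname rgb2hed
#' @param hed n x 3 matrix of stain densities.
#' @return `hed2rgb` returns an n x 3 RGB matrix (0-255, clipped).
#' @export
hed2rgb <- function(hed) {
  od <- hed %*% hedStainMatrix()
  pmin(pmax(10^(-od) * 255, 0), 255)
}

#' Augmentation configuration
#'
#' Parameters of the tile augmentation used when building embedding stores:
#' random HED stain perturbation (per-channel multiplicative jitter and
#' additive bias in stain-density space), Gaussian pixel noise, rotations
#' from an allowed set and horizontal/vertical flips.
#'
#' @param hedSigma per-channel multiplicative stain jitter: scale drawn from
#'   \[1 - hedSigma, 1 + hedSigma\].
#' @param hedBias additive stain shift drawn from \[-hedBias, hedBias\].
#' @param gaussNoiseSd Gaussian pixel noise sd (0-255 units).
#' @param rotations allowed rotation angles, subset of c(90, 180, 270);
#'   identity is always allowed.
#' @param flips allowed flip axes, subset of c("horizontal", "vertical");
#'   each is applied independently with probability 1/2.
#' @param nAugmentations augmented replicas per tile (default 2).
#' @param seed integer seed for the whole augmented dataset.
#' @return config list of class `"AugmentConfig"`.
#' @export
augmentConfig <- function(hedSigma = 0.05, hedBias = 0.01, gaussNoiseSd = 3,
                          rotations = c(90, 180, 270),
                          flips = c("horizontal", "vertical"),
                          nAugmentations = 2L, seed = 1L) {
  if (hedSigma < 0 || hedBias < 0 || gaussNoiseSd < 0)
    stop("augmentation ranges must be nonnegative")
  if (!all(rotations %in% c(90, 180, 270)))
    stop("rotations must be a subset of 90/180/270")
  if (!all(flips %in% c("horizontal", "vertical")))
    stop("flips must be a subset of horizontal/vertical")
  if (nAugmentations < 0L) stop("nAugmentations must be >= 0")
  structure(list(hedSigma = hedSigma, hedBias = hedBias,
                 gaussNoiseSd = gaussNoiseSd, rotations = rotations,
                 flips = flips, nAugmentations = as.integer(nAugmentations),
                 seed = as.integer(seed)),
            class = "AugmentConfig")
}

#' Rotate an RGB tile by a multiple of 90 degrees (clockwise)
#'
#' @param tile height x width x 3 array.
#' @param angle 0, 90, 180 or 270.
#' @return rotated array.
#' @export
rotateTile <- function(tile, angle) {
  angle <- angle %% 360
  if (angle == 0) return(tile)
  rot90 <- function(a)   # 90 degrees clockwise
    aperm(a, c(2L, 1L, 3L))[, rev(seq_len(nrow(a))), , drop = FALSE]
  for (i in seq_len(angle / 90)) tile <- rot90(tile)
  tile
}

#' Apply one random augmentation draw to a tile
#'
#' HED stain perturbation, Gaussian noise, a rotation sampled from the
#' allowed set (or identity) and independent flips; output clipped to
#' \[0, 255\]. Deterministic for a given draw seed. With all ranges zero and
#' rotations/flips disabled the tile is returned unchanged.
#'
#' @param tile 512 x 512 x 3 array (0-255).
#' @param cfg an [augmentConfig()].
#' @param seed draw seed.
#' @return augmented tile, same shape.
#' @export
augmentTile <- function(tile, cfg, seed = cfg$seed) {
  if (length(dim(tile)) != 3L || dim(tile)[3L] != 3L)
    stop("tile must be a height x width x 3 RGB array")
  withSeed(seed, {
    out <- tile
    if (cfg$hedSigma > 0 || cfg$hedBias > 0) {
      alpha <- stats::runif(3L, 1 - cfg$hedSigma, 1 + cfg$hedSigma)
      beta <- stats::runif(3L, -cfg$hedBias, cfg$hedBias)
      px <- matrix(out, ncol = 3L)
      hed <- rgb2hed(px)
      hed <- sweep(sweep(hed, 2L, alpha, "*"), 2L, beta, "+")
      out <- array(hed2rgb(hed), dim = dim(out))
    }
    if (cfg$gaussNoiseSd > 0)
      out <- out + array(stats::rnorm(length(out), sd = cfg$gaussNoiseSd),
                         dim = dim(out))
    if (length(cfg$rotations) > 0L) {
      angle <- sample(c(0, cfg$rotations), 1L)
      out <- rotateTile(out, angle)
    }
    if ("horizontal" %in% cfg$flips && stats::runif(1) < 0.5)
      out <- out[, rev(seq_len(ncol(out))), , drop = FALSE]
    if ("vertical" %in% cfg$flips && stats::runif(1) < 0.5)
      out <- out[rev(seq_len(nrow(out))), , , drop = FALSE]
    pmin(pmax(out, 0), 255)
  })
}

#' Check a feature extractor against its contract
#'
#' Runs the extractor twice on a probe tile and verifies the declared output
#' dimension and determinism.
#'
#' @param extractor a [FeatureExtractor-class].
#' @param probeTile optional probe tile (defaults to a gray 512 x 512 tile).
#' @return TRUE invisibly; errors if the contract is violated.
#' @export
validateExtractor <- function(extractor, probeTile = NULL) {
  stopifnot(is(extractor, "FeatureExtractor"))
  if (is.null(probeTile)) probeTile <- array(128, dim = c(512L, 512L, 3L))
  e1 <- extractor@fun(probeTile)
  e2 <- extractor@fun(probeTile)
  if (length(e1) != extractor@dim)
    stop("extractor '", extractor@name, "' returned length ", length(e1),
         ", declared ", extractor@dim)
  if (!identical(e1, e2))
    stop("extractor '", extractor@name, "' is not deterministic")
  invisible(TRUE)
}

#' Embed tiles, with augmented replicas
#'
#' Computes one embedding per tile with the given extractor, plus
#' `cfg$nAugmentations` augmented replicas per tile (each replica set is a
#' separate matrix, tagged with its augmentation index). Augmentation draw
#' seeds derive deterministically from `cfg$seed`, the augmentation index and
#' the tile index.
#'
#' @param tiles list of 512 x 512 x 3 arrays (0-255).
#' @param extractor a [FeatureExtractor-class].
#' @param cfg an [augmentConfig()]; use `nAugmentations = 0` for originals
#'   only.
#' @return list with `original` (n x dim matrix) and `augmented` (list of
#'   n x dim matrices, one per augmentation index).
#' @export
embedTiles <- function(tiles, extractor, cfg = augmentConfig()) {
  validateExtractor(extractor)
  n <- length(tiles)
  emb <- function(tl) {
    out <- t(vapply(tl, extractor@fun, numeric(extractor@dim)))
    if (n == 1L) out <- matrix(out, 1L, extractor@dim)
    out
  }
  original <- emb(tiles)
  augmented <- lapply(seq_len(cfg$nAugmentations), function(k) {
    emb(lapply(seq_len(n), function(i)
      augmentTile(tiles[[i]], cfg, seed = deriveSeed(cfg$seed, k, i))))
  })
  list(original = original, augmented = augmented)
}

## ---- HDF5 store ----------------------------------------------------------

#' Write a bag set to an HDF5 embedding store
#'
#' Schema (one group per bag under `/bags`):
#' \itemize{
#'   \item `embeddings`: n x d float32 dataset
#'   \item `coords`: n x 2 64-bit integer dataset of tile origins (x, y;
#'     0-based, at the bag's magnification); zeros when a bag has no
#'     coordinates
#'   \item `aug/<k>/embeddings`: optional augmented replica sets
#'   \item group attributes: `label` (0/1), `magnification`, `mpp`,
#'     `slide_type`, `config_hash`
#'   \item `instance_labels`: optional test-only dataset of hidden instance
#'     labels (attribute `test_only` = 1)
#' }
#' Payloads are stored as float32; a write-read-write cycle is bit-exact.
#'
#' @param bags a [MILBagSet-class].
#' @param path HDF5 file path (overwritten).
#' @param magnification magnification tag (e.g. `"5x"`).
#' @param mpp microns per pixel.
#' @param slideType slide preparation type.
#' @param configHash provenance string for the pipeline configuration.
#' @param augmented optional list (one entry per bag) of lists of augmented
#'   embedding matrices.
#' @param includeInstanceLabels store hidden instance labels (test-only).
#' @return the path, invisibly.
#' @export
writeBags <- function(bags, path, magnification = "5x", mpp = 1.0,
                      slideType = "flash_frozen", configHash = "",
                      augmented = NULL, includeInstanceLabels = FALSE) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "bags")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (i in seq_len(nBags(bags))) {
    bag <- bags[[i]]
    grp <- paste0("bags/", bagId(bag))
    rhdf5::h5createGroup(path, grp)
    emb <- instanceEmbeddings(bag)
    nm <- paste0(grp, "/embeddings")
    rhdf5::h5createDataset(path, nm, dims = dim(emb),
                           H5type = "H5T_IEEE_F32LE")
    rhdf5::h5write(emb, path, nm)
    co <- tileCoords(bag)
    if (nrow(co) == 0L) co <- matrix(0L, nrow(emb), 2L)
    nm <- paste0(grp, "/coords")
    rhdf5::h5createDataset(path, nm, dims = dim(co),
                           H5type = "H5T_STD_I64LE")
    rhdf5::h5write(co, path, nm)
    if (!is.null(augmented) && length(augmented) >= i &&
        length(augmented[[i]])) {
      rhdf5::h5createGroup(path, paste0(grp, "/aug"))
      for (k in seq_along(augmented[[i]])) {
        rhdf5::h5createGroup(path, paste0(grp, "/aug/", k))
        nm <- paste0(grp, "/aug/", k, "/embeddings")
        rhdf5::h5createDataset(path, nm, dims = dim(augmented[[i]][[k]]),
                               H5type = "H5T_IEEE_F32LE")
        rhdf5::h5write(augmented[[i]][[k]], path, nm)
      }
    }
    if (includeInstanceLabels && length(hiddenInstanceLabels(bag))) {
      nm <- paste0(grp, "/instance_labels")
      rhdf5::h5write(hiddenInstanceLabels(bag), path, nm)
      fid <- rhdf5::H5Fopen(path)
      did <- rhdf5::H5Dopen(fid, nm)
      rhdf5::h5writeAttribute(1L, did, "test_only")
      rhdf5::H5Dclose(did); rhdf5::H5Fclose(fid)
    }
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, grp)
    rhdf5::h5writeAttribute(bagLabel(bag), gid, "label")
    rhdf5::h5writeAttribute(magnification, gid, "magnification")
    rhdf5::h5writeAttribute(mpp, gid, "mpp")
    rhdf5::h5writeAttribute(slideType, gid, "slide_type")
    rhdf5::h5writeAttribute(configHash, gid, "config_hash")
    rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

#' Read a bag set back from an HDF5 embedding store
#'
#' Validates the schema: every bag group must contain `embeddings` and
#' `coords`; a missing dataset raises an error naming it.
#'
#' @param path HDF5 file written by [writeBags()].
#' @param withInstanceLabels also load the test-only hidden instance labels
#'   when present.
#' @return a [MILBagSet-class]; augmented replica sets, when present, are
#'   attached as the `"augmented"` attribute (list per bag), and per-bag
#'   metadata as the `"meta"` attribute.
#' @export
readBags <- function(path, withInstanceLabels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  bagNames <- sort(ls$name[ls$group == "/bags" & ls$otype == "H5I_GROUP"])
  if (length(bagNames) == 0L) stop("schema error: no groups under /bags")
  bags <- vector("list", length(bagNames))
  augmented <- vector("list", length(bagNames))
  meta <- vector("list", length(bagNames))
  for (i in seq_along(bagNames)) {
    grp <- paste0("/bags/", bagNames[i])
    inGrp <- ls$name[ls$group == grp]
    for (req in c("embeddings", "coords"))
      if (!req %in% inGrp)
        stop("schema error: missing dataset '", req, "' in ", grp)
    emb <- rhdf5::h5read(path, paste0(grp, "/embeddings"))
    co <- rhdf5::h5read(path, paste0(grp, "/coords"),
                        bit64conversion = "double")
    attrs <- rhdf5::h5readAttributes(path, grp)
    if (is.null(attrs$label))
      stop("schema error: missing attribute 'label' on ", grp)
    il <- integer(0)
    if (withInstanceLabels && "instance_labels" %in% inGrp)
      il <- as.integer(rhdf5::h5read(path, paste0(grp, "/instance_labels")))
    bags[[i]] <- new("MILBag", embeddings = matrix(as.numeric(emb), nrow(emb)),
                     label = as.integer(attrs$label), bagId = bagNames[i],
                     coords = matrix(as.integer(co), nrow(co)),
                     instanceLabels = il)
    augGrp <- paste0(grp, "/aug")
    ks <- ls$name[ls$group == augGrp & ls$otype == "H5I_GROUP"]
    if (length(ks))
      augmented[[i]] <- lapply(sort(as.integer(ks)), function(k)
        rhdf5::h5read(path, paste0(augGrp, "/", k, "/embeddings")))
    meta[[i]] <- attrs
  }
  out <- new("MILBagSet", bags = bags)
  attr(out, "augmented") <- augmented
  attr(out, "meta") <- meta
  out
}
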