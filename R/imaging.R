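#' Generate a synthetic grayscale photograph
#'
#' Produces a smooth correlated random field standing in for a natural
#' photograph: white Gaussian noise is low-pass filtered with an isotropic
#' Gaussian kernel (circular convolution via FFT) and min-max scaled to
#' \[0, 1\], so the image always contains both fully dark and fully light
#' regions. `correlationLength` controls the spatial scale of the light and
#' dark blobs (the kernel standard deviation is `correlationLength / 2`
#' pixels; values <= 1 leave the noise unfiltered).
#'
#' @param height,width image dimensions in pixels (default mirrors the
#'   553 x 737 source photograph of the original image experiments).
#' @param correlationLength blob scale in pixels.
#' @param seed integer seed; the image is deterministic given the seed.
#' @return numeric `height x width` matrix with values in \[0, 1\].
#' @export
syntheticPhotograph <- function(height = 553, width = 737,
                                correlationLength = 6, seed = NULL) {
  height <- assertScalarCount(height, "height")
  width <- assertScalarCount(width, "width")
  if (height < 12 || width < 12)
    stop("image must be at least 12 x 12 pixels", call. = FALSE)
  noise <- withSeed(seed, matrix(stats::rnorm(height * width), height, width))
  if (correlationLength > 1) {
    sigma <- correlationLength / 2
    g1 <- function(n) {
      d <- pmin(0:(n - 1), n - (0:(n - 1)))  # circular distance
      k <- exp(-d^2 / (2 * sigma^2))
      k / sum(k)
    }
    kern <- outer(g1(height), g1(width))
    field <- Re(stats::fft(stats::fft(noise) * stats::fft(kern),
                           inverse = TRUE)) / (height * width)
  } else {
    field <- noise
  }
  rng <- range(field)
  (field - rng[1]) / (rng[2] - rng[1])
}

#' Sample square patches from an image
#'
#' Draws `n` patches of `size x size` pixels at independent uniformly random
#' in-bounds origins (patches may overlap). Each patch is flattened in
#' row-major order to a vector of length `size^2`, matching the input-layer
#' convention (a 12 x 12 patch feeds a 144-neuron layer 1).
#'
#' @param img numeric matrix in \[0, 1\] (see [syntheticPhotograph()]).
#' @param n number of patches.
#' @param size patch side length in pixels (default 12).
#' @param seed integer seed.
#' @return numeric `n x size^2` matrix, one patch per row, with an
#'   `origins` attribute (`n x 2` matrix of top-left row/col positions).
#' @export
samplePatches <- function(img, n, size = 12, seed = NULL) {
  n <- assertScalarCount(n, "n", min = 0L)
  size <- assertScalarCount(size, "size")
  if (size > nrow(img) || size > ncol(img))
    stop("patch does not fit in the image", call. = FALSE)
  withSeed(seed, {
    rows <- sample.int(nrow(img) - size + 1L, n, replace = TRUE)
    cols <- sample.int(ncol(img) - size + 1L, n, replace = TRUE)
  })
  out <- matrix(0, n, size * size)
  for (p in seq_len(n)) {
    patch <- img[rows[p]:(rows[p] + size - 1L),
                 cols[p]:(cols[p] + size - 1L), drop = FALSE]
    out[p, ] <- as.vector(t(patch))  # row-major flattening
  }
  attr(out, "origins") <- cbind(row = rows, col = cols)
  out
}

#' Reshape a flattened patch back to an image
#' @param v numeric vector of length `size^2` (row-major).
#' @param size patch side length.
#' @return `size x size` matrix.
#' @export
patchToImage <- function(v, size = 12) {
  stopifnot(length(v) == size * size)
  matrix(v, size, size, byrow = TRUE)
}

#' Rank candidates by gene-array similarity
#'
#' Orders candidate active-gene arrays by ascending L1 distance to a
#' template array (ties broken by candidate index) — the image-search
#' operation: finding, among layer-2 responses of an image corpus, the ones
#' most similar to a (possibly deep-layer, possibly transformed) template
#' array.
#'
#' @param template numeric vector of length GR.
#' @param candidates matrix with one candidate array per row (or list of
#'   vectors).
#' @param k how many top matches to return (default: all).
#' @return integer vector of candidate indices, best match first, with the
#'   corresponding distances as attribute `distance`.
#' @export
imageSearch <- function(template, candidates, k = NULL) {
  if (is.list(candidates)) candidates <- do.call(rbind, candidates)
  if (!nrow(candidates)) stop("no candidates supplied", call. = FALSE)
  if (ncol(candidates) != length(template))
    stop("template and candidates must share one gene repertoire",
         call. = FALSE)
  d <- rowSums(abs(sweep(candidates, 2, template)))
  if (is.null(k)) k <- length(d)
  k <- min(k, length(d))
  ord <- order(d, seq_along(d))[seq_len(k)]
  structure(ord, distance = d[ord])
}

#' Input order of a reference gene array
#'
#' Permutation of gene ids sorting the reference array in descending count
#' order (ties by ascending gene id). Transformed arrays are re-aligned in
#' this order so that augmentation of high- or low-ranking genes becomes
#' visible as a left/right trend.
#'
#' @param referenceArray numeric vector over the gene repertoire.
#' @return integer permutation of `seq_along(referenceArray)`.
#' @export
inputOrder <- function(referenceArray) {
  order(-referenceArray, seq_along(referenceArray))
}

#' Optimum image of a neuron
#'
#' Pixel-wise mean of all input patches for which the neuron was active: a
#' receptive-field-like summary of the neuron's response specificity.
#'
#' @param patches `n x d` matrix of flattened input patches.
#' @param activeMatrix `n x nNeurons` logical matrix; entry (p, j) says
#'   whether neuron j was active for patch p (collect from
#'   [propagate()] states).
#' @param neuron neuron index.
#' @param size patch side length for the reshaped result.
#' @return `size x size` matrix, or `NULL` (with a warning) when the neuron
#'   was never active.
#' @export
optimumImage <- function(patches, activeMatrix, neuron, size = 12) {
  stopifnot(nrow(patches) == nrow(activeMatrix))
  rows <- which(activeMatrix[, neuron])
  if (!length(rows)) {
    warning(sprintf("neuron %d was never active; no optimum image", neuron))
    return(NULL)
  }
  patchToImage(colMeans(patches[rows, , drop = FALSE]), size = size)
}

#' Read a grayscale image from PNG
#' @param path PNG file path; color images are averaged to gray.
#' @return numeric matrix in \[0, 1\].
#' @export
readGrayImage <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                      c(1, 2), mean)
  a
}

#' Write a grayscale image to PNG
#' @param img numeric matrix; values clamped to \[0, 1\].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeGrayImage <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
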