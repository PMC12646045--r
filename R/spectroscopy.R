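#' Constant-coherence-length spectrum family
#'
#' Gaussian targets whose spectral FWHM grows with the center wavelength as
#' `dlambda_i = lambda_i^2 / (2 lc)` so every member has exactly the same
#' temporal coherence length. Scanning such a family probes the wavelength
#' dependence of the sample response while keeping the probed axial volume
#' constant.
#'
#' @param centers center wavelengths, nm
#' @param lc coherence length, um
#' @param table optional [calibration_table()]; a warning is issued when a
#'   member's FWHM falls below the instantaneous linewidth at its center
#' @return list of [target_spectrum()] objects
#' @examples
#' fam <- constant_lc_family(seq(750, 950, 25), 10.6)
#' sapply(fam, function(t) t$fwhm)  # 26.5 nm at 750 nm, growing with lambda
#' @export
constant_lc_family <- function(centers, lc, table = NULL) {
  assert_num(centers, "centers", positive = TRUE)
  assert_num(lc, "lc", len = 1, positive = TRUE)
  lapply(centers, function(c0) {
    fw <- fwhm_for_coherence_length(c0, lc)
    if (!is.null(table)) {
      lw <- linewidth_at(table, c0)
      if (fw < lw)
        warnf("FWHM %.3g nm at %.5g nm is below the instantaneous linewidth (%.3g nm)",
              fw, c0, lw)
    }
    target_spectrum("gaussian", center = c0, fwhm = fw)
  })
}

#' Threshold blob segmentation of a particle image
#'
#' Pixels above `mean + threshold_sigma * sd` are labeled into connected
#' components (EBImage), relabeled deterministically in raster order
#' (column-major first pixel), and filtered by component area.
#'
#' @param image 2-D non-negative numeric matrix
#' @param threshold_sigma threshold in standard deviations above the mean
#' @param min_area,max_area component area bounds, pixels
#' @return integer label matrix (0 = background, labels 1..n in raster
#'   order) with attribute `n` giving the component count
#' @export
segment_particles <- function(image, threshold_sigma = 3, min_area = 1,
                              max_area = Inf) {
  stopifnot(is.matrix(image))
  if (any(image < 0)) stopf("`image` must be non-negative")
  thr <- mean(image) + threshold_sigma * stats::sd(image)
  mask <- image > thr
  if (!any(mask)) {
    lab <- matrix(0L, nrow(image), ncol(image))
    attr(lab, "n") <- 0L
    return(lab)
  }
  raw <- EBImage::bwlabel(mask)
  raw <- matrix(as.integer(raw), nrow(image), ncol(image))
  sizes <- tabulate(raw)
  keep <- which(sizes >= min_area & sizes <= max_area)
  # deterministic relabeling by first occurrence in raster order
  first <- vapply(keep, function(l) which(raw == l)[1], numeric(1))
  keep <- keep[order(first)]
  lab <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_along(keep)) lab[raw == keep[i]] <- i
  attr(lab, "n") <- length(keep)
  lab
}

#' Per-particle spectra from a wavelength-indexed image stack
#'
#' Entry (p, w) is the maximum amplitude within mask p in the image at
#' wavelength w. Empty masks give a row of zeros and are flagged.
#'
#' @param stack array H x W x n_wavelengths of amplitude images
#' @param masks integer label matrix from [segment_particles()]
#' @param wavelengths wavelength of each slice, nm
#' @return a `particle_spectra` object: list with `matrix` (particles x
#'   wavelengths), `wavelengths`, `centroids` (particle x 2 pixel
#'   coordinates), `empty` (logical per particle)
#' @export
extract_particle_spectra <- function(stack, masks, wavelengths) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  if (dim(stack)[3] != length(wavelengths))
    stopf("stack depth must equal the number of wavelengths")
  if (!all(dim(masks) == dim(stack)[1:2]))
    stopf("mask shape must match the images")
  n <- max(masks)
  mat <- matrix(0, n, length(wavelengths))
  cent <- matrix(NA_real_, n, 2)
  empty <- logical(n)
  for (p in seq_len(n)) {
    idx <- which(masks == p, arr.ind = TRUE)
    if (nrow(idx) == 0L) { empty[p] <- TRUE; next }
    cent[p, ] <- colMeans(idx)
    for (w in seq_along(wavelengths))
      mat[p, w] <- max(stack[, , w][idx])
  }
  if (any(empty)) warnf("%d empty mask(s); rows set to zero", sum(empty))
  structure(list(matrix = mat, wavelengths = wavelengths, centroids = cent,
                 empty = empty),
            class = "particle_spectra")
}

#' @export
print.particle_spectra <- function(x, ...) {
  cat(sprintf("<particle_spectra> %d particles x %d wavelengths (%.5g-%.5g nm)\n",
              nrow(x$matrix), ncol(x$matrix), min(x$wavelengths),
              max(x$wavelengths)))
  invisible(x)
}

#' Principal-component filtering of particle spectra
#'
#' Mean-centered PCA of the particles x wavelengths matrix; the filtered
#' spectra are the mean plus the projection onto the first `n_components`
#' components. Filtering is idempotent, and the explained energy fractions
#' are the per-component variance fractions (non-increasing, summing to at
#' most 1).
#'
#' @param spectra a `particle_spectra`
#' @param n_components number of components kept (default 3)
#' @param center mean-center before the decomposition (default TRUE; the
#'   uncentered variant is available for comparison)
#' @return list with `filtered` (a `particle_spectra`) and
#'   `explained_energy` (fraction per kept component)
#' @export
pca_filter_spectra <- function(spectra, n_components = 3, center = TRUE) {
  stopifnot(inherits(spectra, "particle_spectra"))
  m <- spectra$matrix
  if (nrow(m) < n_components + 1)
    stopf("need at least n_components + 1 particles")
  pc <- stats::prcomp(m, center = center, scale. = FALSE)
  if (n_components > ncol(pc$rotation))
    stopf("n_components exceeds the rank of the spectra matrix")
  keep <- seq_len(n_components)
  recon <- pc$x[, keep, drop = FALSE] %*% t(pc$rotation[, keep, drop = FALSE])
  if (center) recon <- sweep(recon, 2, pc$center, "+")
  out <- spectra
  out$matrix <- recon
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(filtered = out, explained_energy = frac[keep])
}

#' Assign particles to spectral templates
#'
#' Nearest-template classification: every spectrum and every template is
#' normalized to unit Euclidean norm and each particle is assigned to the
#' template with the smallest distance (equivalently the largest cosine
#' similarity).
#'
#' @param spectra a `particle_spectra`
#' @param templates matrix (templates x wavelengths) or list of numeric
#'   vectors on the same wavelength grid
#' @return integer vector of template indices, one per particle
#' @export
classify_particle_spectra <- function(spectra, templates) {
  stopifnot(inherits(spectra, "particle_spectra"))
  tm <- if (is.list(templates)) do.call(rbind, templates) else templates
  if (ncol(tm) != ncol(spectra$matrix))
    stopf("templates must be on the particle wavelength grid")
  unit <- function(v) {
    n <- sqrt(sum(v^2)); if (n > 0) v / n else v
  }
  tm <- t(apply(tm, 1, unit))
  apply(spectra$matrix, 1, function(s) {
    s <- unit(s)
    which.min(colSums((t(tm) - s)^2))
  })
}
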