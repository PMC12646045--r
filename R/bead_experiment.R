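#' Synthetic spectroscopic bead experiment
#'
#' Generates the wavelength-series amplitude images of a two-size bead
#' phantom, the ground truth, and the Mie class templates, emulating a
#' spectroscopic FFOCT acquisition: monodisperse beads of two diameters in a
#' gel, imaged at a constant-coherence-length family of center wavelengths.
#' A fraction of the beads carries an extra, colocated aggregate
#' contribution whose spectral response is that of a much larger effective
#' sphere; additive Gaussian detection noise is applied per image.
#'
#' Beads are placed on a jittered grid so segmentation can recover each one;
#' each bead p of class c has peak amplitude
#' `a_p * (Qback_c(lambda) + strength * r * Qback_agg(lambda))` (second term
#' only when contaminated), where `a_p` is log-normal and `r` scales the
#' aggregate curve to the class's mean backscattering level. Blobs are
#' rendered as Gaussian spots of width `spot_sigma` pixels.
#'
#' @param n_particles number of beads
#' @param wavelengths center wavelengths, nm
#' @param diameters the two bead diameters, nm
#' @param aggregate_fraction fraction of beads with aggregate contamination
#' @param aggregate_diameter effective aggregate diameter, nm
#' @param aggregate_strength aggregate amplitude relative to the bead's mean
#'   level (default 0.8: aggregates contribute about as much light as the
#'   bead itself, enough to visibly distort the median spectrum)
#' @param noise additive noise sd as a fraction of the median bead peak
#' @param particle_index,medium_index refractive indices (polystyrene in
#'   agar/water by default)
#' @param spot_sigma rendered spot width, pixels
#' @param amp_sdlog log-normal sd of the per-bead amplitude
#' @param seed RNG seed
#' @return list with `stack` (H x W x wavelengths array), `wavelengths`,
#'   `truth` (data.frame: row, col, class, contaminated, amplitude),
#'   `templates` (2 x wavelengths matrix of injected Mie curves)
#' @export
simulate_bead_experiment <- function(n_particles = 200,
                                     wavelengths = seq(750, 950, 25),
                                     diameters = c(990, 505),
                                     aggregate_fraction = 0.3,
                                     aggregate_diameter = 5000,
                                     aggregate_strength = 0.8,
                                     noise = 0.05,
                                     particle_index = 1.59,
                                     medium_index = 1.34,
                                     spot_sigma = 1.5,
                                     amp_sdlog = 0.3,
                                     seed = 1) {
  set.seed(seed)
  nl <- length(wavelengths)
  tpl <- rbind(mie_backscatter(diameters[1], wavelengths, particle_index,
                               medium_index)$q_back,
               mie_backscatter(diameters[2], wavelengths, particle_index,
                               medium_index)$q_back)
  agg <- mie_backscatter(aggregate_diameter, wavelengths, particle_index,
                         medium_index)$q_back
  # jittered grid placement with a safe margin
  spacing <- 24
  ncols <- ceiling(sqrt(n_particles))
  nrows <- ceiling(n_particles / ncols)
  hw <- c(nrows, ncols) * spacing + 2 * spacing
  cells <- expand.grid(r = seq_len(nrows), c = seq_len(ncols))
  cells <- cells[seq_len(n_particles), ]
  rr <- spacing + cells$r * spacing + round(stats::runif(n_particles, -4, 4))
  cc <- spacing + cells$c * spacing + round(stats::runif(n_particles, -4, 4))
  cls <- sample(rep(1:2, length.out = n_particles))
  contaminated <- stats::runif(n_particles) < aggregate_fraction
  amp <- stats::rlnorm(n_particles, 0, amp_sdlog)
  stack <- array(0, c(hw[1], hw[2], nl))
  half <- ceiling(4 * spot_sigma)
  patch <- outer(-half:half, -half:half,
                 function(i, j) exp(-(i^2 + j^2) / (2 * spot_sigma^2)))
  for (p in seq_len(n_particles)) {
    spec <- tpl[cls[p], ]
    if (contaminated[p])
      spec <- spec + aggregate_strength * mean(tpl[cls[p], ]) / mean(agg) * agg
    ri <- (rr[p] - half):(rr[p] + half)
    ci <- (cc[p] - half):(cc[p] + half)
    for (w in seq_len(nl))
      stack[ri, ci, w] <- stack[ri, ci, w] + amp[p] * spec[w] * patch
  }
  peak_ref <- stats::median(amp * tpl[cls, 1])
  stack <- stack + array(stats::rnorm(length(stack), 0, noise * peak_ref),
                         dim(stack))
  stack[stack < 0] <- 0
  list(stack = stack, wavelengths = wavelengths,
       truth = data.frame(row = rr, col = cc, class = cls,
                          contaminated = contaminated, amplitude = amp),
       templates = tpl)
}

#' Full synthetic spectroscopy pipeline
#'
#' Runs the spectroscopic analysis end to end on a
#' [simulate_bead_experiment()] acquisition: segment the beads on the
#' wavelength-mean image, extract per-particle spectra, PCA-filter them, and
#' assign each particle to the nearest injected Mie template. Detected
#' components are matched to ground-truth beads by nearest centroid.
#'
#' @param experiment output of [simulate_bead_experiment()]
#' @param n_components PCA components kept (default 3)
#' @param threshold_sigma segmentation threshold
#' @return list with `spectra` (raw), `filtered`, `explained_energy`,
#'   `assigned` (template index per detected particle), `true_class`
#'   (matched ground truth), `accuracy`, `n_detected`
#' @export
analyze_bead_experiment <- function(experiment, n_components = 3,
                                    threshold_sigma = 2) {
  ex <- experiment
  ref_img <- apply(ex$stack, c(1, 2), mean)
  masks <- segment_particles(ref_img, threshold_sigma = threshold_sigma,
                             min_area = 3)
  spectra <- extract_particle_spectra(ex$stack, masks, ex$wavelengths)
  flt <- pca_filter_spectra(spectra, n_components = n_components)
  assigned <- classify_particle_spectra(flt$filtered, ex$templates)
  # match detected centroids to injected beads
  true_class <- vapply(seq_len(nrow(spectra$centroids)), function(p) {
    d2 <- (ex$truth$row - spectra$centroids[p, 1])^2 +
          (ex$truth$col - spectra$centroids[p, 2])^2
    ex$truth$class[which.min(d2)]
  }, integer(1))
  list(spectra = spectra, filtered = flt$filtered,
       explained_energy = flt$explained_energy, assigned = assigned,
       true_class = true_class,
       accuracy = mean(assigned == true_class),
       n_detected = nrow(spectra$matrix))
}
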