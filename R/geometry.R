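#' FFOCT system geometry
#'
#' Optical layout parameters of the imaging chain. The objective focal
#' length follows the 180 mm reference-tube-length convention, so a 4x
#' objective has f = 180/4 = 45 mm and the tube lens gives a system
#' magnification of 300/45 = 6.67.
#'
#' @param camera_pixel physical camera pixel pitch, um
#' @param tube_lens_focal tube lens focal length, mm
#' @param objective_magnification nominal objective magnification
#' @param objective_reference_focal reference tube length convention, mm
#' @param relay_magnification fiber-output to pupil-plane magnification
#' @param fiber a [fiber_spec()]
#' @param n_pixels camera pixels per side
#' @return a `system_geometry` object
#' @export
system_geometry <- function(camera_pixel = 12, tube_lens_focal = 300,
                            objective_magnification = 4,
                            objective_reference_focal = 180,
                            relay_magnification = 4.17,
                            fiber = fiber_spec(), n_pixels = 1440) {
  for (nm in c("camera_pixel", "tube_lens_focal", "objective_magnification",
               "objective_reference_focal", "relay_magnification", "n_pixels"))
    assert_num(get(nm), nm, len = 1, positive = TRUE)
  stopifnot(inherits(fiber, "fiber_spec"))
  structure(list(camera_pixel = camera_pixel,
                 tube_lens_focal = tube_lens_focal,
                 objective_magnification = objective_magnification,
                 objective_reference_focal = objective_reference_focal,
                 relay_magnification = relay_magnification,
                 fiber = fiber, n_pixels = n_pixels),
            class = "system_geometry")
}

#' System magnification (tube lens over objective focal length)
#' @param geom a [system_geometry()]
#' @return magnification, dimensionless
#' @export
system_magnification <- function(geom) {
  stopifnot(inherits(geom, "system_geometry"))
  geom$tube_lens_focal /
    (geom$objective_reference_focal / geom$objective_magnification)
}

#' Sample-plane pixel size
#'
#' Camera pixel pitch divided by the system magnification: 12 um pixels with
#' a 300 mm tube lens and a 4x (f = 45 mm) objective give 1.8 um.
#'
#' @param geom a [system_geometry()]
#' @return pixel size in the sample plane, um
#' @export
sample_pixel_size <- function(geom) {
  stopifnot(inherits(geom, "system_geometry"))
  geom$camera_pixel / system_magnification(geom)
}

#' Field of view (square side) in the sample plane
#' @param geom a [system_geometry()]
#' @return side length, mm
#' @export
field_of_view <- function(geom) {
  sample_pixel_size(geom) * geom$n_pixels / 1000
}

#' Illumination beam diameter in the objective pupil plane
#'
#' Fiber core diameter times the relay magnification: a 200 um core relayed
#' at G = 4.17 gives a 0.834 mm beam.
#'
#' @param geom a [system_geometry()]
#' @return beam diameter, mm
#' @export
pupil_beam_diameter <- function(geom) {
  stopifnot(inherits(geom, "system_geometry"))
  geom$fiber$core_diameter / 1000 * geom$relay_magnification
}
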