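#' Synthetic reflector phantom
#'
#' A phantom is a list of discrete reflectors at geometric depths (um) with
#' amplitude reflectivities sqrt(R), embedded in a medium of given refractive
#' index. The optical path difference of a reflector relative to zero OPD is
#' `2 * depth * medium_index` (double pass). An optional `spectral_response`
#' id per reflector points at a wavelength-dependent scattering amplitude
#' (used by the spectroscopy tools).
#'
#' @param depth reflector depths, um (>= 0)
#' @param reflectivity amplitude reflectivities sqrt(R) (>= 0)
#' @param spectral_response optional character ids, one per reflector
#' @param medium_index refractive index of the medium (>= 1)
#' @return a `phantom` object
#' @export
phantom <- function(depth, reflectivity = rep(1, length(depth)),
                    spectral_response = NULL, medium_index = 1) {
  assert_num(depth, "depth", nonneg = TRUE)
  assert_num(reflectivity, "reflectivity", len = length(depth), nonneg = TRUE)
  assert_num(medium_index, "medium_index", len = 1)
  if (medium_index < 1) stopf("`medium_index` must be >= 1")
  if (!is.null(spectral_response) && length(spectral_response) != length(depth))
    stopf("`spectral_response` must have one id per reflector")
  structure(list(depth = depth, reflectivity = reflectivity,
                 spectral_response = spectral_response,
                 medium_index = medium_index),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d reflector(s), depths %s um, medium index %g\n",
              length(x$depth),
              paste(signif(utils::head(x$depth, 5), 4), collapse = ", "),
              x$medium_index))
  invisible(x)
}

#' Optical path differences of the reflectors
#' @param ph a `phantom`
#' @return OPDs, um (`2 * depth * medium_index`)
#' @export
phantom_opd <- function(ph) {
  stopifnot(inherits(ph, "phantom"))
  2 * ph$depth * ph$medium_index
}

#' Phantom fixture generators
#'
#' * `mirror`: one reflector at `params$depth` (um, default 6).
#' * `two_mirror`: reflectors at `params$depth` and `params$depth +
#'   params$separation_opd / (2 * medium_index)`, i.e. separated by a given
#'   OPD (roll-off fixture).
#' * `beads3d`: `params$n` reflectors at uniform random depths in
#'   `params$depth_range` with diameters drawn from `params$diameters` (nm);
#'   a fraction `params$aggregate_fraction` is marked with the aggregate
#'   spectral response (`params$aggregate_diameter`, default 5000 nm
#'   effective diameter). Spectral response ids are `"bead_<diameter>"` or
#'   `"aggregate_<diameter>"`.
#' * `layered`: `params$n` interfaces every `params$period` um starting at
#'   `params$depth0`.
#'
#' A warning is issued when two reflectors fall closer than `params$dz_min`
#' (um) if given. Generation is a pure function of `(params, seed)`.
#'
#' @param kind one of `"mirror"`, `"two_mirror"`, `"beads3d"`, `"layered"`
#' @param params named list of parameters, see Details
#' @param seed RNG seed (used by `beads3d`)
#' @return a [phantom()]
#' @examples
#' make_phantom("mirror", list(depth = 6))        # 12 um of optical path
#' @export
make_phantom <- function(kind = c("mirror", "two_mirror", "beads3d", "layered"),
                         params = list(), seed = 1) {
  kind <- match.arg(kind)
  p <- params
  n_medium <- p$medium_index %||% 1
  ph <- switch(kind,
    mirror = phantom(p$depth %||% 6, p$reflectivity %||% 1,
                     medium_index = n_medium),
    two_mirror = {
      d1 <- p$depth %||% 2
      sep <- p$separation_opd %||% 20
      phantom(c(d1, d1 + sep / (2 * n_medium)),
              p$reflectivity %||% c(1, 1), medium_index = n_medium)
    },
    beads3d = {
      set.seed(seed)
      n <- p$n %||% 50
      rng <- p$depth_range %||% c(2, 20)
      dia <- sample(p$diameters %||% c(990, 505), n, replace = TRUE)
      agg <- stats::runif(n) < (p$aggregate_fraction %||% 0)
      ids <- ifelse(agg,
                    paste0("aggregate_", p$aggregate_diameter %||% 5000),
                    paste0("bead_", dia))
      phantom(stats::runif(n, rng[1], rng[2]),
              p$reflectivity %||% rep(1, n),
              spectral_response = ids, medium_index = n_medium)
    },
    layered = {
      n <- p$n %||% 5
      phantom((p$depth0 %||% 2) + (seq_len(n) - 1) * (p$period %||% 5),
              p$reflectivity %||% rep(1, n), medium_index = n_medium)
    })
  if (!is.null(p$dz_min) && length(ph$depth) > 1) {
    if (min(diff(sort(ph$depth))) < p$dz_min / 2)
      warnf("reflectors closer than dz_min/2 = %g um may be unresolved",
            p$dz_min / 2)
  }
  ph
}
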