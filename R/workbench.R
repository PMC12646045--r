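#' Read a run configuration from YAML or JSON
#'
#' Recognized fields (all optional, with defaults): `band` (nm, length 2),
#' `n_frames`, `window`, `zero_pad`, `seed`, `shape_exposure` (logical),
#' `phantom` (list with `kind` and `params`), `full_well`.
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`
#' @return named list
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stopf("config must be .yaml/.yml or .json")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a swept-source experiment end to end
#'
#' Wires the pipeline together: design the k-linear sweep (with optional
#' duty-cycle spectral flattening), build the phantom, simulate the k-stack,
#' reconstruct, and measure the PSF metrics. Writes the axial profile as
#' CSV, the sweep plan as CSV, and a JSON manifest carrying the metrics,
#' seed, config hash and package version; reruns of the same config are
#' byte-identical for the CSV/JSON outputs.
#'
#' @param config named list (see [read_run_config()]) or a path to one
#' @param out_dir output directory (created if missing)
#' @return list with `profile`, `metrics`, `files` (invisibly writes them)
#' @export
run_experiment <- function(config, out_dir = tempfile("ffoct_run_")) {
  if (is.character(config)) config <- read_run_config(config)
  band <- config$band %||% c(650, 950)
  n_frames <- config$n_frames %||% 250
  window <- config$window %||% "hamming"
  zero_pad <- config$zero_pad %||% 8
  seed <- config$seed %||% 1
  table <- default_calibration()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("[%s] %s", name, conditionMessage(e)))
  }
  plan <- stage("design", {
    p <- design_k_linear_sweep(band[1], band[2], n_frames, table)
    if (isTRUE(config$shape_exposure)) p <- design_exposure_shaping(p, table)
    p
  })
  ph <- stage("phantom", {
    pk <- config$phantom %||% list(kind = "mirror", params = list(depth = 6))
    make_phantom(pk$kind, pk$params %||% list(), seed = seed)
  })
  st <- stage("simulate",
    simulate_ss_stack(ph, plan, table, full_well = config$full_well,
                      seed = seed))
  pr <- stage("reconstruct",
    ss_reconstruct(st, window = window, zero_pad = zero_pad))
  met <- stage("metrics", {
    m <- psf_metrics(pr)
    m$depth_range_um <- depth_range(n_frames, band[1], band[2])
    m
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(profile = file.path(out_dir, "profile.csv"),
             plan = file.path(out_dir, "sweep_plan.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  write_profile_csv(pr, files[["profile"]])
  write_sweep_csv(plan, files[["plan"]], table)
  manifest <- list(metrics = met, seed = seed, config = config,
                   config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("ffoctsim")))
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(profile = pr, metrics = met, files = files))
}

#' Save / load a k-stack as multi-page TIFF plus JSON sidecar
#'
#' Frames are written in ascending-k order as 32-bit float TIFF pages; the
#' sidecar (`<path>.json`) stores the sweep plan, reference frames and
#' metadata so the stack round-trips.
#'
#' @param stack a [kstack()]
#' @param path TIFF path
#' @return `path` (`write_kstack_tiff`) or a [kstack()] (`read_kstack_tiff`)
#' @export
write_kstack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "kstack"))
  fr <- stack$frames
  if (!is.array(fr) || length(dim(fr)) != 3)
    fr <- array(fr, c(1, 1, length(fr)))
  pages <- lapply(seq_len(dim(fr)[3]), function(i) fr[, , i, drop = TRUE])
  pages <- lapply(pages, function(p) matrix(p, dim(fr)[1], dim(fr)[2]))
  scale <- max(unlist(pages), 1e-12)
  tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                  bits.per.sample = 32L)
  side <- list(wavelengths = stack$plan$wavelengths,
               exposure_weights = stack$plan$exposure_weights,
               frame_period = stack$plan$frame_period,
               reference_frames = as.vector(stack$reference_frames),
               reference_dim = dim(stack$reference_frames),
               intensity_scale = scale,
               meta = stack$meta[setdiff(names(stack$meta), "eta")],
               eta = stack$meta$eta,
               frame_order = "k ascending")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_kstack_tiff
#' @export
read_kstack_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  scale <- side$intensity_scale
  plan <- sweep_plan(side$wavelengths, side$exposure_weights,
                     side$frame_period)
  d <- dim(pages[[1]])
  fr <- array(unlist(pages), c(d[1], d[2], length(pages))) * scale
  ref <- side$reference_frames
  if (length(side$reference_dim) == 3) dim(ref) <- side$reference_dim
  if (d[1] == 1 && d[2] == 1) fr <- as.vector(fr)
  meta <- as.list(side$meta %||% list())
  meta$eta <- side$eta
  kstack(plan, fr, ref, meta = meta)
}
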