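# Storage, configuration and reporting.  Complex-valued objects
# (k-space, motion fields, subspaces) round-trip bit-exactly through
# R-native serialization; magnitude series and displacement fields are
# additionally exported as NIfTI for interoperability; reports are
# JSON + CSV; configurations are YAML.

#' Write / read radial k-space data
#'
#' `write_kspace` stores an `lrmc_kspace` object (complex samples,
#' trajectory, density weights, noise metadata) in a single file;
#' `read_kspace` loads and validates it, raising a format error that
#' names the first missing element.
#'
#' @param kspace `lrmc_kspace` object.
#' @param path file path (conventionally `.rds`).
#' @return `read_kspace` returns the validated `lrmc_kspace`.
#' @export
write_kspace <- function(kspace, path) {
  stopifnot(inherits(kspace, "lrmc_kspace"))
  saveRDS(kspace, path)
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) {
  obj <- readRDS(path)
  required <- c("data", "traj", "dcf")
  miss <- setdiff(required, names(obj))
  if (length(miss))
    stop("format error: k-space file is missing element(s): ",
         paste(miss, collapse = ", "))
  if (!inherits(obj, "lrmc_kspace")) class(obj) <- "lrmc_kspace"
  obj
}

#' Write / read an image series
#'
#' Magnitude series are written as a single 3D NIfTI volume (frames
#' along the third dimension, float64); complex series are written as a
#' pair of real/imaginary NIfTI volumes with suffixes `_real` / `_imag`
#' before the extension.  Reading reverses the layout.
#'
#' @param series array `[N, N, n_frames]`, real or complex.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `read_series` returns the array (complex when the pair
#'   layout is found).
#' @export
write_series <- function(series, path) {
  if (is.complex(series)) {
    RNifti::writeNifti(RNifti::asNifti(Re(series), datatype = "double"),
                       series_part_path(path, "real"))
    RNifti::writeNifti(RNifti::asNifti(Im(series), datatype = "double"),
                       series_part_path(path, "imag"))
  } else {
    RNifti::writeNifti(RNifti::asNifti(series, datatype = "double"), path)
  }
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  pre <- series_part_path(path, "real")
  pim <- series_part_path(path, "imag")
  if (file.exists(pre) && file.exists(pim)) {
    re <- as.array(RNifti::readNifti(pre))
    im <- as.array(RNifti::readNifti(pim))
    out <- re + 1i * im
    dim(out) <- dim(re)
    return(out)
  }
  if (!file.exists(path)) stop("format error: no series found at ", path)
  as.array(RNifti::readNifti(path))
}

series_part_path <- function(path, part) {
  sub("(\\.nii(\\.gz)?)$", paste0("_", part, "\\1"), path)
}

#' Write displacement fields as NIfTI
#'
#' Forward fields of a motion series as a 4D volume
#' `[N, N, 2, n_frames]` (row/col displacement channels), float64.
#' @param motion `lrmc_motion`.
#' @param path `.nii` path.
#' @export
write_fields <- function(motion, path) {
  stopifnot(inherits(motion, "lrmc_motion"))
  RNifti::writeNifti(RNifti::asNifti(motion$forward, datatype = "double"), path)
  invisible(path)
}

#' Write a metrics report as JSON (and CSV tables)
#'
#' @param report `lrmc_report` from [evaluate_reconstructions()].
#' @param path `.json` path; sibling `.csv` files are written for the
#'   sharpness and CoV tables.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "lrmc_report"))
  jsonlite::write_json(list(sharpness = report$sharpness,
                            cov = report$cov,
                            mae = report$mae,
                            key_frames = as.list(report$key_frames)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  base <- sub("\\.json$", "", path)
  utils::write.csv(report$sharpness, paste0(base, "_sharpness.csv"),
                   row.names = FALSE)
  utils::write.csv(report$cov, paste0(base, "_cov.csv"), row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Every tunable parameter of the simulate / estimate / reconstruct /
#' evaluate pipeline, with defaults matching the targeted acquisition
#' protocol and the package's reference reconstruction settings (6
#' itSENSE iterations; LpS lambda_L = lambda_S = 0.1 with 6 iterations;
#' 5 ICA modes and a (0.2, 0.5) Hz respiratory band; ADMM 10 x 3 with
#' lambda = 1e-3; 96% subspace energy).  The configuration round-trips losslessly through
#' YAML ([read_config()] / [write_config()]).
#'
#' @param matrix_size,n_frames,n_coils,spokes_per_frame phantom /
#'   trajectory geometry.
#' @param seed master seed for all randomness.
#' @param ... overrides for any nested field, as `section.name = value`
#'   pairs are not supported; modify the returned list instead.
#' @return nested list of class `lrmc_config`.
#' @export
default_config <- function(matrix_size = 128, n_frames = 60, n_coils = 8,
                           spokes_per_frame = 53, seed = 1L, ...) {
  cfg <- list(
    phantom = list(matrix_size = matrix_size, n_frames = n_frames,
                   heartbeat_interval_s = 1.0, n_coils = n_coils,
                   spokes_per_frame = spokes_per_frame,
                   samples_per_spoke = 2 * matrix_size,
                   motion_amplitude_px = round(10 * matrix_size / 128, 1),
                   resp_freq_hz = 0.3, noise_fraction = 0.02,
                   texture_strength = 0.08),
    itsense = list(n_iters = 6),
    ica = list(n_components = 5, resp_band_hz = c(0.2, 0.5),
               remove = "in_band"),
    registration = list(grid_spacing_px = 16, levels = 3,
                        bending_weight = 1e-2, max_iter = 60),
    subspace = list(energy_threshold = 0.96, rank = NULL),
    lps = list(lambda_L = 0.1, lambda_S = 0.1, n_iters = 6),
    admm = list(outer_iters = 10, inner_cg_iters = 3, lambda_reg = 1e-3,
                penalty_mu = NULL, cg_tolerance = 1e-6),
    patch = list(patch_size = 5, search_window = 21, n_similar = 10,
                 stride = 2, matching_reference = "rss",
                 threshold_rule = "soft"),
    metrics = list(cov_window = 7, n_profiles = 10),
    methods = c("zerofill", "itsense", "lps", "lrmc"),
    seed = as.integer(seed)
  )
  structure(utils::modifyList(cfg, list(...)), class = "lrmc_config")
}

#' Read / write a pipeline configuration (YAML)
#' @param cfg `lrmc_config` list.
#' @param path `.yaml` path.
#' @return `read_config` returns the `lrmc_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  cfg <- utils::modifyList(unclass(base), cfg)
  structure(cfg, class = "lrmc_config")
}

#' Run the full reconstruction pipeline
#'
#' Orchestrates: phantom simulation (or an externally supplied k-space
#' file) -> auxiliary itSENSE -> ICA motion references -> nonrigid
#' motion estimation -> motion-aligned subspace estimation -> LRMC
#' (plus the requested baselines) -> metric evaluation.  Every stage
#' output is written under `out_dir` together with a JSON manifest;
#' stages whose outputs already exist are reloaded when
#' `resume = TRUE`, so the pipeline can be re-entered at any stage.
#' Fully deterministic given `config$seed`.
#'
#' @param config [default_config()] list.
#' @param out_dir output directory (created if needed).
#' @param resume reload existing stage outputs instead of recomputing.
#' @param verbose print stage progress.
#' @return invisibly, a list with every stage product (`phantom`,
#'   `kspace`, `itsense`, `ica`, `motion`, `subspace`, `recons`,
#'   `report`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("lrmcperf_"),
                         resume = FALSE, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[lrmcperf] ", ...)
  stage_path <- function(nm) file.path(out_dir, paste0(nm, ".rds"))
  stage <- function(nm, expr) {
    p <- stage_path(nm)
    if (resume && file.exists(p)) {
      say("stage ", nm, ": reloaded")
      return(readRDS(p))
    }
    say("stage ", nm, " ...")
    val <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e)))
    saveRDS(val, p)
    val
  }

  pc <- config$phantom
  phantom <- stage("phantom", {
    spec <- phantom_spec(matrix_size = pc$matrix_size, n_frames = pc$n_frames,
                         heartbeat_interval_s = pc$heartbeat_interval_s,
                         n_coils = pc$n_coils,
                         spokes_per_frame = pc$spokes_per_frame,
                         samples_per_spoke = pc$samples_per_spoke,
                         motion_amplitude_px = pc$motion_amplitude_px,
                         resp_freq_hz = pc$resp_freq_hz,
                         noise_fraction = pc$noise_fraction,
                         texture_strength = pc$texture_strength,
                         seed = config$seed)
    make_phantom(spec)
  })
  kspace <- stage("kspace", sample_kspace(phantom))
  maps <- phantom$coil_maps

  its <- stage("itsense", itsense(kspace, maps, n_iters = config$itsense$n_iters))
  ica <- stage("ica", ica_references(abs(its),
                                     n_components = config$ica$n_components,
                                     resp_band_hz = config$ica$resp_band_hz,
                                     frame_rate_hz = 1 / pc$heartbeat_interval_s,
                                     seed = config$seed,
                                     remove = config$ica$remove))
  motion <- stage("motion", {
    rg <- config$registration
    estimate_motion(abs(its), ica$Xref,
                    grid_spacing_px = rg$grid_spacing_px, levels = rg$levels,
                    bending_weight = rg$bending_weight, max_iter = rg$max_iter)
  })
  sub <- stage("subspace", {
    Xal <- align_series(abs(its), motion)
    estimate_subspace(Xal, energy_threshold = config$subspace$energy_threshold,
                      roi = phantom$roi, rank = config$subspace$rank)
  })

  recons <- list()
  if ("zerofill" %in% config$methods)
    recons$zerofill <- stage("recon_zerofill", zerofill_recon(kspace, maps))
  if ("itsense" %in% config$methods)
    recons$itsense <- its
  if ("lps" %in% config$methods)
    recons$lps <- stage("recon_lps", lps(kspace, maps,
                                         lambda_L = config$lps$lambda_L,
                                         lambda_S = config$lps$lambda_S,
                                         n_iters = config$lps$n_iters))$M
  if ("lrmc" %in% config$methods)
    recons$lrmc <- stage("recon_lrmc", {
      ac <- config$admm
      pcfg <- config$patch
      lrmc(kspace, maps, motion, sub,
           admm = admm_config(outer_iters = ac$outer_iters,
                              inner_cg_iters = ac$inner_cg_iters,
                              lambda_reg = ac$lambda_reg,
                              penalty_mu = ac$penalty_mu,
                              cg_tolerance = ac$cg_tolerance,
                              seed = config$seed),
           patch = patch_config(patch_size = pcfg$patch_size,
                                search_window = pcfg$search_window,
                                n_similar = pcfg$n_similar,
                                stride = pcfg$stride,
                                matching_reference = pcfg$matching_reference,
                                threshold_rule = pcfg$threshold_rule))
    })$series

  report <- stage("report", evaluate_reconstructions(
    recons, phantom, co_registered = intersect("lrmc", names(recons)),
    cov_window = config$metrics$cov_window,
    n_profiles = config$metrics$n_profiles))
  write_report(report, file.path(out_dir, "report.json"))

  manifest <- list(
    created = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    stages = c("phantom", "kspace", "itsense", "ica", "motion", "subspace",
               paste0("recon_", setdiff(names(recons), "itsense")), "report"),
    config = unclass(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(phantom = phantom, kspace = kspace, itsense = its,
                 ica = ica, motion = motion, subspace = sub,
                 recons = recons, report = report, manifest = manifest,
                 out_dir = out_dir))
}
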