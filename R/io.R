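# On-disk interchange: dynamic series as NIfTI 4D + frame-schedule CSV +
# JSON metadata, yield maps as NIfTI + JSON sidecar, and YAML/JSON pipeline
# configuration. The same trio is accepted for externally produced data.

#' Write / read a dynamic series
#'
#' A series is stored as three files sharing a basename: `<base>.nii` (4D
#' volume), `<base>_frames.csv` (`frame_start_s`, `frame_end_s`) and
#' `<base>.json` (metadata: voxel size, beam energy, normalisation, noise
#' seed).
#'
#' @param series A `dynamic_series`.
#' @param base Path basename (without extension).
#' @return `write_dynamic_series()` the basename, invisibly;
#'   `read_dynamic_series()` a `dynamic_series`.
#' @export
write_dynamic_series <- function(series, base) {
  stopifnot(inherits(series, "dynamic_series"))
  vox <- series$meta$voxel_mm %||% c(1, 1, 1)
  img <- RNifti::asNifti(series$counts, pixdim = c(vox, 1))
  RNifti::writeNifti(img, paste0(base, ".nii"))
  utils::write.csv(data.frame(frame_start_s = series$schedule$start_s,
                              frame_end_s = series$schedule$end_s),
                   paste0(base, "_frames.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(series$meta, paste0(base, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(base)
}

#' @rdname write_dynamic_series
#' @export
read_dynamic_series <- function(base) {
  img <- RNifti::readNifti(paste0(base, ".nii"))
  fr <- utils::read.csv(paste0(base, "_frames.csv"))
  sched <- structure(data.frame(start_s = fr$frame_start_s,
                                end_s = fr$frame_end_s),
                     class = c("frame_schedule", "data.frame"))
  validate_schedule(sched)
  counts <- array(as.numeric(img), dim = dim(img))
  if (length(dim(counts)) != 4L) stop("expected a 4D volume in ", base, ".nii")
  if (dim(counts)[4] != nrow(sched))
    stop("frame count in NIfTI does not match the schedule")
  meta_path <- paste0(base, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(list(counts = counts, schedule = sched, meta = meta),
            class = "dynamic_series")
}

#' Write a 3D volume as NIfTI with a JSON sidecar
#'
#' Used for yield maps, S_v maps and component images.
#'
#' @param volume 3D array.
#' @param base Path basename.
#' @param voxel_mm Voxel sizes, mm.
#' @param meta Extra metadata stored in the sidecar.
#' @return The basename, invisibly.
#' @export
write_volume <- function(volume, base, voxel_mm = c(1, 1, 1), meta = list()) {
  img <- RNifti::asNifti(volume, pixdim = voxel_mm)
  RNifti::writeNifti(img, paste0(base, ".nii"))
  meta$voxel_mm <- voxel_mm
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(base)
}

#' Write a depth profile as CSV
#'
#' Two columns, `depth_mm` and `value`.
#'
#' @param profile A [depth_profile()].
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline configuration
#'
#' YAML or JSON file with optional keys `phantom` (`size_mm`, `voxel_mm`,
#' `density_g_cm3`, `mass_fractions`), `beam` (`energy_MeV`, `diameter_mm`,
#' `entry_mm`) and `model` (`mode`, `bk_alpha`, `bk_p`). Missing keys fall
#' back to the package defaults.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return List with `phantom` ([phantom_spec()]), `beam` ([beam_spec()] or
#'   `NULL`), `model` ([stopping_model()]).
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  mat <- water_gel()
  if (!is.null(cfg$phantom$density_g_cm3) || !is.null(cfg$phantom$mass_fractions)) {
    fr <- cfg$phantom$mass_fractions %||% as.list(water_gel()$mass_fractions)
    mat <- material_composition(cfg$phantom$density_g_cm3 %||% 1.010,
                                unlist(fr))
  }
  phantom <- phantom_spec(unlist(cfg$phantom$size_mm) %||% c(100, 100, 400),
                          unlist(cfg$phantom$voxel_mm) %||% c(10, 10, 0.5),
                          mat)
  beam <- if (!is.null(cfg$beam$energy_MeV)) {
    beam_spec(cfg$beam$energy_MeV, cfg$beam$diameter_mm %||% 10,
              unlist(cfg$beam$entry_mm))
  }
  model <- stopping_model(cfg$model$mode %||% "bragg_kleeman",
                          bk_alpha = cfg$model$bk_alpha %||% 0.0022,
                          bk_p = cfg$model$bk_p %||% 1.77)
  list(phantom = phantom, beam = beam, model = model)
}
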