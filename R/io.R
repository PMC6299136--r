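# File formats: CSV for intervals/signals/tables, NIfTI for image data,
# JSON for ground truth / transforms / manifests, YAML for configs.

#' Write / read a hypnogram CSV (`start_s,end_s,state`)
#' @param hyp hypnogram tibble.
#' @param path file path.
#' @return `read_hypnogram` returns the hypnogram tibble.
#' @export
write_hypnogram <- function(hyp, path) {
  utils::write.csv(hyp[, c("start_s", "end_s", "state")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("start_s", "end_s", "state") %in% names(df))) {
    abort(paste0("not a hypnogram CSV: ", path))
  }
  tibble::as_tibble(df)
}

#' Write / read a sampled-signal CSV (`time_s,value`)
#' @param x signal tibble.
#' @param path file path.
#' @return `read_signal_csv` returns the signal tibble.
#' @export
write_signal_csv <- function(x, path) {
  utils::write.csv(x[, c("time_s", "value")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    abort(paste0("not a signal CSV: ", path))
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    abort(paste0("non-monotone time column in ", path))
  }
  tibble::as_tibble(df)
}

#' Write / read a Doppler movie as NIfTI plus a frame-time sidecar CSV
#' @param movie a `doppler_movie`.
#' @param path NIfTI file path (`.nii` / `.nii.gz`); the sidecar is
#'   `<path>.times.csv`.
#' @return `read_movie_nifti` returns the `doppler_movie`.
#' @export
write_movie_nifti <- function(movie, path) {
  RNifti::writeNifti(movie$data, path)
  utils::write.csv(data.frame(time_s = movie$frame_times_s,
                              normalized = movie$normalized),
                   paste0(path, ".times.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_movie_nifti
#' @export
read_movie_nifti <- function(path) {
  arr <- array(as.numeric(RNifti::readNifti(path)),
               dim = dim(RNifti::readNifti(path)))
  side <- utils::read.csv(paste0(path, ".times.csv"))
  if (dim(arr)[3] != nrow(side)) {
    abort(sprintf("shape error: %d movie frames but %d timestamps in %s",
                  dim(arr)[3], nrow(side), path))
  }
  doppler_movie(arr, side$time_s, normalized = isTRUE(all(side$normalized)))
}

#' Write / read a region label map (NIfTI grid + names CSV)
#' @param labels a `region_labels`.
#' @param path NIfTI path; names table goes to `<path>.names.csv`.
#' @return `read_labels_nifti` returns the `region_labels`.
#' @export
write_labels_nifti <- function(labels, path) {
  RNifti::writeNifti(labels$labels, path)
  utils::write.csv(labels$names, paste0(path, ".names.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_nifti
#' @export
read_labels_nifti <- function(path) {
  m <- RNifti::readNifti(path)
  lab <- matrix(as.integer(m), dim(m)[1], dim(m)[2])
  nm <- tibble::as_tibble(utils::read.csv(paste0(path, ".names.csv"),
                                          stringsAsFactors = FALSE))
  structure(list(labels = lab, names = nm), class = "region_labels")
}

#' Serialize a plane transform to JSON (9 named parameters + convention)
#' @param tf a `plane_transform`.
#' @param path JSON file path.
#' @return `read_plane_transform` returns the `plane_transform`.
#' @export
write_plane_transform <- function(tf, path) {
  jsonlite::write_json(list(offsets = tf$offsets, scalings = tf$scalings,
                            rotations = tf$rotations,
                            convention = tf$convention),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plane_transform
#' @export
read_plane_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  plane_transform(j$offsets, j$scalings, j$rotations)
}

#' Write a full synthetic recording bundle to a directory
#'
#' Writes signals (CSV), movie and labels (NIfTI + sidecars), hypnogram
#' (CSV), ground truth (JSON), config (YAML) and a `manifest.json` naming
#' every file with its MD5 checksum and core metadata.
#'
#' @param sim list from [simulate_recording()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_recording <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_signal_csv(sim$lfp, p("lfp.csv"))
  write_signal_csv(sim$emg, p("emg.csv"))
  write_signal_csv(sim$acc, p("acc.csv"))
  write_hypnogram(sim$hypnogram, p("hypnogram.csv"))
  write_movie_nifti(sim$movie, p("movie.nii.gz"))
  write_labels_nifti(sim$labels, p("labels.nii.gz"))
  truth <- sim$truth
  jsonlite::write_json(list(
    surge_intervals = truth$surge_intervals,
    bursts = truth$bursts,
    kernel_lag_s = as.list(truth$kernel_lag_s),
    coupling_gain = truth$coupling_gain
  ), p("truth.json"), digits = NA, auto_unbox = TRUE, dataframe = "columns")
  cfg <- sim$config
  cfg$state_cbv_offsets <- as.data.frame(cfg$state_cbv_offsets)
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  files <- c("lfp.csv", "emg.csv", "acc.csv", "hypnogram.csv",
             "movie.nii.gz", "movie.nii.gz.times.csv", "labels.nii.gz",
             "labels.nii.gz.names.csv", "truth.json", "config.yaml")
  manifest <- list(
    files = lapply(setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(p(f))))
    }),
    duration_s = sim$config$duration_s,
    lfp_rate = sim$config$lfp_rate,
    cbv_rate = sim$config$cbv_rate,
    seed = sim$config$seed
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(p("manifest.json"))
}

#' Read and validate a recording bundle directory
#'
#' Checks that every file named in the manifest exists and that the
#' declared durations agree across modalities within 1 s; failures name
#' the offending file and quantity.
#'
#' @param dir bundle directory containing `manifest.json`.
#' @return a `recording_bundle` list: `lfp`, `emg`, `acc`, `hypnogram`,
#'   `movie`, `labels`, `truth`, `config`, `manifest`.
#' @export
read_bundle <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) abort(paste0("missing manifest: ", mpath))
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  for (f in rownames(manifest$files) %||% names(manifest$files)) {
    if (!file.exists(file.path(dir, f))) {
      abort(paste0("missing file listed in manifest: ", f))
    }
  }
  p <- function(f) file.path(dir, f)
  bundle <- list(
    lfp = read_signal_csv(p("lfp.csv")),
    emg = read_signal_csv(p("emg.csv")),
    acc = read_signal_csv(p("acc.csv")),
    hypnogram = read_hypnogram(p("hypnogram.csv")),
    movie = read_movie_nifti(p("movie.nii.gz")),
    labels = read_labels_nifti(p("labels.nii.gz")),
    truth = jsonlite::read_json(p("truth.json"), simplifyVector = TRUE),
    config = yaml::read_yaml(p("config.yaml")),
    manifest = manifest
  )
  dur <- manifest$duration_s
  for (nm in c("lfp", "emg", "acc")) {
    got <- max(bundle[[nm]]$time_s) + 1 / manifest$lfp_rate
    if (abs(got - dur) > 1) {
      abort(sprintf("duration mismatch in %s.csv: %.1f s vs %.1f s declared",
                    nm, got, dur))
    }
  }
  got <- max(bundle$movie$frame_times_s) + 1 / manifest$cbv_rate
  if (abs(got - dur) > 1) {
    abort(sprintf("duration mismatch in movie.nii.gz: %.1f s vs %.1f s",
                  got, dur))
  }
  class(bundle) <- "recording_bundle"
  bundle
}
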