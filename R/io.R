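#' Load a stimulus set
#'
#' Accepts a directory of PNG images, a CSV file (one row per stimulus,
#' flattened square image, values in `[0, 1]`, column-major: row index
#' fastest), or an `.rds` file holding a `side x side x n` array. RGB images
#' are converted to grayscale by channel averaging with a warning. All
#' stimuli are validated to be square, equally sized and within `[0, 1]`.
#'
#' @param path Directory or file path.
#' @return Array `side x side x n`.
#' @export
load_stimulus_set <- function(path) {
  if (!file.exists(path)) stop("stimulus path not found: ", path, call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG files in ", path, call. = FALSE)
    imgs <- lapply(files, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) {
        warning("RGB(A) image converted to grayscale: ", basename(f),
                call. = FALSE)
        img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
      }
      img
    })
    sides <- vapply(imgs, function(m) dim(m)[1], integer(1))
    if (length(unique(sides)) != 1L ||
        any(vapply(imgs, function(m) dim(m)[2], integer(1)) != sides[1])) {
      stop(sprintf("stimuli must be square and equally sized (expected %dx%d)",
                   sides[1], sides[1]), call. = FALSE)
    }
    out <- array(unlist(imgs), c(sides[1], sides[1], length(imgs)))
  } else if (grepl("\\.rds$", path)) {
    out <- readRDS(path)
    if (length(dim(out)) == 2L) dim(out) <- c(dim(out), 1L)
    if (length(dim(out)) != 3L || dim(out)[1] != dim(out)[2]) {
      stop("stimulus array must be side x side x n", call. = FALSE)
    }
  } else {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    side <- sqrt(ncol(m))
    if (side != round(side)) {
      stop(sprintf("CSV rows of length %d are not flattened square images",
                   ncol(m)), call. = FALSE)
    }
    out <- array(t(m), c(as.integer(side), as.integer(side), nrow(m)))
  }
  if (min(out) < 0 || max(out) > 1) {
    rng <- range(out)
    out <- (out - rng[1]) / (rng[2] - rng[1])
    warning("stimulus values rescaled to [0, 1]", call. = FALSE)
  }
  out
}

#' Save a stimulus set
#'
#' Writes the stack either as an `.rds` array (bitwise round trip) or as a
#' flattened CSV (one row per stimulus, column-major).
#'
#' @param stimuli Array `side x side x n`.
#' @param path Output `.rds` or `.csv` path.
#' @return `path`, invisibly.
#' @export
save_stimulus_set <- function(stimuli, path) {
  if (grepl("\\.rds$", path)) {
    saveRDS(stimuli, path)
  } else {
    n <- dim(stimuli)[3]
    m <- t(matrix(stimuli, ncol = n))
    utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Load a voxel response matrix
#'
#' CSV with one row per stimulus and one column per voxel (header = voxel
#' ids). A leading `repeat` column marks repeated validation presentations;
#' it is folded into a `repeats x n x n_voxels` array. `.rds` files holding a
#' matrix or 3-D array are also accepted.
#'
#' @param path CSV or `.rds` path.
#' @param n_stimuli Optional expected stimulus count; mismatch is an error.
#' @return Matrix `n x n_voxels` (with voxel-id column names) or a 3-D array
#'   for repeated presentations.
#' @export
load_response_matrix <- function(path, n_stimuli = NULL) {
  if (!file.exists(path)) stop("response file not found: ", path, call. = FALSE)
  if (grepl("\\.rds$", path)) {
    out <- readRDS(path)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    if (names(df)[1] == "repeat") {
      reps <- df[[1]]
      m <- as.matrix(df[-1])
      n_rep <- length(unique(reps))
      n <- nrow(m) / n_rep
      if (n != round(n)) stop("ragged repeat blocks in ", path, call. = FALSE)
      out <- array(0, c(n_rep, n, ncol(m)),
                   dimnames = list(NULL, NULL, colnames(m)))
      for (r in seq_len(n_rep)) out[r, , ] <- m[reps == unique(reps)[r], ]
    } else {
      out <- as.matrix(df)
    }
  }
  n_found <- if (length(dim(out)) == 3L) dim(out)[2] else nrow(out)
  if (!is.null(n_stimuli) && n_found != n_stimuli) {
    stop(sprintf("response matrix has %d stimuli but %d were expected",
                 n_found, n_stimuli), call. = FALSE)
  }
  out
}

#' Save a voxel response matrix
#'
#' Inverse of [load_response_matrix()]: matrices are written as CSV with
#' voxel-id headers, 3-D repeat arrays with a leading `repeat` column.
#'
#' @param responses Matrix `n x n_voxels` or array `repeats x n x n_voxels`.
#' @param path Output CSV path.
#' @param voxel_ids Optional column headers (default `v1..vK`).
#' @return `path`, invisibly.
#' @export
save_response_matrix <- function(responses, path, voxel_ids = NULL) {
  if (length(dim(responses)) == 3L) {
    n_rep <- dim(responses)[1]
    n_vox <- dim(responses)[3]
    if (is.null(voxel_ids)) voxel_ids <- paste0("v", seq_len(n_vox))
    blocks <- lapply(seq_len(n_rep), function(r) {
      m <- matrix(responses[r, , ], dim(responses)[2], n_vox)
      cbind(data.frame(`repeat` = r, check.names = FALSE),
            stats::setNames(as.data.frame(m), voxel_ids))
    })
    df <- do.call(rbind, blocks)
  } else {
    if (is.null(voxel_ids)) voxel_ids <- paste0("v", seq_len(ncol(responses)))
    df <- stats::setNames(as.data.frame(responses), voxel_ids)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file mirroring the model, training, evaluation and
#' interpretation settings and fills in package defaults for anything
#' omitted. The file may contain top-level keys `seed`, `output_dir`,
#' `paths` (dataset file locations), `model`, `training`, `evaluation`
#' (`alpha`, `n_perm`) and `interpretation` (`top_n`, `mask_fraction`, `k`).
#'
#' @param path YAML file path.
#' @return A `run_config` list with `model` ([model_config()]), `training`
#'   ([training_config()]), `evaluation`, `interpretation`, `paths`,
#'   `output_dir` and `seed`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 1L
  model <- do.call(model_config, raw$model %||% list())
  training_args <- raw$training %||% list()
  if (is.null(training_args$seed)) training_args$seed <- seed
  training <- do.call(training_config, training_args)
  evaluation <- utils::modifyList(list(alpha = 0.001, n_perm = 1000L),
                                  raw$evaluation %||% list())
  interpretation <- utils::modifyList(list(top_n = 100L, mask_fraction = 0.1,
                                           k = 8L),
                                      raw$interpretation %||% list())
  structure(list(model = model, training = training, evaluation = evaluation,
                 interpretation = interpretation,
                 paths = raw$paths %||% list(),
                 output_dir = raw$output_dir %||% ".",
                 seed = as.integer(seed)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a reproducibility manifest
#'
#' Records the seed, package version, timestamp and a digest of the settings
#' used to produce an artifact directory, sufficient to re-run the producing
#' command.
#'
#' @param dir Artifact directory.
#' @param command Producing command name.
#' @param settings List of settings to embed.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, settings) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(command = command,
                            settings = settings,
                            package_version =
                              as.character(utils::packageVersion("gaborenc")),
                            r_version = R.version.string,
                            timestamp = format(Sys.time(), tz = "UTC")),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
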