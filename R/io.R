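# File formats: NIfTI-1 volumes (RNifti), CSV manifests and grade tables,
# YAML run configuration with a frozen schema version, and JSON metric /
# history reports. Synthetic volumes carry an identity affine; affines of
# volumes read from disk are passed through untouched.

#' Read a NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file (3D, or 4D for K-channel
#'   attention exports).
#' @return list with `grid` (plain numeric array) and `affine` (4 x 4
#'   matrix).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("volume file not found: %s", path), call. = FALSE)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop(sprintf("cannot read NIfTI file %s: %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  list(grid = array(as.vector(img), dim = dim(img)), affine = aff)
}

#' Write a NIfTI volume
#'
#' @param grid 3D (or 4D) numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine 4 x 4 affine; default identity.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, affine = diag(4)) {
  img <- RNifti::asNifti(grid)
  RNifti::sform(img) <- structure(affine, code = 2L)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Hash of a configuration object
#'
#' Deterministic 32-bit FNV-1a hash of the YAML rendering, embedded in every
#' artifact a run produces.
#'
#' @param cfg any YAML-serializable object.
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) fnv1a(yaml::as.yaml(cfg))

#' Write a synthetic cohort to disk
#'
#' Writes one NIfTI per subject, the parcellation and ground-truth effect
#' map, a cohort manifest CSV (`subject_id`, `label`, `cohort`, `path`) and a
#' grades CSV (`subject_id`, `region_id`, `stain`, `grade`).
#'
#' @param cohort a `dg_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dg_cohort"))
  dir.create(file.path(dir, "volumes"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$samples, function(s) {
    p <- file.path("volumes", paste0(s$subject_id, ".nii.gz"))
    write_volume(s$volume, file.path(dir, p))
    data.frame(subject_id = s$subject_id, label = s$label, cohort = s$cohort,
               path = p, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$grade_records, file.path(dir, "grades.csv"),
                   row.names = FALSE)
  write_volume(cohort$parcellation$labels, file.path(dir, "parcellation.nii.gz"))
  write_volume(cohort$effect_map * 1, file.path(dir, "effect_map.nii.gz"))
  meta <- list(spec = unclass(cohort$spec),
               region_names = as.list(cohort$parcellation$region_names))
  meta$config_hash <- config_hash(meta)
  yaml::write_yaml(meta, file.path(dir, "cohort.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `dg_cohort` (without the base volume, which is a generator
#'   internal).
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop(sprintf("no cohort manifest at %s", man_path), call. = FALSE)
  manifest <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  grades <- utils::read.csv(file.path(dir, "grades.csv"), stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "cohort.yaml"))
  labels_grid <- read_volume(file.path(dir, "parcellation.nii.gz"))$grid
  storage.mode(labels_grid) <- "integer"
  parc <- structure(list(labels = labels_grid,
                         region_names = unlist(meta$region_names),
                         shape = dim(labels_grid)),
                    class = "dg_parcellation")
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    vol <- read_volume(file.path(dir, manifest$path[i]))$grid
    structure(list(volume = vol, label = manifest$label[i],
                   subject_id = manifest$subject_id[i],
                   grades = NULL, cohort = manifest$cohort[i]),
              class = "dg_sample")
  })
  effect <- read_volume(file.path(dir, "effect_map.nii.gz"))$grid > 0.5
  spec <- meta$spec
  spec$n_per_class <- as.integer(unlist(spec$n_per_class))
  spec$shape <- as.integer(unlist(spec$shape))
  spec$disease_regions <- as.integer(unlist(spec$disease_regions))
  class(spec) <- "dg_cohort_spec"
  structure(list(samples = samples, effect_map = effect, base_volume = NULL,
                 grade_records = grades, parcellation = parc, spec = spec),
            class = "dg_cohort")
}

#' Write class priors to disk
#'
#' One NIfTI per class plus a JSON sidecar with provenance (class id, number
#' of samples averaged, scale, config hash).
#'
#' @param priors list of `dg_prior`s.
#' @param dir output directory.
#' @param cfg configuration object hashed into the sidecars.
#' @return `dir`, invisibly.
#' @export
write_priors <- function(priors, dir, cfg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pr in priors) {
    stem <- file.path(dir, sprintf("prior_class%d", pr$class_id))
    side <- list(class_id = pr$class_id,
                 n_samples_averaged = pr$n_samples_averaged,
                 scale = pr$scale, absent = isTRUE(pr$absent),
                 config_hash = if (!is.null(cfg)) config_hash(cfg) else NA)
    jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE)
    if (!isTRUE(pr$absent)) write_volume(pr$grid, paste0(stem, ".nii.gz"))
  }
  invisible(dir)
}

#' Read class priors written by [write_priors()]
#'
#' @param dir priors directory.
#' @return list of `dg_prior`s, ordered by class id.
#' @export
read_priors <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "^prior_class[0-9]+\\.json$",
                              full.names = TRUE))
  if (length(sidecars) == 0L) stop(sprintf("no priors found in %s", dir), call. = FALSE)
  lapply(sidecars, function(sc) {
    side <- jsonlite::read_json(sc)
    grid <- NULL
    if (!isTRUE(side$absent)) {
      grid <- read_volume(sub("\\.json$", ".nii.gz", sc))$grid
    }
    structure(list(class_id = side$class_id, grid = grid,
                   n_samples_averaged = side$n_samples_averaged,
                   scale = side$scale, absent = isTRUE(side$absent)),
              class = "dg_prior")
  })
}

#' Read and validate a run configuration
#'
#' YAML with a frozen `schema_version` (currently 1) and sections `seed`,
#' `paths.workdir`, `cohort`, `model`, `train`, `attribution`, `split`.
#' Missing or unknown keys raise an error naming the offending key.
#'
#' @param path path to a YAML config.
#' @return named list with class `dg_run_config` (and the config hash in
#'   `$config_hash`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop(sprintf("cannot parse config %s: %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  if (is.null(cfg$schema_version) || cfg$schema_version != 1) {
    stop("config key 'schema_version' missing or not 1", call. = FALSE)
  }
  required <- c("seed", "paths", "cohort", "model", "train", "attribution", "split")
  known <- c("schema_version", required)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key '%s'", unknown[1]), call. = FALSE)
  }
  for (key in required) {
    if (is.null(cfg[[key]])) stop(sprintf("config key '%s' is missing", key), call. = FALSE)
  }
  if (is.null(cfg$paths$workdir)) stop("config key 'paths.workdir' is missing", call. = FALSE)
  cfg$config_hash <- config_hash(cfg[known[known %in% names(cfg)]])
  class(cfg) <- "dg_run_config"
  cfg
}

#' Default run configuration
#'
#' Desk-scale defaults used by the examples and the end-to-end smoke tests.
#'
#' @param workdir working directory for run artifacts.
#' @param seed master seed.
#' @return a `dg_run_config` list.
#' @export
default_run_config <- function(workdir = tempfile("dgattn_run_"), seed = 1L) {
  cfg <- list(
    schema_version = 1,
    seed = as.integer(seed),
    paths = list(workdir = workdir),
    cohort = list(n_per_class = c(20L, 15L, 10L), shape = c(16L, 16L, 16L),
                  n_regions = 8L, disease_regions = c(1L, 2L),
                  effect_size = 0.25, noise_sd = 0.02),
    model = list(encoder_channels = 6L, downsample_factor = 2L),
    train = list(lambda = 5e-4, epochs = 20L, micro_batch = 4L,
                 accumulation_steps = 1L, lr = 0.01, prior_scale = "unit"),
    attribution = list(n_background = 4L, n_draws = 6L),
    split = list(k = 5L, fold = 1L))
  cfg$config_hash <- config_hash(cfg)
  class(cfg) <- "dg_run_config"
  cfg
}
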