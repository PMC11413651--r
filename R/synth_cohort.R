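#' Scanner effect parameters
#'
#' A simple acquisition model standing in for real scanner differences: a
#' multiplicative gain, an additive offset, a Gaussian blur width and an
#' additive noise scale.  The effect applied to a volume at confound
#' strength `s` is
#' `smooth(v, s * smooth_sigma) * (1 + s * (gain - 1)) + s * offset + e`,
#' with `e ~ N(0, (s * noise_sd)^2)`; `s = 0` is an exact identity.
#'
#' @param gain multiplicative intensity factor (`> 0`).
#' @param offset additive intensity shift.
#' @param smooth_sigma Gaussian blur width in voxels (`>= 0`).
#' @param noise_sd additive noise standard deviation (`>= 0`).
#' @return An object of class `scanner_params`.
#' @export
scanner_params <- function(gain = 1, offset = 0, smooth_sigma = 0, noise_sd = 0) {
  vals <- c(gain, offset, smooth_sigma, noise_sd)
  if (any(!is.finite(vals))) stop("scanner parameters must be finite")
  if (gain <= 0) stop("gain must be positive")
  if (smooth_sigma < 0) stop("smooth_sigma must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(gain = gain, offset = offset,
                 smooth_sigma = smooth_sigma, noise_sd = noise_sd),
            class = "scanner_params")
}

#' Synthetic multi-center cohort specification
#'
#' Describes a cohort whose statistical structure mirrors a large
#' multi-center neuroimaging database: tens of centers with highly variable
#' shard sizes (including centers with fewer than five samples), a shared
#' pool of scanner types, centers operating one or several scanners, and
#' per-center disease prevalences that may be 0 or 1 (single-class centers).
#'
#' @param n_centers number of centers.
#' @param scanner_pool list of `M >= 2` [scanner_params()].
#' @param center_sizes integer vector (length `n_centers`) of shard sizes.
#' @param center_scanner_map list (length `n_centers`) of integer vectors of
#'   scanner ids in `1..M`; every center maps to at least one scanner.
#' @param prevalence_per_center disease prevalence per center in `[0, 1]`.
#' @param volume_shape integer(3) spatial shape (desk scale 24x24x24 by
#'   default; the full-scale 160x192x160 is supported for shape checks).
#' @param disease_mask logical array of `volume_shape` marking the region
#'   carrying disease signal; defaults to a central sphere.
#' @param disease_delta intensity shift added inside the mask for diseased
#'   samples.
#' @param confound_strength nonnegative scalar scaling all scanner effects.
#' @param noise_sd acquisition-independent additive noise level.
#' @param seed integer; the same spec and seed give a bit-identical cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_centers, scanner_pool, center_sizes,
                        center_scanner_map, prevalence_per_center,
                        volume_shape = c(24L, 24L, 24L),
                        disease_mask = NULL,
                        disease_delta = 0.5,
                        confound_strength = 1,
                        noise_sd = 0.05,
                        seed = 1L) {
  n_centers <- as.integer(n_centers)
  M <- length(scanner_pool)
  if (M < 2) stop("scanner pool must contain at least 2 scanner types")
  for (p in scanner_pool) stopifnot(inherits(p, "scanner_params"))
  if (length(center_sizes) != n_centers ||
      length(center_scanner_map) != n_centers ||
      length(prevalence_per_center) != n_centers)
    stop("center_sizes, center_scanner_map and prevalence_per_center must all have length n_centers")
  if (any(center_sizes < 1)) stop("center sizes must be positive")
  for (m in center_scanner_map) {
    if (length(m) < 1) stop("every center must map to at least one scanner")
    if (any(!m %in% seq_len(M))) stop("scanner id outside the pool")
  }
  if (any(prevalence_per_center < 0 | prevalence_per_center > 1))
    stop("prevalences must lie in [0, 1]")
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3 || any(volume_shape < 1))
    stop("volume_shape must be 3 positive integers")
  if (is.null(disease_mask)) disease_mask <- default_disease_mask(volume_shape)
  if (!identical(dim(disease_mask), volume_shape))
    stop("disease_mask shape must equal volume_shape")
  if (confound_strength < 0) stop("confound_strength must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(n_centers = n_centers, scanner_pool = scanner_pool,
                 center_sizes = as.integer(center_sizes),
                 center_scanner_map = lapply(center_scanner_map, as.integer),
                 prevalence_per_center = prevalence_per_center,
                 volume_shape = volume_shape,
                 disease_mask = disease_mask,
                 disease_delta = disease_delta,
                 confound_strength = confound_strength,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default disease mask: a central sphere
#'
#' @param shape integer(3).
#' @param radius sphere radius in voxels; defaults to a sixth of the
#'   smallest extent (at least 2).
#' @return Logical array of dimension `shape`.
#' @export
default_disease_mask <- function(shape, radius = NULL) {
  shape <- as.integer(shape)
  if (is.null(radius)) radius <- max(2, round(min(shape) / 6))
  ctr <- (shape + 1) / 2
  dx2 <- (seq_len(shape[1]) - ctr[1])^2
  dy2 <- (seq_len(shape[2]) - ctr[2])^2
  dz2 <- (seq_len(shape[3]) - ctr[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  array(r2 <= radius^2, dim = shape)
}

# Smooth anatomical phantom: a superposition of separable Gaussian blobs
# drawn deterministically from `seed`, scaled into [0, ~2].  This is a fully
# synthetic stand-in for brain anatomy; it has the right smoothness and
# contrast structure for exercising the pipeline, not MRI physics.
phantom_template <- function(shape, seed, n_blobs = 6L) {
  shape <- as.integer(shape)
  with_seed(derive_seed(seed, "phantom"), {
    vol <- array(0, dim = shape)
    ax <- seq_len(shape[1]); ay <- seq_len(shape[2]); az <- seq_len(shape[3])
    for (k in seq_len(n_blobs)) {
      ctr <- c(runif(1, 0.25, 0.75) * shape[1],
               runif(1, 0.25, 0.75) * shape[2],
               runif(1, 0.25, 0.75) * shape[3])
      sds <- runif(3, 0.10, 0.30) * shape
      amp <- runif(1, 0.4, 1)
      gx <- exp(-(ax - ctr[1])^2 / (2 * sds[1]^2))
      gy <- exp(-(ay - ctr[2])^2 / (2 * sds[2]^2))
      gz <- exp(-(az - ctr[3])^2 / (2 * sds[3]^2))
      vol <- vol + amp * outer(outer(gx, gy), gz)
    }
    vol <- 0.2 + 1.3 * vol / max(vol)
    vol
  })
}

# Separable Gaussian blur via banded matrix products along each axis; kernel
# truncated at 3 sigma and renormalized row-wise at the edges.
blur3d <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  d <- dim(vol)
  smooth_mat <- function(n) {
    r <- max(1L, ceiling(3 * sigma))
    k <- dnorm(-r:r, sd = sigma)
    B <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      B[i, j[ok]] <- k[ok]
      B[i, ] <- B[i, ] / sum(B[i, ])
    }
    B
  }
  v <- matrix(vol, nrow = d[1])
  v <- smooth_mat(d[1]) %*% v
  vol <- array(v, d)
  vol <- aperm(vol, c(2, 1, 3))
  v <- smooth_mat(d[2]) %*% matrix(vol, nrow = d[2])
  vol <- aperm(array(v, d[c(2, 1, 3)]), c(2, 1, 3))
  vol <- aperm(vol, c(3, 2, 1))
  v <- smooth_mat(d[3]) %*% matrix(vol, nrow = d[3])
  aperm(array(v, d[c(3, 2, 1)]), c(3, 2, 1))
}

#' Apply a scanner effect to a volume
#'
#' `smooth(v, s*smooth_sigma) * (1 + s*(gain-1)) + s*offset + N(0, (s*noise_sd)^2)`
#' where `s` is the confound strength.  `strength = 0` returns the input
#' exactly.  Noise draws use the current RNG stream, so wrap calls in a
#' seeded context for reproducibility.
#'
#' @param volume finite 3D array.
#' @param params a [scanner_params()].
#' @param strength nonnegative confound strength.
#' @return A 3D array of the same shape.
#' @export
inject_scanner_effect <- function(volume, params, strength = 1) {
  stopifnot(inherits(params, "scanner_params"))
  if (any(!is.finite(volume))) stop("volume must be finite")
  if (!is.finite(strength) || strength < 0) stop("strength must be finite and nonnegative")
  if (strength == 0) return(volume)
  v <- blur3d(volume, strength * params$smooth_sigma)
  v <- v * (1 + strength * (params$gain - 1)) + strength * params$offset
  nsd <- strength * params$noise_sd
  if (nsd > 0) v <- v + array(rnorm(length(v), sd = nsd), dim = dim(v))
  v
}

#' Apply a disease effect to a volume
#'
#' Shifts intensities inside the mask by `delta`; voxels outside the mask
#' are untouched.
#'
#' @param volume 3D array.
#' @param mask logical array with the same shape.
#' @param delta intensity shift.
#' @return A 3D array of the same shape.
#' @export
inject_disease_effect <- function(volume, mask, delta) {
  if (!identical(dim(volume), dim(mask))) stop("mask shape must match volume shape")
  volume + delta * (mask != 0)
}

#' Generate a synthetic multi-center cohort
#'
#' For every center, disease labels are drawn at the center's prevalence and
#' each sample's scanner is drawn uniformly from the center's scanner map.
#' Each volume is the shared anatomy phantom, plus the disease effect when
#' the label is 1, then the scanner effect (acquisition acting on anatomy),
#' then additive noise.  The whole generation runs under `spec$seed`: the
#' same spec yields a bit-identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @return A list of center shards; each shard is a `center_shard` with
#'   `center_id`, `volumes`, `disease_labels`, `scanner_labels`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  template <- phantom_template(spec$volume_shape, spec$seed)
  M <- length(spec$scanner_pool)
  with_seed(derive_seed(spec$seed, "cohort"), {
    shards <- vector("list", spec$n_centers)
    for (c in seq_len(spec$n_centers)) {
      n <- spec$center_sizes[c]
      prev <- spec$prevalence_per_center[c]
      labels <- rbinom(n, 1, prev)
      smap <- spec$center_scanner_map[[c]]
      scanners <- if (length(smap) == 1) rep(smap, n) else sample(smap, n, replace = TRUE)
      vols <- vector("list", n)
      for (i in seq_len(n)) {
        v <- template
        if (labels[i] == 1)
          v <- inject_disease_effect(v, spec$disease_mask, spec$disease_delta)
        v <- inject_scanner_effect(v, spec$scanner_pool[[scanners[i]]],
                                   spec$confound_strength)
        if (spec$noise_sd > 0)
          v <- v + array(rnorm(length(v), sd = spec$noise_sd), dim = dim(v))
        vols[[i]] <- v
      }
      shards[[c]] <- structure(list(center_id = sprintf("center_%02d", c),
                                    volumes = vols,
                                    disease_labels = labels,
                                    scanner_labels = scanners),
                               class = "center_shard")
    }
    shards
  })
}

#' Mask-mean threshold oracle
#'
#' Direct, model-free readout of disease separability: classify each volume
#' by thresholding its mean intensity inside the disease mask at the
#' midpoint of the two class means.  Used as the calibration oracle for the
#' generator's disease signal.
#'
#' @param volumes list of 3D arrays.
#' @param labels binary vector.
#' @param mask logical array.
#' @return Classification accuracy of the threshold rule.
#' @export
mask_mean_oracle <- function(volumes, labels, mask) {
  m <- vapply(volumes, function(v) mean(v[mask != 0]), numeric(1))
  if (length(unique(labels)) < 2) stop("both classes required")
  thr <- (mean(m[labels == 1]) + mean(m[labels == 0])) / 2
  mean(as.integer(m > thr) == labels)
}

# ---- manifest I/O -----------------------------------------------------------

MANIFEST_COLS <- c("sample_id", "center_id", "scanner_id", "disease_label",
                   "volume_path")

#' Cohort metadata as a manifest table
#'
#' @param shards list of center shards.
#' @param volume_paths optional character vector of per-sample volume paths
#'   (e.g. NIfTI files), in shard order.
#' @return A data frame with columns `sample_id`, `center_id`, `scanner_id`,
#'   `disease_label`, `volume_path`.
#' @export
manifest_from_shards <- function(shards, volume_paths = NULL) {
  rows <- lapply(shards, function(s) {
    n <- length(s$volumes)
    data.frame(sample_id = sprintf("%s_s%03d", s$center_id, seq_len(n)),
               center_id = rep(s$center_id, n),
               scanner_id = s$scanner_labels,
               disease_label = s$disease_labels,
               volume_path = rep(NA_character_, n),
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows) == 0) {
    data.frame(sample_id = character(), center_id = character(),
               scanner_id = integer(), disease_label = integer(),
               volume_path = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  if (!is.null(volume_paths)) {
    if (length(volume_paths) != nrow(df)) stop("one volume path per sample required")
    df$volume_path <- volume_paths
  }
  df
}

#' Write / read a cohort manifest CSV
#'
#' The manifest carries per-sample metadata (`sample_id`, `center_id`,
#' `scanner_id`, `disease_label`, `volume_path`); reading then writing is an
#' identity on the metadata.
#'
#' @param shards list of center shards.
#' @param path CSV file path.
#' @param volume_paths optional per-sample volume paths.
#' @export
write_manifest <- function(shards, path, volume_paths = NULL) {
  write.csv(manifest_from_shards(shards, volume_paths), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param scanner_space optional size `M` of the scanner label space; rows
#'   with scanner ids outside `1..M` are rejected.
#' @return `read_manifest` returns the manifest data frame.
#' @export
read_manifest <- function(path, scanner_space = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(volume_path = "character"))
  missing <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing) > 0)
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  if (!is.null(scanner_space)) {
    if (any(!df$scanner_id %in% seq_len(scanner_space)))
      stop("manifest contains scanner ids outside the label space")
  }
  df[MANIFEST_COLS]
}

# ---- YAML spec and NIfTI I/O ------------------------------------------------

#' Write / read a cohort spec as YAML
#'
#' Scalar fields, the scanner pool, sizes, scanner map and prevalences are
#' serialized; the disease mask is reconstructed as the default central
#' sphere for the stored shape (custom masks are an in-memory feature).
#'
#' @param spec a [cohort_spec()].
#' @param path YAML file path.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  x <- list(n_centers = spec$n_centers,
            scanner_pool = lapply(spec$scanner_pool, unclass),
            center_sizes = spec$center_sizes,
            center_scanner_map = spec$center_scanner_map,
            prevalence_per_center = spec$prevalence_per_center,
            volume_shape = spec$volume_shape,
            disease_delta = spec$disease_delta,
            confound_strength = spec$confound_strength,
            noise_sd = spec$noise_sd,
            seed = spec$seed)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @return `read_cohort_spec` returns a [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  cohort_spec(n_centers = x$n_centers,
              scanner_pool = lapply(x$scanner_pool, function(p)
                scanner_params(p$gain, p$offset, p$smooth_sigma, p$noise_sd)),
              center_sizes = unlist(x$center_sizes),
              center_scanner_map = x$center_scanner_map,
              prevalence_per_center = unlist(x$prevalence_per_center),
              volume_shape = unlist(x$volume_shape),
              disease_delta = x$disease_delta,
              confound_strength = x$confound_strength,
              noise_sd = x$noise_sd,
              seed = x$seed)
}

#' Export / import cohort volumes as NIfTI
#'
#' Volumes are written as single-precision `.nii.gz` files named after their
#' sample ids; requires the RNifti package.
#'
#' @param shards list of center shards.
#' @param dir output directory (created if needed).
#' @return `write_cohort_nifti` returns the manifest data frame (with
#'   `volume_path` filled) invisibly.
#' @export
write_cohort_nifti <- function(shards, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI export")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- manifest_from_shards(shards)
  paths <- file.path(dir, paste0(df$sample_id, ".nii.gz"))
  i <- 0L
  for (s in shards) {
    for (v in s$volumes) {
      i <- i + 1L
      RNifti::writeNifti(v, paths[i], datatype = "float")
    }
  }
  df$volume_path <- paths
  write.csv(df, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(df)
}

#' @rdname write_cohort_nifti
#' @param manifest_path path to a manifest CSV whose `volume_path` column
#'   points at NIfTI files.
#' @return `read_cohort_nifti` returns a list of center shards.
#' @export
read_cohort_nifti <- function(manifest_path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI import")
  df <- read_manifest(manifest_path)
  if (any(is.na(df$volume_path))) stop("manifest has missing volume paths")
  shards <- lapply(split(df, df$center_id), function(g) {
    structure(list(center_id = g$center_id[1],
                   volumes = lapply(g$volume_path, function(p) {
                     v <- RNifti::readNifti(p)
                     array(as.numeric(v), dim = dim(v))
                   }),
                   disease_labels = g$disease_label,
                   scanner_labels = g$scanner_id),
              class = "center_shard")
  })
  unname(shards[order(names(shards))])
}
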