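#' Configuration for a synthetic gray-matter-density cohort
#'
#' Describes a two-class (AD / CN) cohort of smooth, anatomy-like 3D density
#' maps with localized class-dependent intensity reduction ("atrophy") at
#' configurable sites. The background is a fixed smooth pseudo-anatomy — a
#' superposition of a few low-frequency Gaussian bumps under a soft
#' envelope — identical across subjects up to a small per-subject random
#' sub-voxel translation, which emulates the residual misalignment left by
#' spatial normalization. Atrophy multiplies intensities by `1 - delta`
#' inside a hard sphere with a 2-voxel soft edge; independent Gaussian noise
#' is added afterwards and intensities are clipped to
#' `[0, 1 + 5 * noise_sd]`.
#'
#' @param n_subjects total cohort size (>= 2).
#' @param class_fraction_ad fraction of subjects labelled AD, in (0, 1).
#'   Default 0.45, matching the class imbalance typical of case-control
#'   neuroimaging cohorts.
#' @param volume_shape grid extents in voxels (default 121 x 145 x 121, the
#'   size of spatially normalized maps before background cropping).
#' @param voxel_size_mm isotropic voxel size (default 1.5).
#' @param atrophy_sites list of sites, each `list(center = 0-based voxel
#'   triple, radius = voxels, delta = fractional intensity reduction in
#'   [0, 1])`. Every site's sphere must intersect the volume. Defaults to a
#'   mirrored pair of medial-temporal-like sites from
#'   [default_atrophy_sites()].
#' @param heterogeneity_fraction fraction of AD subjects whose *first*
#'   listed site is spared (disease heterogeneity: the primary site is well
#'   preserved in a subset of patients). Default 0.
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units; the noise-free template has maximum 1).
#' @param background_smoothness_mm length scale of the background bumps.
#' @param jitter_voxels per-subject uniform translation amplitude, at most
#'   one voxel.
#' @param seed integer seed; generation is fully deterministic given the
#'   configuration.
#' @return A `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_subjects = 40L, class_fraction_ad = 0.45,
                          volume_shape = c(121L, 145L, 121L),
                          voxel_size_mm = 1.5,
                          atrophy_sites = default_atrophy_sites(volume_shape),
                          heterogeneity_fraction = 0,
                          noise_sd = 0.05,
                          background_smoothness_mm = 12,
                          jitter_voxels = 0.5,
                          seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  volume_shape <- check_len3(volume_shape, "volume_shape")
  if (n_subjects < 2L) stop("`n_subjects` must be >= 2", call. = FALSE)
  if (class_fraction_ad <= 0 || class_fraction_ad >= 1) {
    stop("`class_fraction_ad` must lie in (0, 1)", call. = FALSE)
  }
  if (voxel_size_mm <= 0) stop("`voxel_size_mm` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  if (background_smoothness_mm < 0) {
    stop("`background_smoothness_mm` must be nonnegative", call. = FALSE)
  }
  if (heterogeneity_fraction < 0 || heterogeneity_fraction > 1) {
    stop("`heterogeneity_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (jitter_voxels < 0 || jitter_voxels > 1) {
    stop("`jitter_voxels` must lie in [0, 1]", call. = FALSE)
  }
  for (site in atrophy_sites) {
    ctr <- as.numeric(site$center)
    if (length(ctr) != 3L || is.null(site$radius) || is.null(site$delta)) {
      stop("each atrophy site needs center (triple), radius and delta",
           call. = FALSE)
    }
    if (site$delta < 0 || site$delta > 1) {
      stop("site `delta` must lie in [0, 1]", call. = FALSE)
    }
    if (site$radius <= 0) stop("site `radius` must be positive", call. = FALSE)
    if (any(ctr + site$radius < 0) || any(ctr - site$radius > volume_shape - 1)) {
      stop(sprintf("atrophy site at (%s) lies wholly outside the volume",
                   paste(ctr, collapse = ",")), call. = FALSE)
    }
  }
  structure(
    list(n_subjects = n_subjects, class_fraction_ad = class_fraction_ad,
         volume_shape = volume_shape, voxel_size_mm = voxel_size_mm,
         atrophy_sites = atrophy_sites,
         heterogeneity_fraction = heterogeneity_fraction,
         noise_sd = noise_sd,
         background_smoothness_mm = background_smoothness_mm,
         jitter_voxels = jitter_voxels, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Default mirrored atrophy sites for a given volume shape
#'
#' A left/right pair of medial-temporal-like sites at fixed fractional
#' coordinates (0.35/0.65, 0.42, 0.35 of each extent), radius 6.5% of the
#' smallest extent, effect size 0.3.
#'
#' @param volume_shape integer triple.
#' @param delta effect size for both sites.
#' @return List of two site lists.
#' @export
default_atrophy_sites <- function(volume_shape, delta = 0.3) {
  volume_shape <- check_len3(volume_shape, "volume_shape")
  r <- max(3, round(0.065 * min(volume_shape)))
  mk <- function(fx) list(
    center = round(c(fx, 0.42, 0.35) * (volume_shape - 1)),
    radius = r, delta = delta
  )
  list(mk(0.35), mk(0.65))
}

# fixed bump table defining the pseudo-anatomy (fractional centers,
# amplitude, width multiplier on background_smoothness_mm)
.template_bumps <- data.frame(
  fx = c(0.35, 0.65, 0.50, 0.50, 0.40, 0.60, 0.50),
  fy = c(0.45, 0.45, 0.65, 0.28, 0.60, 0.60, 0.45),
  fz = c(0.40, 0.40, 0.55, 0.60, 0.30, 0.30, 0.70),
  amp = c(0.35, 0.35, 0.30, 0.25, 0.20, 0.20, 0.18),
  w = c(1.6, 1.6, 2.2, 1.8, 1.2, 1.2, 1.5)
)

# evaluate the (unnormalized) analytic template on the grid shifted by
# `jitter` voxels; smooth by construction, so jitter is exact interpolation
template_raw <- function(shape, voxel_size_mm, smoothness_mm,
                         jitter = c(0, 0, 0)) {
  ax <- lapply(1:3, function(a) (seq_len(shape[a]) - 1 + jitter[a]))
  half <- (shape - 1) / 2
  env1 <- lapply(1:3, function(a) exp(-1.3 * ((ax[[a]] - half[a]) / half[a])^2))
  out <- 0.45 * outer(outer(env1[[1]], env1[[2]]), env1[[3]])
  w_mm <- max(smoothness_mm, 1e-6)
  for (i in seq_len(nrow(.template_bumps))) {
    b <- .template_bumps[i, ]
    ctr <- c(b$fx, b$fy, b$fz) * (shape - 1)
    s_vox <- b$w * w_mm / voxel_size_mm
    e <- lapply(1:3, function(a) exp(-(ax[[a]] - ctr[a])^2 / (2 * s_vox^2)))
    out <- out + b$amp * outer(outer(e[[1]], e[[2]]), e[[3]])
  }
  out
}

#' The class-free background template of a cohort configuration
#'
#' The noise-free, atrophy-free pseudo-anatomy all subjects share (before
#' their individual sub-voxel jitter), normalized to maximum 1.
#'
#' @param config a [cohort_config()].
#' @return A [vol3d].
#' @export
cohort_template <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  raw <- template_raw(config$volume_shape, config$voxel_size_mm,
                      config$background_smoothness_mm)
  vol3d(raw / max(raw), voxel_size_mm = config$voxel_size_mm)
}

# multiplicative atrophy: factor 1 - delta inside radius-2, ramping to 1 at
# the radius; applied only inside the site's bounding box
apply_atrophy <- function(arr, center, radius, delta, jitter = c(0, 0, 0)) {
  if (delta == 0) return(arr)
  shape <- dim(arr)
  ctr <- center + jitter
  lo <- pmax(floor(ctr - radius), 0)
  hi <- pmin(ceiling(ctr + radius), shape - 1)
  if (any(lo > hi)) return(arr)
  ix <- lapply(1:3, function(a) (lo[a]:hi[a]))
  d2 <- outer(outer((ix[[1]] - ctr[1])^2, (ix[[2]] - ctr[2])^2, "+"),
              (ix[[3]] - ctr[3])^2, "+")
  d <- sqrt(d2)
  wgt <- pmin(pmax((radius - d) / 2, 0), 1)  # 2-voxel soft edge
  sub <- arr[ix[[1]] + 1, ix[[2]] + 1, ix[[3]] + 1, drop = FALSE]
  arr[ix[[1]] + 1, ix[[2]] + 1, ix[[3]] + 1] <- sub * (1 - delta * wgt)
  arr
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` volumes from the configuration's generative model:
#' shared smooth template, per-subject sub-voxel jitter, multiplicative
#' atrophy at every site for AD subjects (except the first site in the
#' spared fraction), additive voxel-wise Gaussian noise, clipping at zero.
#' `round(class_fraction_ad * n_subjects)` subjects are labelled AD. The
#' whole procedure is deterministic given the configuration (including its
#' seed): the same config reproduces identical volumes.
#'
#' @param config a [cohort_config()].
#' @param dir if non-`NULL`, volumes are written there as NIfTI-1
#'   (`<subject_id>.nii.gz`, voxel size in the header) and `volume_path`
#'   is filled in.
#' @param keep_volumes keep the generated volumes in memory as
#'   `attr(, "volumes")` (a named list of [vol3d]); default `TRUE` when
#'   nothing is written to disk.
#' @return A tibble of subject records: `subject_id`, `label`,
#'   `volume_path`, `split` (initially `"unassigned"`).
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 4, volume_shape = c(20, 24, 20),
#'                      atrophy_sites = default_atrophy_sites(c(20, 24, 20)),
#'                      seed = 7)
#' cohort <- generate_cohort(cfg)
#' table(cohort$label)
generate_cohort <- function(config, dir = NULL,
                            keep_volumes = is.null(dir)) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(dir) && !keep_volumes) {
    stop("either write volumes (`dir`) or keep them (`keep_volumes`)",
         call. = FALSE)
  }
  n <- config$n_subjects
  n_ad <- round(config$class_fraction_ad * n)
  n_ad <- min(max(n_ad, 1L), n - 1L)  # both classes nonempty
  labels <- c(rep("AD", n_ad), rep("CN", n - n_ad))
  ids <- sprintf("sub-%03d", seq_len(n))
  raw0 <- template_raw(config$volume_shape, config$voxel_size_mm,
                       config$background_smoothness_mm)
  norm <- max(raw0)
  upper <- 1 + 5 * config$noise_sd
  vols <- if (keep_volumes) vector("list", n)
  paths <- rep(NA_character_, n)
  with_local_seed(config$seed, {
    spared <- rep(FALSE, n)
    ad_idx <- which(labels == "AD")
    n_spared <- round(config$heterogeneity_fraction * n_ad)
    if (n_spared > 0 && length(config$atrophy_sites) > 0) {
      spared[sample(ad_idx, n_spared)] <- TRUE
    }
    for (i in seq_len(n)) {
      jit <- stats::runif(3, -config$jitter_voxels, config$jitter_voxels)
      arr <- template_raw(config$volume_shape, config$voxel_size_mm,
                          config$background_smoothness_mm, jitter = jit) / norm
      if (labels[i] == "AD") {
        for (s in seq_along(config$atrophy_sites)) {
          if (s == 1L && spared[i]) next
          site <- config$atrophy_sites[[s]]
          arr <- apply_atrophy(arr, as.numeric(site$center), site$radius,
                               site$delta, jitter = jit)
        }
      }
      if (config$noise_sd > 0) {
        arr <- arr + stats::rnorm(length(arr), sd = config$noise_sd)
      }
      arr <- array(pmin(pmax(arr, 0), upper), dim(arr))
      v <- vol3d(arr, voxel_size_mm = config$voxel_size_mm)
      if (!is.null(dir)) {
        paths[i] <- file.path(dir, paste0(ids[i], ".nii.gz"))
        write_volume(v, paths[i])
      }
      if (keep_volumes) vols[[i]] <- v
    }
  })
  records <- tibble::tibble(
    subject_id = ids, label = labels, volume_path = paths,
    split = "unassigned"
  )
  if (keep_volumes) {
    names(vols) <- ids
    attr(records, "volumes") <- vols
  }
  records
}

#' Access the in-memory volumes of a generated cohort
#'
#' @param records a cohort tibble from [generate_cohort()].
#' @return Named list of [vol3d], or `NULL` if volumes were not kept.
#' @export
cohort_volumes <- function(records) attr(records, "volumes")

#' Write / read a cohort table as headered CSV
#'
#' Columns `subject_id,label,volume_path,split`. Reading validates the
#' schema and reports the offending row on malformed input; duplicate
#' subject ids are rejected. Round-trips are exact.
#'
#' @param records cohort tibble.
#' @param path CSV path.
#' @return `path` (write) or the cohort tibble (read).
#' @export
write_cohort_table <- function(records, path) {
  if (nrow(records) == 0L) stop("`records` must be non-empty", call. = FALSE)
  cols <- c("subject_id", "label", "volume_path", "split")
  if (!all(cols %in% names(records))) {
    stop("records must have columns subject_id, label, volume_path, split",
         call. = FALSE)
  }
  utils::write.csv(records[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = NULL)
  cols <- c("subject_id", "label", "volume_path", "split")
  if (!identical(names(df), cols)) {
    stop(sprintf("malformed cohort table: expected columns %s, found %s",
                 paste(cols, collapse = ","),
                 paste(names(df), collapse = ",")), call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    if (!nzchar(df$subject_id[i])) {
      stop(sprintf("malformed cohort table: empty subject_id in row %d", i),
           call. = FALSE)
    }
    if (!df$label[i] %in% c("AD", "CN")) {
      stop(sprintf("malformed cohort table: bad label '%s' in row %d",
                   df$label[i], i), call. = FALSE)
    }
    if (!df$split[i] %in% c("train", "val", "test", "unassigned")) {
      stop(sprintf("malformed cohort table: bad split '%s' in row %d",
                   df$split[i], i), call. = FALSE)
    }
  }
  dup <- which(duplicated(df$subject_id))
  if (length(dup)) {
    stop(sprintf("duplicate subject_id '%s' in row %d",
                 df$subject_id[dup[1]], dup[1]), call. = FALSE)
  }
  df$volume_path[df$volume_path == ""] <- NA_character_
  tibble::as_tibble(df)
}
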