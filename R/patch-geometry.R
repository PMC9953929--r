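#' Evenly spaced patch start offsets along one axis
#'
#' Places `count` windows of length `patch_len` along an axis of length
#' `extent` with endpoint anchoring: the first window starts at 0, the last
#' at `extent - patch_len`, and intermediate starts follow
#' `round(i * (extent - patch_len) / (count - 1))` with halves rounded down.
#' Neighbouring windows overlap whenever `count * patch_len > extent`, which
#' is how a small number of patches can still cover the whole axis.
#'
#' @param extent axis length in voxels.
#' @param patch_len window length in voxels, `<= extent`.
#' @param count number of windows.
#' @param require_coverage if `TRUE` (default), error when the windows cannot
#'   jointly cover every voxel of the axis.
#' @return Integer vector of `count` 0-based start offsets.
#' @export
#' @examples
#' plan_axis_positions(91, 48, 2)   # 0, 43
#' plan_axis_positions(115, 48, 3)  # 0, 33, 67
plan_axis_positions <- function(extent, patch_len, count,
                                require_coverage = TRUE) {
  extent <- as.integer(extent); patch_len <- as.integer(patch_len)
  count <- as.integer(count)
  if (count < 1L) stop("`count` must be >= 1", call. = FALSE)
  if (patch_len < 1L) stop("`patch_len` must be >= 1", call. = FALSE)
  if (patch_len > extent) {
    stop(sprintf("patch length %d exceeds extent %d", patch_len, extent),
         call. = FALSE)
  }
  if (require_coverage && count == 1L && patch_len != extent) {
    stop(sprintf(
      "a single patch of length %d cannot cover extent %d", patch_len, extent
    ), call. = FALSE)
  }
  if (count == 1L) return(0L)
  if (require_coverage && as.numeric(patch_len) * count < extent) {
    stop(sprintf(
      "%d patches of length %d cannot cover extent %d", count, patch_len,
      extent
    ), call. = FALSE)
  }
  i <- seq_len(count) - 1L
  starts <- as.integer(round_half_down(i * (extent - patch_len) / (count - 1L)))
  if (require_coverage && max(diff(starts)) > patch_len) {
    stop("even spacing leaves an uncovered gap; increase count", call. = FALSE)
  }
  starts
}

#' Plan an overlapping patch grid over a volume
#'
#' Builds the Cartesian product of per-axis start positions from
#' [plan_axis_positions()], giving `prod(counts)` axis-aligned patches of a
#' common shape. With the counts used for 91 x 115 x 91 gray-matter maps this
#' reproduces the standard partitions: twelve 48^3 cubic patches (counts
#' 2,3,2), eight 64^3 (2,2,2), and six 91 x 25 x 91 coronal slabs (1,6,1).
#'
#' Patch counts are taken as explicit configuration rather than derived from
#' a stride: published patch totals do not always equal the product of
#' minimal per-axis covering counts, so the grid is whatever the analyst
#' asks for, and coverage is audited rather than assumed. An optional filter
#' drops patches whose fraction of nonzero voxels in a reference volume falls
#' below `min_nonzero_fraction` (default 0 = keep everything), which is one
#' way such reduced totals can arise.
#'
#' @param volume_shape integer triple, the parent volume shape.
#' @param patch_shape integer triple, the common patch shape.
#' @param counts integer triple, number of patches along each axis.
#' @param require_coverage demand that the union of patches covers the
#'   volume (default `TRUE`).
#' @param min_nonzero_fraction drop patches whose nonzero-voxel fraction in
#'   `volume` is below this threshold; needs `volume` when positive.
#' @param volume optional [vol3d] (or 3D array) used by the nonzero filter.
#' @return A `grid_plan`: list with `volume_shape`, `patch_shape`, `counts`
#'   and `specs`, a tibble of 0-based starts and shapes sorted
#'   lexicographically by start.
#' @seealso [coverage_report()], [extract_patches()], [write_grid_plan()]
#' @export
#' @examples
#' plan <- plan_grid(c(91, 115, 91), c(48, 48, 48), c(2, 3, 2))
#' nrow(plan$specs)  # 12
plan_grid <- function(volume_shape, patch_shape, counts,
                      require_coverage = TRUE, min_nonzero_fraction = 0,
                      volume = NULL) {
  volume_shape <- check_len3(volume_shape, "volume_shape")
  patch_shape <- check_len3(patch_shape, "patch_shape")
  counts <- check_len3(counts, "counts")
  pos <- vector("list", 3L)
  for (a in 1:3) {
    pos[[a]] <- tryCatch(
      plan_axis_positions(volume_shape[a], patch_shape[a], counts[a],
                          require_coverage = require_coverage),
      error = function(e) {
        stop(sprintf("axis %s: %s", axis_names[a], conditionMessage(e)),
             call. = FALSE)
      }
    )
  }
  grid <- expand.grid(start_z = pos[[3]], start_y = pos[[2]],
                      start_x = pos[[1]], KEEP.OUT.ATTRS = FALSE)
  specs <- tibble::tibble(
    start_x = as.integer(grid$start_x),
    start_y = as.integer(grid$start_y),
    start_z = as.integer(grid$start_z),
    size_x = patch_shape[1], size_y = patch_shape[2], size_z = patch_shape[3]
  )
  specs <- specs[order(specs$start_x, specs$start_y, specs$start_z), ]
  if (min_nonzero_fraction > 0) {
    if (is.null(volume)) {
      stop("`volume` is required when `min_nonzero_fraction` > 0",
           call. = FALSE)
    }
    v <- as_vol3d(volume)
    frac <- vapply(seq_len(nrow(specs)), function(i) {
      p <- extract_patches(v, specs[i, ])[[1]]
      mean(p$data != 0)
    }, numeric(1))
    specs <- specs[frac >= min_nonzero_fraction, ]
  }
  rownames(specs) <- NULL
  plan <- structure(
    list(volume_shape = volume_shape, patch_shape = patch_shape,
         counts = counts, specs = specs),
    class = "grid_plan"
  )
  if (require_coverage && min_nonzero_fraction == 0) {
    rep <- coverage_report(plan)
    if (!rep$covered) {
      stop(sprintf("grid plan leaves %d voxels uncovered", rep$n_uncovered),
           call. = FALSE)
    }
  }
  plan
}

#' @export
print.grid_plan <- function(x, ...) {
  cat(sprintf(
    "<grid_plan> %d patches of %s over %s (counts %s)\n",
    nrow(x$specs), paste(x$patch_shape, collapse = "x"),
    paste(x$volume_shape, collapse = "x"), paste(x$counts, collapse = ",")
  ))
  print(x$specs, ...)
  invisible(x)
}

#' Audit a grid plan's voxel coverage and overlap
#'
#' Counts, for every voxel of the parent volume, how many patches contain it.
#'
#' @param plan a `grid_plan`, or a tibble of patch specs together with
#'   `volume_shape`.
#' @param volume_shape required when `plan` is a bare spec tibble.
#' @return One-row tibble: `covered`, `n_uncovered`, `min_overlap`,
#'   `max_overlap`, `mean_overlap`.
#' @export
coverage_report <- function(plan, volume_shape = NULL) {
  if (inherits(plan, "grid_plan")) {
    specs <- plan$specs
    volume_shape <- plan$volume_shape
  } else {
    specs <- plan
    if (is.null(volume_shape)) stop("`volume_shape` required", call. = FALSE)
    volume_shape <- check_len3(volume_shape, "volume_shape")
  }
  counts <- array(0L, volume_shape)
  for (i in seq_len(nrow(specs))) {
    s <- as.integer(unlist(specs[i, c("start_x", "start_y", "start_z")]))
    z <- as.integer(unlist(specs[i, c("size_x", "size_y", "size_z")]))
    counts[(s[1] + 1L):(s[1] + z[1]),
           (s[2] + 1L):(s[2] + z[2]),
           (s[3] + 1L):(s[3] + z[3])] <-
      counts[(s[1] + 1L):(s[1] + z[1]),
             (s[2] + 1L):(s[2] + z[2]),
             (s[3] + 1L):(s[3] + z[3])] + 1L
  }
  n_unc <- sum(counts == 0L)
  tibble::tibble(
    covered = n_unc == 0L, n_uncovered = n_unc,
    min_overlap = min(counts), max_overlap = max(counts),
    mean_overlap = mean(counts)
  )
}

#' Region-of-interest patch specs centered on given voxels
#'
#' One patch per center, centered with the floor of half the patch taken as
#' the left half-width when the patch extent is even, then clamped so the
#' patch stays inside the volume. Used for anatomically targeted patches
#' (e.g. a pair of mirrored hippocampus-centered 64^3 boxes); no atlas is
#' bundled, centers are caller-supplied voxel coordinates.
#'
#' @param centers list of 0-based voxel triples (or a single triple).
#' @param patch_shape integer triple.
#' @param volume_shape integer triple.
#' @return Tibble of patch specs (same columns as `grid_plan$specs`).
#' @export
roi_patch_specs <- function(centers, patch_shape, volume_shape) {
  patch_shape <- check_len3(patch_shape, "patch_shape")
  volume_shape <- check_len3(volume_shape, "volume_shape")
  if (any(patch_shape > volume_shape)) {
    stop("patch shape exceeds volume shape", call. = FALSE)
  }
  if (!is.list(centers)) centers <- list(centers)
  rows <- lapply(centers, function(ctr) {
    ctr <- check_len3(ctr, "center")
    if (any(ctr < 0L) || any(ctr >= volume_shape)) {
      stop(sprintf("center (%s) lies outside the volume",
                   paste(ctr, collapse = ",")), call. = FALSE)
    }
    start <- ctr - patch_shape %/% 2L
    start <- pmin(pmax(start, 0L), volume_shape - patch_shape)
    tibble::tibble(start_x = start[1], start_y = start[2], start_z = start[3],
                   size_x = patch_shape[1], size_y = patch_shape[2],
                   size_z = patch_shape[3])
  })
  dplyr::bind_rows(rows)
}

#' Extract sub-volumes given patch specs
#'
#' @param v a [vol3d] (or 3D array).
#' @param specs a `grid_plan` or a tibble of patch specs.
#' @return List of [vol3d] patches; each records its start in
#'   `origin_offset`. The input is not modified.
#' @export
extract_patches <- function(v, specs) {
  v <- as_vol3d(v)
  if (inherits(specs, "grid_plan")) specs <- specs$specs
  d <- dim(v)
  lapply(seq_len(nrow(specs)), function(i) {
    s <- as.integer(unlist(specs[i, c("start_x", "start_y", "start_z")]))
    z <- as.integer(unlist(specs[i, c("size_x", "size_y", "size_z")]))
    if (any(s < 0L) || any(s + z > d)) {
      stop(sprintf("patch spec %d is out of bounds for a %s volume",
                   i, paste(d, collapse = "x")), call. = FALSE)
    }
    vol3d(
      v$data[(s[1] + 1L):(s[1] + z[1]),
             (s[2] + 1L):(s[2] + z[2]),
             (s[3] + 1L):(s[3] + z[3]), drop = FALSE],
      voxel_size_mm = v$voxel_size_mm,
      origin_offset = v$origin_offset + s
    )
  })
}

#' Serialize / read a grid plan as JSON
#'
#' The JSON layout is `{patch_shape, counts, volume_shape,
#' specs: [{start, shape}, ...]}` with 0-based starts.
#'
#' @param plan a `grid_plan`.
#' @param path output path.
#' @return `path` (write) or a `grid_plan` (read).
#' @export
write_grid_plan <- function(plan, path) {
  stopifnot(inherits(plan, "grid_plan"))
  specs <- lapply(seq_len(nrow(plan$specs)), function(i) {
    list(
      start = as.integer(unlist(plan$specs[i, c("start_x", "start_y", "start_z")])),
      shape = as.integer(unlist(plan$specs[i, c("size_x", "size_y", "size_z")]))
    )
  })
  jsonlite::write_json(
    list(volume_shape = plan$volume_shape, patch_shape = plan$patch_shape,
         counts = plan$counts, specs = specs),
    path, auto_unbox = FALSE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_grid_plan
#' @export
read_grid_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- tibble::tibble(
    start_x = vapply(j$specs$start, `[`, numeric(1), 1),
    start_y = vapply(j$specs$start, `[`, numeric(1), 2),
    start_z = vapply(j$specs$start, `[`, numeric(1), 3),
    size_x = vapply(j$specs$shape, `[`, numeric(1), 1),
    size_y = vapply(j$specs$shape, `[`, numeric(1), 2),
    size_z = vapply(j$specs$shape, `[`, numeric(1), 3)
  )
  specs[] <- lapply(specs, as.integer)
  structure(
    list(volume_shape = as.integer(j$volume_shape),
         patch_shape = as.integer(j$patch_shape),
         counts = as.integer(j$counts), specs = specs),
    class = "grid_plan"
  )
}

#' Monte-Carlo mean pairwise distance between points in a box
#'
#' Estimates the expected Euclidean distance between two independent points
#' drawn uniformly from the physical box `box_shape_voxels * voxel_size_mm`.
#' For a cube of side a the expectation is the Robbins constant
#' 0.661707... * a, so a 48-voxel cube at 1.5 mm gives about 47.6 mm, while
#' an equal-volume elongated 91 x 25 x 91 slab gives about 73.3 mm — the
#' geometric argument for why compact patches keep locally related anatomy
#' closer together than slab-shaped ones.
#'
#' Points are continuous-uniform over the box (not voxel centers). Degenerate
#' boxes with some zero extents are allowed (the distance reduces to the
#' lower-dimensional one, e.g. a/3 on a segment of length a); all extents
#' zero is an error.
#'
#' @param box_shape_voxels box extents in voxels (length 3, or any length
#'   >= 1).
#' @param voxel_size_mm physical voxel size, scalar or per axis.
#' @param n_samples number of independent point pairs.
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @param chunk_size pairs per vectorized block (memory/time trade-off).
#' @return One-row tibble: `mean_mm`, `se_mm`, `n`.
#' @export
#' @examples
#' mean_pairwise_distance_mc(c(48, 48, 48), 1.5, n_samples = 1e5, seed = 1)
mean_pairwise_distance_mc <- function(box_shape_voxels, voxel_size_mm = 1.5,
                                      n_samples = 1e7, seed = NULL,
                                      chunk_size = 1e6) {
  n_samples <- as.numeric(n_samples)
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  sides <- as.numeric(box_shape_voxels) * as.numeric(voxel_size_mm)
  if (any(sides < 0)) stop("box extents must be nonnegative", call. = FALSE)
  if (all(sides == 0)) stop("box has all extents zero", call. = FALSE)
  with_local_seed(seed, {
    total <- 0
    total2 <- 0
    done <- 0
    while (done < n_samples) {
      m <- min(chunk_size, n_samples - done)
      d2 <- 0
      for (s in sides) {
        if (s > 0) {
          diff <- (stats::runif(m) - stats::runif(m)) * s
          d2 <- d2 + diff * diff
        }
      }
      d <- sqrt(d2)
      total <- total + sum(d)
      total2 <- total2 + sum(d * d)
      done <- done + m
    }
    mean_d <- total / n_samples
    var_d <- max(0, total2 / n_samples - mean_d^2)
    tibble::tibble(
      mean_mm = mean_d,
      se_mm = sqrt(var_d / n_samples),
      n = n_samples
    )
  })
}
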