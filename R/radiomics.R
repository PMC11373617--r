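# PET radiomics: SUV volume container, isotropic resampling, conventional SUV
# metrics, fixed-bin-width discretization, first-order and GLCM features.

#' Construct an SUV volume
#'
#' A 3D grid of body-weight-normalized standardized uptake values with its
#' voxel spacing in mm. Axis order is x, y, z (array dims 1..3).
#'
#' @param data numeric 3D array of SUV values.
#' @param spacing numeric length-3 voxel spacing in mm per axis.
#' @return object of class `suv_volume`.
#' @export
suv_volume <- function(data, spacing) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values in mm")
  if (any(!is.finite(data))) stop("SUV values must be finite")
  structure(list(data = data, spacing = spacing, axis_order = "xyz"),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat("<suv_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Construct a VOI mask aligned to an SUV volume
#'
#' @param data logical/0-1 3D array of the same shape as its volume.
#' @param volume the `suv_volume` the mask belongs to (shape check).
#' @return object of class `voi_mask`.
#' @export
voi_mask <- function(data, volume = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  m <- array(as.logical(data), dim = dim(data))
  if (!is.null(volume) && !identical(dim(m), dim(volume$data)))
    stop("mask shape must match its volume")
  structure(list(data = m), class = "voi_mask")
}

# Separable cubic-spline interpolation of a 3D array at new axis grids.
.interp_axis <- function(arr, axis, old, new, method) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = dim(a)[1])
  out <- apply(m, 2, function(col) {
    if (length(old) == 1L) return(rep(col, length(new)))
    if (method == "cubic") {
      f <- stats::splinefun(old, col, method = "natural")
      f(new)
    } else {
      idx <- vapply(new, function(p) which.min(abs(old - p)), integer(1))
      col[idx]
    }
  })
  out <- array(out, dim = c(length(new), dim(a)[2], dim(a)[3]))
  aperm(out, order(perm))
}

#' Resample a volume and mask to isotropic spacing
#'
#' Resamples the SUV grid to `target` mm isotropic spacing using separable
#' cubic spline interpolation and the mask with nearest-neighbor
#' interpolation followed by re-binarization. The output grid spans the same
#' physical extent, anchored at the first voxel center.
#'
#' @param volume an [suv_volume()].
#' @param mask a [voi_mask()] aligned to `volume`.
#' @param target target isotropic spacing in mm (default 2).
#' @return list with resampled `volume` and `mask`.
#' @export
resample_isotropic <- function(volume, mask, target = 2) {
  stopifnot(inherits(volume, "suv_volume"), inherits(mask, "voi_mask"))
  if (!identical(dim(mask$data), dim(volume$data))) stop("mask/volume shape mismatch")
  d <- dim(volume$data); sp <- volume$spacing
  old <- lapply(1:3, function(i) (seq_len(d[i]) - 1) * sp[i])
  new <- lapply(1:3, function(i) {
    extent <- (d[i] - 1) * sp[i]
    seq(0, extent, by = target)
  })
  v <- volume$data
  m <- array(as.numeric(mask$data), dim = d)
  for (ax in 1:3) {
    v <- .interp_axis(v, ax, old[[ax]], new[[ax]], "cubic")
    m <- .interp_axis(m, ax, old[[ax]], new[[ax]], "nearest")
  }
  m <- array(m >= 0.5, dim = dim(m))
  if (!any(m)) stop("mask is empty after resampling")
  list(volume = suv_volume(v, rep(target, 3)), mask = voi_mask(m))
}

#' Conventional SUV metrics of a VOI
#'
#' Returns SUVmin, SUVmax, SUVmean over in-mask voxels; PSMA-avid tumor
#' volume `PSMA_TV` (ml) as voxel count times voxel volume; total lesion PSMA
#' `TL_PSMA = SUVmean * PSMA_TV`; and `SUVpeak`, the largest mean SUV over the
#' in-mask voxels of a 1 ml sphere (voxel-center inclusion) centered on any
#' in-mask voxel.
#'
#' @param volume an [suv_volume()].
#' @param mask a [voi_mask()].
#' @param peak_volume_ml sphere volume for SUVpeak (default 1 ml).
#' @return named numeric vector of the six metrics.
#' @export
suv_metrics <- function(volume, mask, peak_volume_ml = 1) {
  stopifnot(inherits(volume, "suv_volume"), inherits(mask, "voi_mask"))
  inmask <- which(mask$data)
  if (length(inmask) == 0L) stop("empty VOI mask")
  vals <- volume$data[inmask]
  sp <- volume$spacing
  vox_ml <- prod(sp) / 1000  # mm^3 -> ml
  tv <- length(inmask) * vox_ml
  radius <- (3 * peak_volume_ml * 1000 / (4 * pi))^(1 / 3)  # mm
  d <- dim(volume$data)
  idx <- arrayInd(inmask, d)
  # physical voxel-center coordinates of in-mask voxels
  phys <- sweep(idx - 1, 2, sp, `*`)
  # sphere neighborhood offsets in voxel units
  noff <- lapply(1:3, function(i) seq(-floor(radius / sp[i]), floor(radius / sp[i])))
  grid <- as.matrix(expand.grid(noff))
  gphys <- sweep(grid, 2, sp, `*`)
  keep <- sqrt(rowSums(gphys^2)) <= radius + 1e-9
  grid <- grid[keep, , drop = FALSE]
  # sphere average restricted to in-mask voxels, so the metric is invariant
  # to values outside the VOI
  peak <- max(vapply(seq_len(nrow(idx)), function(r) {
    nb <- sweep(grid, 2, idx[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    nb <- nb[mask$data[nb], , drop = FALSE]
    mean(volume$data[nb])
  }, numeric(1)))
  c(SUVmin = min(vals), SUVmax = max(vals), SUVmean = mean(vals),
    SUVpeak = peak, PSMA_TV = tv, TL_PSMA = mean(vals) * tv)
}

#' Fixed-bin-width discretization of in-mask SUV values
#'
#' Bins are referenced to the in-mask minimum:
#' `bin(x) = floor((x - min) / width) + 1`, so labels start at 1 and are
#' invariant to uniform SUV shifts.
#'
#' @param volume an [suv_volume()] (or numeric vector of in-mask values).
#' @param mask a [voi_mask()]; ignored when `volume` is already a vector.
#' @param bin_width bin width in SUV units (default 0.3).
#' @return integer 3D array of bin labels (`NA` outside the mask) when given
#'   a volume, otherwise an integer vector.
#' @export
discretize_fixed_bin_width <- function(volume, mask = NULL, bin_width = 0.3) {
  if (inherits(volume, "suv_volume")) {
    stopifnot(inherits(mask, "voi_mask"))
    if (!any(mask$data)) stop("empty VOI mask")
    vals <- volume$data[mask$data]
    lab <- array(NA_integer_, dim = dim(volume$data))
    lab[mask$data] <- as.integer(floor((vals - min(vals)) / bin_width)) + 1L
    return(lab)
  }
  vals <- as.numeric(volume)
  as.integer(floor((vals - min(vals)) / bin_width)) + 1L
}

# The 13 unique 3D direction offsets (distance-1 neighbors, half-space).
.glcm_directions <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # keep one of each +/- pair
  keep <- apply(offs, 1, function(o) {
    nz <- which(o != 0)[1]
    o[nz] > 0
  })
  offs[keep, , drop = FALSE]
}

#' Gray-level co-occurrence matrix features of a binned VOI
#'
#' For each of the 13 unique 3D directions at distance 1, co-occurrence
#' counts are accumulated over voxel pairs that both lie inside the mask,
#' symmetrized, and normalized to a joint probability matrix `p(i, j)`.
#' Features are computed per direction and averaged over directions
#' (IBSI "average over 3D directions" aggregation).
#'
#' @param labels integer 3D array of bin labels with `NA` outside the mask
#'   (from [discretize_fixed_bin_width()]).
#' @param distance neighbor distance in voxels (default 1).
#' @return named numeric vector: `joint_energy`, `joint_entropy`, `contrast`,
#'   `dissimilarity`, `inverse_difference_moment`, `correlation`,
#'   `joint_maximum`, `autocorrelation`, `cluster_shade`,
#'   `cluster_prominence`. `NA` with a warning for a single-voxel VOI.
#' @export
glcm_features <- function(labels, distance = 1) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  feat_names <- c("joint_energy", "joint_entropy", "contrast", "dissimilarity",
                  "inverse_difference_moment", "correlation", "joint_maximum",
                  "autocorrelation", "cluster_shade", "cluster_prominence")
  inmask <- which(!is.na(labels))
  if (length(inmask) < 2L) {
    warning("GLCM undefined for a VOI with fewer than 2 voxels")
    return(stats::setNames(rep(NA_real_, length(feat_names)), feat_names))
  }
  d <- dim(labels)
  nlev <- max(labels, na.rm = TRUE)
  dirs <- .glcm_directions() * distance
  per_dir <- matrix(NA_real_, nrow = nrow(dirs), ncol = length(feat_names))
  idx <- arrayInd(inmask, d)
  for (k in seq_len(nrow(dirs))) {
    nb <- sweep(idx, 2, dirs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    a <- labels[idx[ok, , drop = FALSE]]
    b <- labels[nb[ok, , drop = FALSE]]
    pair_ok <- !is.na(b)
    if (!any(pair_ok)) next
    a <- a[pair_ok]; b <- b[pair_ok]
    counts <- matrix(0, nlev, nlev)
    tab <- table(factor(a, levels = 1:nlev), factor(b, levels = 1:nlev))
    counts <- counts + as.matrix(tab) + t(as.matrix(tab))  # symmetrize
    p <- counts / sum(counts)
    per_dir[k, ] <- .glcm_stats(p)
  }
  ok_dirs <- stats::complete.cases(per_dir)
  if (!any(ok_dirs)) {
    warning("no valid voxel pairs for GLCM")
    return(stats::setNames(rep(NA_real_, length(feat_names)), feat_names))
  }
  stats::setNames(colMeans(per_dir[ok_dirs, , drop = FALSE]), feat_names)
}

.glcm_stats <- function(p) {
  n <- nrow(p)
  i <- matrix(1:n, n, n); j <- t(i)
  px <- rowSums(p)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p)); sd_j <- sqrt(sum((j - mu_j)^2 * p))
  corr <- if (sd_i * sd_j > 0) sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j) else 1
  nz <- p > 0
  c(joint_energy = sum(p^2),
    joint_entropy = -sum(p[nz] * log2(p[nz])),
    contrast = sum((i - j)^2 * p),
    dissimilarity = sum(abs(i - j) * p),
    inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    correlation = corr,
    joint_maximum = max(p),
    autocorrelation = sum(i * j * p),
    cluster_shade = sum((i + j - mu_i - mu_j)^3 * p),
    cluster_prominence = sum((i + j - mu_i - mu_j)^4 * p))
}

#' First-order (histogram) features of in-mask SUV values
#'
#' Moment-based and histogram features in IBSI conventions. `maximum` equals
#' SUVmax by definition. For a zero-variance VOI, skewness and kurtosis are
#' reported as 0 with a warning (rather than NaN) so feature tables stay
#' numeric; entropy and uniformity use the fixed-bin-width discretization.
#'
#' @param values numeric vector of in-mask SUV values.
#' @param voxel_volume_ml voxel volume in ml (for `total_energy`); default
#'   0.008 (2 mm isotropic).
#' @param bin_width bin width for entropy/uniformity (default 0.3 SUV).
#' @return named numeric vector of 18 features.
#' @export
first_order_features <- function(values, voxel_volume_ml = 0.008, bin_width = 0.3) {
  if (length(values) == 0L) stop("empty VOI")
  n <- length(values)
  mu <- mean(values)
  v <- mean((values - mu)^2)  # population variance
  if (v == 0) {
    warning("zero-variance VOI: skewness and kurtosis reported as 0")
    skew <- 0; kurt <- 0
  } else {
    skew <- mean((values - mu)^3) / v^1.5
    kurt <- mean((values - mu)^4) / v^2
  }
  bins <- discretize_fixed_bin_width(values, bin_width = bin_width)
  pb <- as.numeric(table(bins)) / n
  q <- stats::quantile(values, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
  rw <- values[values >= q[1] & values <= q[3]]
  c(mean = mu, variance = v, skewness = skew, kurtosis = kurt,
    median = q[2], minimum = min(values), maximum = max(values),
    range = max(values) - min(values),
    percentile10 = q[1], percentile90 = q[3],
    interquartile_range = stats::IQR(values, type = 7),
    mean_absolute_deviation = mean(abs(values - mu)),
    robust_mean_absolute_deviation = mean(abs(rw - mean(rw))),
    energy = sum(values^2), total_energy = voxel_volume_ml * sum(values^2),
    root_mean_squared = sqrt(mean(values^2)),
    entropy = -sum(pb[pb > 0] * log2(pb[pb > 0])),
    uniformity = sum(pb^2))
}

#' Radiomics feature block for one volume/mask pair
#'
#' Applies the full preprocessing chain (isotropic resampling, fixed-bin-width
#' discretization) and extracts conventional SUV metrics, first-order and
#' GLCM features with `rad::<family>::<name>` column names. A delegation hook
#' lets an external IBSI-compliant extractor supply additional columns behind
#' the same contract.
#'
#' @param volume an [suv_volume()]; @param mask a [voi_mask()].
#' @param target_spacing isotropic spacing in mm (default 2).
#' @param bin_width discretization width in SUV (default 0.3).
#' @param resample apply resampling first (default `TRUE`).
#' @param extra_extractor optional `function(volume, mask)` returning a named
#'   numeric vector of additional features (already `rad::`-prefixed).
#' @return named numeric vector of features.
#' @export
extract_radiomics <- function(volume, mask, target_spacing = 2, bin_width = 0.3,
                              resample = TRUE, extra_extractor = NULL) {
  if (resample) {
    rs <- resample_isotropic(volume, mask, target_spacing)
    volume <- rs$volume; mask <- rs$mask
  }
  suv <- suv_metrics(volume, mask)
  vals <- volume$data[mask$data]
  fo <- first_order_features(vals, voxel_volume_ml = prod(volume$spacing) / 1000,
                             bin_width = bin_width)
  gl <- glcm_features(discretize_fixed_bin_width(volume, mask, bin_width))
  out <- c(stats::setNames(suv, paste0("rad::suv::", names(suv))),
           stats::setNames(fo, paste0("rad::firstorder::", names(fo))),
           stats::setNames(gl, paste0("rad::glcm::", names(gl))))
  if (!is.null(extra_extractor)) out <- c(out, extra_extractor(volume, mask))
  out
}
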