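#' Configuration for the synthetic corpus-callosum cohort generator
#'
#' Bundles every knob of the synthetic cohort: the design (subjects per
#' group-by-gender cell), the injected localized group effect, the smooth
#' per-subject shape variability, and the covariate distributions. The
#' defaults describe a cohort with a 0.8 mm inward deformation of the
#' superior genu boundary present in female patients only, on top of
#' smooth random diffeomorphic subject-to-subject variation, mirroring the
#' kind of localized, gender-specific morphometric signal the pipeline is
#' designed to detect.
#'
#' @param n_per_cell subjects per (group x gender) cell; at least 2.
#' @param effect_amplitude_mm peak inward displacement (mm) of the patient
#'   group effect applied along the outline normal; 0 disables the effect.
#' @param effect_support arc-length interval (fractions of total outline
#'   perimeter, half-open, may wrap past 1) where the effect applies.
#'   `NULL` (default) resolves to the outer (superior) genu arc of the
#'   base shape.
#' @param effect_gender_ratio multiplier for the effect in male patients
#'   relative to female patients; 0 (default) makes the effect female-only.
#' @param warp_smoothness_mm Gaussian kernel width (mm) of the random
#'   subject-specific warps.
#' @param warp_amplitude_mm scale (mm) of the random warp bump amplitudes.
#' @param jitter_rot_sd_deg,jitter_trans_sd_mm standard deviations of the
#'   small random rigid pose jitter; set to 0 to disable.
#' @param tiv_mean_by_gender named vector `c(F = ..., M = ...)` of mean
#'   total intracranial volume (mm^3) per gender.
#' @param tiv_sd standard deviation of TIV (mm^3).
#' @param age_range age range in years (uniform).
#' @param grid_shape raster dimensions (pixels) of generated label slices.
#' @param pixel_size_mm grid spacing in mm (1 mm isotropic by default).
#' @param seed integer cohort seed; identical seed and configuration give
#'   byte-identical cohorts.
#'
#' @return an object of class `cc_synth_config`.
#' @export
synthetic_config <- function(n_per_cell = 25,
                             effect_amplitude_mm = 0.8,
                             effect_support = NULL,
                             effect_gender_ratio = 0,
                             warp_smoothness_mm = 8,
                             warp_amplitude_mm = 0.6,
                             jitter_rot_sd_deg = 1,
                             jitter_trans_sd_mm = 0.5,
                             tiv_mean_by_gender = c(F = 1500000, M = 1350000),
                             tiv_sd = 100000,
                             age_range = c(12, 43),
                             grid_shape = c(128, 128),
                             pixel_size_mm = 1,
                             seed = 1L) {
  stopifnot(effect_amplitude_mm >= 0,
            warp_smoothness_mm > 0,
            warp_amplitude_mm >= 0,
            tiv_sd >= 0,
            length(age_range) == 2, age_range[1] <= age_range[2],
            length(grid_shape) == 2, all(grid_shape >= 8),
            effect_gender_ratio >= 0)
  if (!all(c("F", "M") %in% names(tiv_mean_by_gender)))
    stop("tiv_mean_by_gender must be named with 'F' and 'M'")
  if (!is.null(effect_support)) {
    if (length(effect_support) != 2 ||
        any(effect_support < 0) || any(effect_support >= 1))
      stop("effect_support must be two arc fractions within [0, 1)")
  }
  cfg <- list(n_per_cell = as.integer(n_per_cell),
              effect_amplitude_mm = effect_amplitude_mm,
              effect_support = effect_support,
              effect_gender_ratio = effect_gender_ratio,
              warp_smoothness_mm = warp_smoothness_mm,
              warp_amplitude_mm = warp_amplitude_mm,
              jitter_rot_sd_deg = jitter_rot_sd_deg,
              jitter_trans_sd_mm = jitter_trans_sd_mm,
              tiv_mean_by_gender = tiv_mean_by_gender,
              tiv_sd = tiv_sd,
              age_range = age_range,
              grid_shape = as.integer(grid_shape),
              pixel_size_mm = pixel_size_mm,
              seed = as.integer(seed))
  class(cfg) <- "cc_synth_config"
  cfg
}

## region codes used on every label slice
cc_region_levels <- function() c("gCC", "bCC", "sCC")

cc_label_slice <- function(grid, pixel_size_mm = 1) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  if (!all(grid %in% 0:3))
    stop("label grid must contain only codes 0 (background), 1 (gCC), 2 (bCC), 3 (sCC)")
  structure(list(grid = grid, pixel_size_mm = pixel_size_mm),
            class = "cc_label_slice")
}

#' @export
print.cc_label_slice <- function(x, ...) {
  cat("<cc_label_slice> ", nrow(x$grid), "x", ncol(x$grid),
      " @ ", x$pixel_size_mm, " mm, foreground ", sum(x$grid > 0),
      " px\n", sep = "")
  invisible(x)
}

#' Build the stylized base corpus-callosum label slice
#'
#' Constructs an arched band (a C-shape opening downward) between two
#' smooth radial profiles, with thickened anterior (genu) and posterior
#' (splenium) ends, and rasterizes it on a 1 mm grid. Sub-region labels
#' are assigned by angular thirds of the arc: the anterior third is genu
#' (gCC), the middle third body (bCC), the posterior third splenium
#' (sCC). The pre-raster outline (with per-vertex labels, inner/outer
#' side flags and arc fractions) is attached as attributes and reused by
#' [sample_subject_shape()] so that an identity deformation reproduces
#' the base raster exactly.
#'
#' @param grid_shape raster dimensions in pixels.
#' @param scale dimensionless global size factor (area scales as scale^2).
#' @param pixel_size_mm grid spacing (mm).
#' @param n_outline number of outline vertices (split between the outer
#'   and inner profile).
#' @param center optional (x, y) center in mm; defaults near the grid
#'   center.
#' @return a `cc_label_slice` with attributes `outline`,
#'   `outline_labels`, `outline_side`, `arc_frac`.
#' @export
make_base_cc_shape <- function(grid_shape = c(128, 128), scale = 1,
                               pixel_size_mm = 1, n_outline = 400,
                               center = NULL) {
  stopifnot(scale > 0, n_outline >= 40)
  nx <- grid_shape[1]; ny <- grid_shape[2]
  px <- pixel_size_mm
  if (is.null(center))
    center <- c((nx - 1) / 2 * px, (ny - 1) / 2 * px - 9 * scale)

  th_min <- -0.25; th_max <- pi + 0.25
  R_m <- 26 * scale
  h0 <- 3.2 * scale
  half_thick <- function(th) {
    h0 * (1 + 0.55 * exp(-((th - (pi + 0.05)) / 0.35)^2) +
            0.75 * exp(-((th - (-0.05)) / 0.40)^2))
  }
  m <- floor(n_outline / 2)
  ## outer profile traversed anterior -> posterior (clockwise, y-up), then
  ## inner profile back, which closes the band with two end caps
  th_out <- seq(th_max, th_min, length.out = m)
  th_in <- seq(th_min, th_max, length.out = m)
  outer_pts <- cbind(center[1] + (R_m + half_thick(th_out)) * cos(th_out),
                     center[2] + (R_m + half_thick(th_out)) * sin(th_out))
  inner_pts <- cbind(center[1] + (R_m - half_thick(th_in)) * cos(th_in),
                     center[2] + (R_m - half_thick(th_in)) * sin(th_in))
  outline <- rbind(outer_pts, inner_pts)
  side <- rep(c("outer", "inner"), each = m)
  th_all <- c(th_out, th_in)
  ## angular thirds: anterior (large theta) -> gCC, middle -> bCC,
  ## posterior -> sCC
  b1 <- th_min + 2 * (th_max - th_min) / 3
  b2 <- th_min + (th_max - th_min) / 3
  labels <- ifelse(th_all >= b1, "gCC", ifelse(th_all >= b2, "bCC", "sCC"))

  if (polygon_signed_area(outline) > 0) {
    idx <- rev(seq_len(nrow(outline)))
    outline <- outline[idx, ]; side <- side[idx]; labels <- labels[idx]
  }
  ## start at the lower-left vertex (min y, then min x), matching the
  ## traced-curve convention
  i0 <- order(outline[, 2], outline[, 1])[1]
  idx <- c(i0:nrow(outline), seq_len(i0 - 1))[seq_len(nrow(outline))]
  outline <- outline[idx, ]; side <- side[idx]; labels <- labels[idx]

  slice <- rasterize_labeled_outline(outline, labels, grid_shape, px)
  attr(slice, "outline") <- outline
  attr(slice, "outline_labels") <- labels
  attr(slice, "outline_side") <- side
  u <- polygon_arc_positions(outline)
  attr(slice, "arc_frac") <- u / polygon_perimeter(outline)
  attr(slice, "scale") <- scale
  slice
}

## Rasterize a labeled closed outline onto the pixel grid: a pixel is
## foreground when its center falls inside the polygon; its label is the
## label of the nearest outline vertex.
rasterize_labeled_outline <- function(outline, labels, grid_shape,
                                      pixel_size_mm = 1) {
  nx <- grid_shape[1]; ny <- grid_shape[2]
  px <- pixel_size_mm
  xr <- range(outline[, 1]); yr <- range(outline[, 2])
  over <- c(if (xr[1] < 0) "left", if (xr[2] > (nx - 1) * px) "right",
            if (yr[1] < 0) "bottom", if (yr[2] > (ny - 1) * px) "top")
  if (length(over))
    stop("shape overflows grid: ", paste(over, collapse = ", "),
         "; enlarge grid_shape or reduce scale")
  ix <- seq(max(1, floor(xr[1] / px)), min(nx, ceiling(xr[2] / px) + 1))
  iy <- seq(max(1, floor(yr[1] / px)), min(ny, ceiling(yr[2] / px) + 1))
  cx <- (ix - 1) * px; cy <- (iy - 1) * px
  gx <- rep(cx, times = length(cy)); gy <- rep(cy, each = length(cx))
  inside <- points_in_polygon(gx, gy, outline)
  grid <- matrix(0L, nx, ny)
  if (any(inside)) {
    qx <- gx[inside]; qy <- gy[inside]
    d2 <- pdist2(cbind(qx, qy), outline)
    lab_code <- match(labels, cc_region_levels())
    codes <- lab_code[max.col(-d2, ties.method = "first")]
    grid[cbind(rep(ix, times = length(iy))[inside],
               rep(iy, each = length(ix))[inside])] <- codes
  }
  cc_label_slice(grid, pixel_size_mm = px)
}

## Tukey (cosine-tapered) window over a cyclic arc-fraction support.
## taper is the ramp fraction on each side; the plateau keeps the injected
## first-order area deficit close to amplitude x support length.
effect_window <- function(u, support, taper = 0.25) {
  u0 <- support[1] %% 1
  len <- (support[2] - support[1]) %% 1
  if (len == 0) return(numeric(length(u)))
  rel <- ((u - u0) %% 1) / len
  w <- numeric(length(u))
  inside <- rel < 1
  z <- rel[inside]
  wi <- rep(1, length(z))
  lo <- z < taper
  hi <- z > 1 - taper
  wi[lo] <- 0.5 * (1 - cos(pi * z[lo] / taper))
  wi[hi] <- 0.5 * (1 - cos(pi * (1 - z[hi]) / taper))
  w[inside] <- wi
  w
}

## Resolve the default effect support: the outer-side genu arc of the base
## outline ("superior portion of gCC"), as a (possibly wrapping) arc
## fraction interval.
default_effect_support <- function(base) {
  lab <- attr(base, "outline_labels")
  side <- attr(base, "outline_side")
  u <- attr(base, "arc_frac")
  sel <- lab == "gCC" & side == "outer"
  if (!any(sel)) stop("base outline has no outer genu arc")
  idx <- which(sel)
  n <- length(lab)
  if (1L %in% idx && n %in% idx && !all(seq_len(n) %in% idx)) {
    ## run wraps through the start vertex: locate its cyclic endpoints
    gaps <- which(diff(idx) > 1)
    first_after_gap <- idx[gaps[1] + 1]
    last_before_gap <- idx[gaps[1]]
    c(u[first_after_gap], u[last_before_gap])
  } else {
    c(u[idx[1]], u[idx[length(idx)]])
  }
}

## outward unit normals of a clockwise (y-up) closed polygon
outline_outward_normals <- function(pts) {
  n <- nrow(pts)
  nxt <- pts[c(2:n, 1), , drop = FALSE]
  prv <- pts[c(n, 1:(n - 1)), , drop = FALSE]
  tng <- nxt - prv
  len <- sqrt(rowSums(tng^2))
  len[len == 0] <- 1
  cbind(-tng[, 2], tng[, 1]) / len
}

## evaluate the random Gaussian-bump velocity field and its Jacobian
warp_velocity <- function(x, centers, amps, width) {
  G <- exp(-pdist2(x, centers) / (2 * width^2))
  G %*% amps
}

warp_velocity_grad <- function(x, centers, amps, width) {
  ## Jacobian components of the bump field at each row of x, as vectors:
  ## dv_p/dx_q = sum_m a_mp (z_mq - x_q) / width^2 * G
  G <- exp(-pdist2(x, centers) / (2 * width^2)) / width^2
  z1 <- centers[, 1]; z2 <- centers[, 2]
  a1 <- amps[, 1]; a2 <- amps[, 2]
  list(J11 = as.numeric(G %*% (z1 * a1) - x[, 1] * (G %*% a1)),
       J12 = as.numeric(G %*% (z2 * a1) - x[, 2] * (G %*% a1)),
       J21 = as.numeric(G %*% (z1 * a2) - x[, 1] * (G %*% a2)),
       J22 = as.numeric(G %*% (z2 * a2) - x[, 2] * (G %*% a2)))
}

#' Deform the base shape into one subject's label slice
#'
#' Applies, in order: global scaling by `(tiv / reference TIV)^(1/3)`,
#' a random smooth stationary velocity-field warp (sum of Gaussian bumps,
#' integrated with 16 small compositional steps so the warp is
#' diffeomorphic), for patients an inward displacement along the outline
#' normal windowed over the configured arc support, and a small random
#' rigid jitter; the deformed outline is then re-rasterized with its
#' labels carried along.
#'
#' @param base base `cc_label_slice` from [make_base_cc_shape()].
#' @param record list or one-row data frame with `subject_id`, `group`
#'   (`"FES"` or `"HC"`), `gender` (`"F"`/`"M"`), `age`, `tiv`.
#' @param cfg a [synthetic_config()].
#' @param stream_seed optional integer RNG stream seed; defaults to a
#'   deterministic stream keyed by `(cfg$seed, subject_id)`.
#' @return a `cc_label_slice` with the deformed outline attached as
#'   attributes (as for the base).
#' @export
sample_subject_shape <- function(base, record, cfg, stream_seed = NULL) {
  stopifnot(inherits(base, "cc_label_slice"))
  outline <- attr(base, "outline")
  if (is.null(outline)) stop("base must carry a pre-raster outline")
  labels <- attr(base, "outline_labels")
  u <- attr(base, "arc_frac")
  set.seed(stream_seed %||% subject_stream_seed(cfg$seed, record$subject_id,
                                                "shape"))
  ## 1: global TIV-coupled scale (cube root: TIV is a volume, slice is 2D)
  s <- (record$tiv / mean(cfg$tiv_mean_by_gender))^(1 / 3)
  ctr <- colMeans(outline)
  O <- sweep(sweep(outline, 2, ctr) * s, 2, ctr, "+")

  ## 2: random smooth warp; bumps are drawn unconditionally so that the
  ## RNG stream does not depend on the effect settings
  n_bumps <- 12L
  width <- cfg$warp_smoothness_mm
  bb <- apply(O, 2, range)
  centers <- cbind(runif(n_bumps, bb[1, 1] - width, bb[2, 1] + width),
                   runif(n_bumps, bb[1, 2] - width, bb[2, 2] + width))
  amps <- matrix(rnorm(2 * n_bumps, 0, cfg$warp_amplitude_mm), n_bumps, 2)
  jit_theta <- rnorm(1, 0, pi / 180)
  jit_tr <- rnorm(2, 0, 1)
  if (cfg$warp_amplitude_mm > 0) {
    nsteps <- 16L
    ## fold check: propagate step-map Jacobians on a coarse probe grid
    probe <- as.matrix(expand.grid(seq(bb[1, 1], bb[2, 1], by = 4),
                                   seq(bb[1, 2], bb[2, 2], by = 4)))
    np <- nrow(probe)
    d11 <- rep(1, np); d12 <- rep(0, np); d21 <- rep(0, np); d22 <- rep(1, np)
    xp <- probe
    for (k in seq_len(nsteps)) {
      gr <- warp_velocity_grad(xp, centers, amps, width)
      s11 <- 1 + gr$J11 / nsteps; s12 <- gr$J12 / nsteps
      s21 <- gr$J21 / nsteps; s22 <- 1 + gr$J22 / nsteps
      ## each compositional step must itself preserve orientation
      if (any(s11 * s22 - s12 * s21 <= 0))
        stop("random warp folds (non-positive Jacobian); ",
             "reduce warp_amplitude_mm")
      n11 <- s11 * d11 + s12 * d21; n12 <- s11 * d12 + s12 * d22
      n21 <- s21 * d11 + s22 * d21; n22 <- s21 * d12 + s22 * d22
      d11 <- n11; d12 <- n12; d21 <- n21; d22 <- n22
      xp <- xp + warp_velocity(xp, centers, amps, width) / nsteps
    }
    if (any(d11 * d22 - d12 * d21 <= 0))
      stop("random warp folds (non-positive Jacobian); reduce warp_amplitude_mm")
    for (k in seq_len(nsteps))
      O <- O + warp_velocity(O, centers, amps, width) / nsteps
  }

  ## 3: localized inward group effect (patients only)
  amp_eff <- if (identical(as.character(record$group), "FES")) {
    cfg$effect_amplitude_mm *
      (if (identical(as.character(record$gender), "F")) 1 else cfg$effect_gender_ratio)
  } else 0
  if (amp_eff > 0) {
    support <- cfg$effect_support %||% default_effect_support(base)
    w <- effect_window(u, support)
    O <- O - amp_eff * w * outline_outward_normals(O)
  }

  ## 4: small random rigid jitter
  if (cfg$jitter_rot_sd_deg > 0 || cfg$jitter_trans_sd_mm > 0) {
    O <- rotate_points(O, jit_theta * cfg$jitter_rot_sd_deg, colMeans(O))
    O <- sweep(O, 2, jit_tr * cfg$jitter_trans_sd_mm, "+")
  }

  slice <- rasterize_labeled_outline(O, labels,
                                     dim(base$grid), base$pixel_size_mm)
  attr(slice, "outline") <- O
  attr(slice, "outline_labels") <- labels
  attr(slice, "outline_side") <- attr(base, "outline_side")
  attr(slice, "arc_frac") <- u
  slice
}

#' Generate a full synthetic cohort
#'
#' Produces `2 x 2 x n_per_cell` subjects (FES/HC crossed with F/M), each
#' with a labeled corpus-callosum-like mask slice and covariates (age,
#' gender, TIV). Subject RNG streams are keyed by `(seed, subject_id)`,
#' so the cohort is reproducible and order-independent.
#'
#' @param cfg a [synthetic_config()].
#' @return an object of class `cc_cohort`: a list with `slices` (named
#'   list of `cc_label_slice`), `covariates` (data frame with columns
#'   `subject_id,group,gender,age,tiv`), `base`, and `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cc_synth_config"))
  if (cfg$n_per_cell < 2)
    stop("n_per_cell must be at least 2 (group statistics undefined otherwise)")
  base <- make_base_cc_shape(grid_shape = cfg$grid_shape,
                             pixel_size_mm = cfg$pixel_size_mm)
  cells <- expand.grid(gender = c("F", "M"), group = c("FES", "HC"),
                       stringsAsFactors = FALSE)
  n <- nrow(cells) * cfg$n_per_cell
  ids <- sprintf("S%03d", seq_len(n))
  cov <- data.frame(subject_id = ids,
                    group = rep(cells$group, each = cfg$n_per_cell),
                    gender = rep(cells$gender, each = cfg$n_per_cell),
                    age = NA_real_, tiv = NA_real_,
                    stringsAsFactors = FALSE)
  slices <- vector("list", n)
  names(slices) <- ids
  for (i in seq_len(n)) {
    sid <- ids[i]
    set.seed(subject_stream_seed(cfg$seed, sid, "cov"))
    cov$age[i] <- round(runif(1, cfg$age_range[1], cfg$age_range[2]), 1)
    tiv <- rnorm(1, cfg$tiv_mean_by_gender[[cov$gender[i]]], cfg$tiv_sd)
    cov$tiv[i] <- round(max(tiv, cfg$tiv_mean_by_gender[[cov$gender[i]]] / 4))
    slices[[i]] <- sample_subject_shape(base, as.list(cov[i, ]), cfg)
  }
  structure(list(slices = slices, covariates = cov, base = base,
                 config = cfg),
            class = "cc_cohort")
}

#' @export
print.cc_cohort <- function(x, ...) {
  cat("<cc_cohort> ", nrow(x$covariates), " subjects (",
      sum(x$covariates$group == "FES"), " FES, ",
      sum(x$covariates$gender == "F"), " F), seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Masks are written as single-slice NIfTI volumes (dimension
#' `1 x nx x ny`, isotropic spacing), covariates as a CSV with header
#' `subject_id,group,gender,age,tiv`, and the full configuration plus
#' seed as a JSON sidecar.
#'
#' @param cohort a `cc_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (sid in names(cohort$slices)) {
    sl <- cohort$slices[[sid]]
    vol <- array(sl$grid, dim = c(1, dim(sl$grid)))
    p <- file.path(dir, "masks", paste0(sid, ".nii"))
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = rep(sl$pixel_size_mm, 3)),
                       p)
    paths <- c(paths, p)
  }
  covp <- file.path(dir, "covariates.csv")
  utils::write.csv(cohort$covariates, covp, row.names = FALSE, quote = FALSE)
  cfgp <- file.path(dir, "synthetic_config.json")
  cfg <- cohort$config
  cfg$effect_support <- cfg$effect_support %||%
    default_effect_support(cohort$base)
  jsonlite::write_json(unclass(cfg), cfgp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, covp, cfgp))
}
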