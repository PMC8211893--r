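#' Extract the mid-sagittal label slice from a labeled volume
#'
#' Takes the central slice along the sagittal (first) axis: 1-based index
#' `ceiling(n / 2)` for a volume with `n` sagittal slices, which is slice
#' 91 for the 181-slice MNI grid.
#'
#' @param volume a 3D integer label array (sagittal axis first), a NIfTI
#'   image, or a path to a NIfTI file. Labels: 0 background, 1 gCC,
#'   2 bCC, 3 sCC.
#' @param pixel_size_mm spacing override; taken from the NIfTI header
#'   when available, else 1.
#' @return a `cc_label_slice`.
#' @export
extract_midsagittal <- function(volume, pixel_size_mm = NULL) {
  if (is.character(volume)) volume <- RNifti::readNifti(volume)
  if (is.null(pixel_size_mm)) {
    pd <- tryCatch(RNifti::pixdim(volume), error = function(e) NULL)
    pixel_size_mm <- if (!is.null(pd) && length(pd) >= 2 && pd[2] > 0) pd[2] else 1
  }
  volume <- unclass(volume)
  if (length(dim(volume)) != 3) stop("volume must be a 3D label array")
  n <- dim(volume)[1]
  idx <- ceiling(n / 2)
  slice <- volume[idx, , ]
  slice[is.na(slice)] <- 0
  slice <- round(slice)
  if (!any(slice %in% 1:3))
    stop("no corpus callosum label found in mid-sagittal slice ", idx,
         "; check segmentation quality")
  cc_label_slice(slice, pixel_size_mm = pixel_size_mm)
}

## 8-connected components of a logical matrix by frontier expansion;
## returns an integer matrix of component ids (0 = background)
label_components8 <- function(fg) {
  comp <- matrix(0L, nrow(fg), ncol(fg))
  nx <- nrow(fg); ny <- ncol(fg)
  remaining <- which(fg)
  cur <- 0L
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  while (length(remaining)) {
    cur <- cur + 1L
    frontier <- remaining[1]
    comp[frontier] <- cur
    while (length(frontier)) {
      fx <- (frontier - 1L) %% nx + 1L
      fy <- (frontier - 1L) %/% nx + 1L
      cand <- integer(0)
      for (k in seq_len(nrow(offs))) {
        qx <- fx + offs[k, 1]; qy <- fy + offs[k, 2]
        ok <- qx >= 1 & qx <= nx & qy >= 1 & qy <= ny
        cand <- c(cand, (qy[ok] - 1L) * nx + qx[ok])
      }
      cand <- unique(cand)
      cand <- cand[fg[cand] & comp[cand] == 0L]
      comp[cand] <- cur
      frontier <- cand
    }
    remaining <- remaining[comp[remaining] == 0L]
  }
  comp
}

## Moore-neighbor boundary tracing with Jacob's stopping criterion.
## fg is indexed [ix, iy] with y-up; output is clockwise (y-up) starting
## from the lower-left pixel. Returns an index matrix (ix, iy).
moore_trace <- function(fg) {
  nx <- nrow(fg); ny <- ncol(fg)
  at <- function(ix, iy) ix >= 1 && ix <= nx && iy >= 1 && iy <= ny && fg[ix, iy]
  ## clockwise neighbor offsets in the y-up convention
  offs <- rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
                c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  idx <- which(fg, arr.ind = TRUE)
  ord <- order(idx[, 2], idx[, 1])
  start <- idx[ord[1], ]
  dir_S <- 5L  # direction from start to its backtrack (below start)
  ## one tracing step: scan the Moore neighborhood clockwise starting at
  ## the backtrack direction; returns the move direction, the next pixel
  ## and the backtrack direction seen from it
  step <- function(cur, back_dir) {
    for (k in 1:8) {
      d <- ((back_dir - 1L + k - 1L) %% 8L) + 1L
      q <- cur + offs[d, ]
      if (at(q[1], q[2])) {
        new_back <- ((d - 2L) %% 8L) + 1L  # last background scanned
        rel <- cur + offs[new_back, ] - q
        return(list(d = d, q = q,
                    back = which(offs[, 1] == rel[1] & offs[, 2] == rel[2])))
      }
    }
    NULL
  }
  path <- matrix(NA_integer_, 8L * sum(fg) + 8L, 2)
  path[1, ] <- start
  np <- 1L
  first <- step(start, dir_S)
  if (is.null(first)) return(path[1, , drop = FALSE])  # isolated pixel
  first_d <- first$d
  cur <- first$q
  back_dir <- first$back
  np <- 2L
  path[2, ] <- cur
  repeat {
    s <- step(cur, back_dir)
    ## Jacob's criterion: stop when the first move out of the start
    ## pixel is about to repeat
    if (cur[1] == start[1] && cur[2] == start[2] && s$d == first_d) {
      np <- np - 1L  # drop the duplicated start visit
      break
    }
    cur <- s$q
    back_dir <- s$back
    np <- np + 1L
    if (np > nrow(path)) stop("boundary tracing failed to terminate")
    path[np, ] <- cur
  }
  path[seq_len(np), , drop = FALSE]
}

## consolidate per-point labels into contiguous cyclic runs: a cyclic
## majority vote in a 5-point window, then reassignment of any leftover
## fragment to the nearest retained run
consolidate_labels <- function(labels) {
  n <- length(labels)
  if (n < 5) return(labels)
  lv <- cc_region_levels()
  for (pass in 1:5) {
    new <- labels
    for (i in seq_len(n)) {
      win <- labels[((i - 3L + seq_len(5)) %% n) + 1L]
      tab <- table(factor(win, levels = lv))
      if (tab[[labels[i]]] < max(tab)) new[i] <- lv[which.max(tab)]
    }
    if (identical(new, labels)) break
    labels <- new
  }
  ## enforce one cyclic run per label: keep the longest run of each label
  runs <- label_runs(labels)
  keep <- integer(0)
  for (lab in unique(labels)) {
    cand <- which(vapply(runs, function(r) r$label == lab, logical(1)))
    if (length(cand) > 1) {
      lens <- vapply(runs[cand], function(r) length(r$idx), integer(1))
      keep <- c(keep, cand[which.max(lens)])
    } else keep <- c(keep, cand)
  }
  if (length(keep) < length(runs)) {
    kept_idx <- unlist(lapply(runs[keep], `[[`, "idx"))
    kept_lab <- rep(vapply(runs[keep], `[[`, character(1), "label"),
                    vapply(runs[keep], function(r) length(r$idx), integer(1)))
    for (i in setdiff(seq_len(n), kept_idx)) {
      d <- pmin(abs(kept_idx - i), n - abs(kept_idx - i))
      labels[i] <- kept_lab[which.min(d)]
    }
  }
  labels
}

## cyclic runs of equal labels; runs wrapping the start are merged
label_runs <- function(labels) {
  n <- length(labels)
  brk <- which(labels != labels[c(n, seq_len(n - 1))])
  if (!length(brk)) return(list(list(label = labels[1], idx = seq_len(n))))
  starts <- sort(brk)
  runs <- list()
  for (k in seq_along(starts)) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1] - 1L else starts[1] - 1L + n
    idx <- ((seq.int(from, to) - 1L) %% n) + 1L
    runs[[k]] <- list(label = labels[from], idx = idx)
  }
  runs
}

#' Trace the labeled boundary curve of a corpus-callosum mask
#'
#' Moore-neighbor tracing over the foreground union of the three
#' sub-region labels, starting at the lower-left boundary pixel (minimum
#' y, then minimum x) and proceeding clockwise in the y-up convention.
#' Each curve point carries the sub-region label of its source pixel;
#' labels are consolidated so each sub-region occupies one contiguous
#' cyclic arc. Pixel centers are mapped to mm via the slice spacing.
#'
#' @param slice a `cc_label_slice`.
#' @param subject_id optional identifier stored on the curve.
#' @param min_boundary minimum number of boundary pixels for a plausible
#'   corpus callosum (default 4; a single pixel always errors).
#' @return a `cc_curve`: list with `points` (n x 2, mm), `labels`,
#'   `subject_id`, `pixel_area_mm2` (foreground pixel-count area) and
#'   `pixel_size_mm`.
#' @export
trace_boundary <- function(slice, subject_id = NULL, min_boundary = 4) {
  stopifnot(inherits(slice, "cc_label_slice"))
  fg <- slice$grid > 0L
  if (!any(fg)) stop("empty label slice")
  comp <- label_components8(fg)
  ncomp <- max(comp)
  if (ncomp > 1) {
    warning("foreground has ", ncomp,
            " 8-connected components; tracing the largest")
    sizes <- tabulate(comp[comp > 0])
    fg <- comp == which.max(sizes)
  }
  path <- moore_trace(fg)
  if (nrow(unique(path)) < min_boundary)
    stop("only ", nrow(unique(path)),
         " boundary pixels; implausibly small corpus callosum")
  px <- slice$pixel_size_mm
  pts <- (path - 1) * px
  labels <- cc_region_levels()[slice$grid[path]]
  labels[is.na(labels)] <- cc_region_levels()[1]
  labels <- consolidate_labels(labels)
  structure(list(points = pts, labels = labels,
                 subject_id = subject_id %||% NA_character_,
                 pixel_area_mm2 = sum(fg) * px^2,
                 pixel_size_mm = px),
            class = "cc_curve")
}

#' @export
print.cc_curve <- function(x, ...) {
  cat("<cc_curve> ", x$subject_id, ": ", nrow(x$points), " points, area ",
      format(x$pixel_area_mm2), " mm^2 (pixel count)\n", sep = "")
  invisible(x)
}

#' Sub-region and total areas of a label slice
#'
#' Pixel-count areas in mm^2 for each sub-region and their sum (the
#' whole corpus callosum); exact integers on a 1 mm grid.
#'
#' @param slice a `cc_label_slice`.
#' @return named numeric vector `c(CC, gCC, bCC, sCC)` in mm^2.
#' @export
region_areas <- function(slice) {
  stopifnot(inherits(slice, "cc_label_slice"))
  px2 <- slice$pixel_size_mm^2
  counts <- tabulate(slice$grid[slice$grid > 0L], nbins = 3) * px2
  c(CC = sum(counts), gCC = counts[1], bCC = counts[2], sCC = counts[3])
}

#' Enclosed area of a boundary curve
#'
#' Absolute shoelace area of the closed pixel-center polygon. Note that
#' for a traced raster boundary this is systematically smaller than the
#' pixel-count area (a w x h block encloses (w-1)(h-1) between pixel
#' centers); the pixel-count dialect is used for template selection and
#' area statistics, the shoelace dialect for internal consistency checks.
#'
#' @param curve a `cc_curve`, or an n x 2 point matrix.
#' @return area in mm^2.
#' @export
curve_area <- function(curve) {
  pts <- if (inherits(curve, "cc_curve")) curve$points else as.matrix(curve)
  if (nrow(pts) < 3) stop("curve must have at least 3 points")
  if (polygon_self_intersects(pts))
    stop("curve is self-intersecting; area undefined")
  abs(polygon_signed_area(pts))
}

## one Zhang-Suen thinning pass; sub = 1 or 2
.zs_pass <- function(M, sub) {
  nx <- nrow(M); ny <- ncol(M)
  P <- matrix(FALSE, nx + 2, ny + 2)
  P[2:(nx + 1), 2:(ny + 1)] <- M
  sh <- function(dx, dy) P[2:(nx + 1) + dx, 2:(ny + 1) + dy]
  p2 <- sh(0, 1); p3 <- sh(1, 1); p4 <- sh(1, 0); p5 <- sh(1, -1)
  p6 <- sh(0, -1); p7 <- sh(-1, -1); p8 <- sh(-1, 0); p9 <- sh(-1, 1)
  B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  A <- matrix(0L, nx, ny)
  for (k in 1:8) A <- A + (!seqs[[k]] & seqs[[k + 1]])
  if (sub == 1) {
    c3 <- !(p2 & p4 & p6); c4 <- !(p4 & p6 & p8)
  } else {
    c3 <- !(p2 & p4 & p8); c4 <- !(p2 & p6 & p8)
  }
  del <- M & B >= 2 & B <= 6 & A == 1 & c3 & c4
  M & !del
}

## Zhang-Suen morphological skeleton of a logical matrix
skeletonize <- function(M) {
  repeat {
    M1 <- .zs_pass(M, 1)
    M2 <- .zs_pass(M1, 2)
    if (identical(M2, M)) return(M2)
    M <- M2
  }
}

#' Regional thickness of the corpus callosum mask
#'
#' Thickness estimated as twice the Euclidean distance transform sampled
#' on the morphological skeleton of the foreground, aggregated per
#' sub-region (by the label of each skeleton pixel) and overall.
#'
#' @param slice a `cc_label_slice`.
#' @return named numeric vector `c(CC, gCC, bCC, sCC)` of mean
#'   thicknesses in mm (`NA` for absent regions).
#' @export
regional_thickness <- function(slice) {
  stopifnot(inherits(slice, "cc_label_slice"))
  fg <- slice$grid > 0L
  if (!any(fg)) stop("empty label slice")
  edt <- EBImage::distmap(fg * 1L)
  edt <- matrix(as.numeric(edt), nrow(fg), ncol(fg))
  skel <- skeletonize(fg)
  if (!any(skel)) stop("skeleton is empty; degenerate region")
  px <- slice$pixel_size_mm
  th <- 2 * edt[skel] * px
  lab <- slice$grid[skel]
  out <- c(CC = mean(th),
           gCC = if (any(lab == 1L)) mean(th[lab == 1L]) else NA_real_,
           bCC = if (any(lab == 2L)) mean(th[lab == 2L]) else NA_real_,
           sCC = if (any(lab == 3L)) mean(th[lab == 3L]) else NA_real_)
  out
}

#' Write traced curves to CSV
#'
#' Standard curve CSV dialect: columns
#' `subject_id,point_index,x_mm,y_mm,region`, plus a JSON metadata
#' sidecar `<path>.json` with the pixel size and per-subject point
#' counts and pixel-count areas.
#'
#' @param curves a `cc_curve` or list of them.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_curves_csv <- function(curves, path) {
  if (inherits(curves, "cc_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    data.frame(subject_id = cv$subject_id,
               point_index = seq_len(nrow(cv$points)),
               x_mm = cv$points[, 1], y_mm = cv$points[, 2],
               region = cv$labels, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  meta <- data.frame(
    subject_id = vapply(curves, function(cv) as.character(cv$subject_id),
                        character(1)),
    n_points = vapply(curves, function(cv) nrow(cv$points), integer(1)),
    pixel_area_mm2 = vapply(curves, function(cv)
      as.numeric(cv$pixel_area_mm2), numeric(1)),
    stringsAsFactors = FALSE)
  jsonlite::write_json(list(pixel_size_mm = curves[[1]]$pixel_size_mm,
                            subjects = meta),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read curves from the standard curve CSV
#'
#' @param path CSV written by [write_curves_csv()].
#' @return a named list of `cc_curve` objects (without pixel areas).
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$point_index), ]
    structure(list(points = cbind(d$x_mm, d$y_mm), labels = d$region,
                   subject_id = d$subject_id[1],
                   pixel_area_mm2 = NA_real_, pixel_size_mm = NA_real_),
              class = "cc_curve")
  })
  out[unique(df$subject_id)]
}
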