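## one equal-arc-length pass over a closed polygon, keeping the start
.equal_arc <- function(pts, K) {
  n <- nrow(pts)
  nxt <- pts[c(2:n, 1), , drop = FALSE]
  seg <- sqrt(rowSums((nxt - pts)^2))
  L <- sum(seg)
  if (L <= 0) stop("degenerate curve: zero perimeter")
  s_vert <- c(0, cumsum(seg))
  targ <- (seq_len(K) - 1) * L / K
  i <- findInterval(targ, s_vert, rightmost.closed = TRUE)
  i[i > n] <- n
  frac <- (targ - s_vert[i]) / seg[i]
  frac[!is.finite(frac)] <- 0
  pts[i, , drop = FALSE] + frac * (nxt[i, , drop = FALSE] -
                                     pts[i, , drop = FALSE])
}

#' Resample a closed curve to uniform spacing
#'
#' Places `K` points along the closed polygon, preserving orientation
#' and the start point, and iterates the equal-arc-length placement to
#' its fixed point so that consecutive points end up equally spaced
#' along the resampled polygon itself (which makes the operation
#' idempotent). Each resampled point inherits the sub-region label of
#' the nearest original vertex.
#'
#' @param curve a `cc_curve` or an n x 2 point matrix.
#' @param K number of resampled points (>= 3).
#' @return a list with `points` (K x 2) and `labels` (length K, `NA`
#'   when the input carries no labels).
#' @export
resample_closed_curve <- function(curve, K) {
  pts <- if (inherits(curve, "cc_curve")) curve$points else as.matrix(curve)
  labels <- if (inherits(curve, "cc_curve")) curve$labels else NULL
  if (K < 3) stop("K must be at least 3")
  ## drop consecutive duplicate vertices (raster spurs)
  keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2) > 0)
  pts <- pts[keep, , drop = FALSE]
  if (!is.null(labels)) labels <- labels[keep]
  if (nrow(pts) < 3) stop("degenerate curve: fewer than 3 distinct points")
  out <- .equal_arc(pts, K)
  for (it in 1:30) {
    nxt <- .equal_arc(out, K)
    moved <- max(abs(nxt - out))
    out <- nxt
    if (moved < 1e-11 * max(1, max(abs(out)))) break
  }
  lab_out <- if (is.null(labels)) rep(NA_character_, K) else {
    labels[max.col(-pdist2(out, pts), ties.method = "first")]
  }
  list(points = out, labels = lab_out)
}

#' Select the cohort template curve
#'
#' Picks the curve whose pixel-count area is closest to the cohort mean
#' area (ties broken by the lexicographically smallest subject id) and
#' resamples it to `K` equally spaced points starting at its lower-left
#' start point.
#'
#' @param curves list of `cc_curve` objects (>= 2) with pixel areas.
#' @param K number of template points (default 200).
#' @return a `cc_template`: list with `points`, `labels`, `subject_id`,
#'   `K`, `pixel_area_mm2`, `curve_area_mm2`, `source_curve`, and
#'   per-subject selection `diagnostics`.
#' @export
select_template <- function(curves, K = 200) {
  if (length(curves) < 2)
    stop("template selection requires at least 2 curves")
  if (K < 8) stop("template discretization K must be at least 8")
  areas <- vapply(curves, function(cv) cv$pixel_area_mm2, numeric(1))
  ids <- vapply(curves, function(cv) as.character(cv$subject_id),
                character(1))
  if (anyNA(areas)) stop("curves must carry pixel-count areas")
  mu <- mean(areas)
  dev <- abs(areas - mu)
  pick <- order(dev, ids)[1]
  rs <- resample_closed_curve(curves[[pick]], K)
  structure(list(points = rs$points, labels = rs$labels,
                 subject_id = ids[pick], K = K,
                 pixel_area_mm2 = areas[pick],
                 curve_area_mm2 = abs(polygon_signed_area(rs$points)),
                 source_curve = curves[[pick]],
                 diagnostics = data.frame(subject_id = ids,
                                          area_mm2 = areas,
                                          abs_dev_from_mean = dev,
                                          stringsAsFactors = FALSE)),
            class = "cc_template")
}

#' @export
print.cc_template <- function(x, ...) {
  cat("<cc_template> from ", x$subject_id, ": K = ", x$K,
      ", area ", format(x$pixel_area_mm2), " mm^2 (pixel count)\n",
      sep = "")
  invisible(x)
}

#' Write a template curve and its selection diagnostics
#'
#' @param template a `cc_template`.
#' @param path CSV path for the curve (standard curve dialect); a JSON
#'   sidecar `<path>.json` records the selection diagnostics.
#' @return invisibly, the paths written.
#' @export
write_template <- function(template, path) {
  df <- data.frame(subject_id = template$subject_id,
                   point_index = seq_len(nrow(template$points)),
                   x_mm = unname(template$points[, 1]),
                   y_mm = unname(template$points[, 2]),
                   region = template$labels, stringsAsFactors = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jp <- paste0(path, ".json")
  jsonlite::write_json(list(subject_id = template$subject_id,
                            K = template$K,
                            pixel_area_mm2 = template$pixel_area_mm2,
                            curve_area_mm2 = template$curve_area_mm2,
                            diagnostics = template$diagnostics),
                       jp, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(c(path, jp))
}

#' Read a template written by [write_template()]
#' @param path the CSV path.
#' @return a `cc_template` (without the source curve).
#' @export
read_template <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(points = cbind(df$x_mm, df$y_mm), labels = df$region,
                 subject_id = meta$subject_id, K = meta$K,
                 pixel_area_mm2 = meta$pixel_area_mm2,
                 curve_area_mm2 = meta$curve_area_mm2,
                 source_curve = NULL,
                 diagnostics = as.data.frame(meta$diagnostics)),
            class = "cc_template")
}
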