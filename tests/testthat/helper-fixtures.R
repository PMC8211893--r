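# Shared fixtures: all synthetic, built in code at test time.

.fix <- new.env()

fixture_base <- function() {
  if (is.null(.fix$base)) .fix$base <- make_base_cc_shape()
  .fix$base
}

## cc_template built directly from one slice (bypasses cohort selection)
template_from_slice <- function(slice, K = 60, id = "tplsrc") {
  cv <- trace_boundary(slice, id)
  rs <- resample_closed_curve(cv, K)
  structure(list(points = rs$points, labels = rs$labels, subject_id = id,
                 K = K, pixel_area_mm2 = cv$pixel_area_mm2,
                 curve_area_mm2 = abs(ccmorph:::polygon_signed_area(rs$points)),
                 source_curve = cv, diagnostics = NULL),
            class = "cc_template")
}

fixture_template <- function(K = 60) {
  key <- paste0("tpl", K)
  if (is.null(.fix[[key]])) .fix[[key]] <- template_from_slice(fixture_base(), K)
  .fix[[key]]
}

## rectangular label slice with a margin of background
rect_slice <- function(w, h, label = 1L, margin = 3L) {
  g <- matrix(0L, w + 2L * margin, h + 2L * margin)
  g[margin + seq_len(w), margin + seq_len(h)] <- label
  ccmorph:::cc_label_slice(g)
}

## brute-force boundary oracle: foreground pixels with at least one
## background 4-neighbor (the grid border counts as background)
boundary_pixel_oracle <- function(fg) {
  nx <- nrow(fg); ny <- ncol(fg)
  P <- matrix(FALSE, nx + 2, ny + 2)
  P[2:(nx + 1), 2:(ny + 1)] <- fg
  all4 <- P[1:nx, 2:(ny + 1)] & P[3:(nx + 2), 2:(ny + 1)] &
    P[2:(nx + 1), 1:ny] & P[2:(nx + 1), 3:(ny + 2)]
  which(fg & !all4, arr.ind = TRUE)
}

## smooth random blob mask: sum of Gaussian bumps thresholded, largest
## 8-connected component, 4-connectivity holes filled
random_blob_mask <- function(n = 48, seed = 1) {
  set.seed(seed)
  ctr <- cbind(runif(6, n * 0.25, n * 0.75), runif(6, n * 0.25, n * 0.75))
  amp <- runif(6, 0.5, 1)
  gx <- rep(seq_len(n), times = n); gy <- rep(seq_len(n), each = n)
  v <- numeric(n * n)
  for (k in 1:6)
    v <- v + amp[k] * exp(-((gx - ctr[k, 1])^2 + (gy - ctr[k, 2])^2) /
                            (2 * (n / 8)^2))
  fg <- matrix(v >= stats::quantile(v, 0.8), n, n)
  comp <- ccmorph:::label_components8(fg)
  fg <- comp == which.max(tabulate(comp[comp > 0]))
  ## fill holes: background not 4-connected to the border becomes fg
  reach <- matrix(FALSE, n, n)
  frontier <- which(!fg & (gx == 1 | gx == n | gy == 1 | gy == n))
  reach[frontier] <- TRUE
  while (length(frontier)) {
    fx <- (frontier - 1L) %% n + 1L
    fy <- (frontier - 1L) %/% n + 1L
    cand <- c((fy - 1L) * n + pmax(fx - 1L, 1L),
              (fy - 1L) * n + pmin(fx + 1L, n),
              pmax(fy - 2L, 0L) * n + fx,
              pmin(fy, n - 1L) * n + fx)
    cand <- unique(cand)
    cand <- cand[!fg[cand] & !reach[cand]]
    reach[cand] <- TRUE
    frontier <- cand
  }
  fg | (!fg & !reach)
}

## quick synthetic study: cohort -> curves -> template -> registration
run_small_study <- function(seed, n_per_cell = 25, K = 50, n_perm = 500,
                            effect_amplitude_mm = 0.8, reg_iters = 40,
                            scopes = c("female", "male")) {
  cfg <- synthetic_config(n_per_cell = n_per_cell,
                          effect_amplitude_mm = effect_amplitude_mm,
                          seed = seed)
  co <- generate_cohort(cfg)
  curves <- lapply(names(co$slices),
                   function(s) trace_boundary(co$slices[[s]], s))
  names(curves) <- names(co$slices)
  tpl <- select_template(curves, K = K)
  rcfg <- registration_config(max_iters = reg_iters, rel_tol = 1e-4)
  mtab <- suppressWarnings(register_cohort(curves, tpl, rcfg))
  stats <- list()
  for (i in seq_along(scopes))
    stats[[scopes[i]]] <- pointwise_shape_analysis(
      mtab, co$covariates, scope = scopes[i], n_perm = n_perm,
      seed = seed + i)
  list(cohort = co, template = tpl, mtab = mtab, stats = stats)
}

## map the injected effect support onto a template's arc fractions
template_arc_fracs <- function(tpl) {
  ccmorph:::polygon_arc_positions(tpl$points) /
    ccmorph:::polygon_perimeter(tpl$points)
}

support_on_template <- function(tpl, base) {
  sup <- ccmorph:::default_effect_support(base)
  out <- attr(base, "outline")
  bu <- attr(base, "arc_frac")
  tu <- template_arc_fracs(tpl)
  near_frac <- function(u) {
    i <- which.min(ccmorph:::cyclic_frac_dist(bu, u))
    j <- which.min(rowSums(sweep(tpl$points, 2, out[i, ])^2))
    tu[j]
  }
  v <- c(near_frac(sup[1]), near_frac(sup[2]))
  if (((v[2] - v[1]) %% 1) > 0.5) v <- rev(v)
  v
}

## per-subject region areas of a cohort as a data frame
cohort_areas <- function(co) {
  do.call(rbind, lapply(names(co$slices), function(s) {
    a <- region_areas(co$slices[[s]])
    data.frame(subject_id = s, CC = a[["CC"]], gCC = a[["gCC"]],
               bCC = a[["bCC"]], sCC = a[["sCC"]],
               stringsAsFactors = FALSE)
  }))
}
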