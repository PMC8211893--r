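#' Configuration of the rigid + LDDMM curve registration
#'
#' Free parameters of the diffeomorphic curve matching. The velocity
#' kernel width `sigma_V` controls the smoothness scale of admissible
#' deformations, the currents kernel width `sigma_W` the spatial scale at
#' which the two curves are compared, and `lambda_match` the trade-off
#' between deformation cost and matching fidelity. `NULL` values are
#' resolved per registration: `sigma_V` to 1/8 of the template
#' bounding-box diagonal, `sigma_W` to `sigma_V / 2`, and `lambda_match`
#' to `K / mismatch_0`, which normalizes the initial currents mismatch to
#' the number of curve points so that the two energy terms are of
#' comparable order once the optimizer has moved. In cohort use,
#' [register_cohort()] resolves one study-wide `lambda_match` from the
#' median initial mismatch across subjects, so that every subject is
#' registered with the same deformation/matching trade-off.
#'
#' @param sigma_V velocity (deformation) kernel width, mm.
#' @param sigma_W currents (matching) kernel width, mm.
#' @param lambda_match matching-term weight (dimensionless).
#' @param n_timesteps flow discretization steps (>= 5).
#' @param max_iters maximum gradient-descent iterations.
#' @param rel_tol relative energy-decrease stopping threshold.
#' @param rigid_max_iters maximum ICP iterations of the rigid prestep.
#' @return an object of class `cc_reg_config`.
#' @export
registration_config <- function(sigma_V = NULL, sigma_W = NULL,
                                lambda_match = NULL, n_timesteps = 10,
                                max_iters = 500, rel_tol = 1e-6,
                                rigid_max_iters = 50) {
  stopifnot(is.null(sigma_V) || sigma_V > 0,
            is.null(sigma_W) || sigma_W > 0,
            is.null(lambda_match) || lambda_match > 0,
            n_timesteps >= 5, max_iters >= 1, rel_tol > 0,
            rigid_max_iters >= 1)
  structure(list(sigma_V = sigma_V, sigma_W = sigma_W,
                 lambda_match = lambda_match,
                 n_timesteps = as.integer(n_timesteps),
                 max_iters = as.integer(max_iters), rel_tol = rel_tol,
                 rigid_max_iters = as.integer(rigid_max_iters)),
            class = "cc_reg_config")
}

.as_points <- function(x) {
  if (inherits(x, "cc_curve") || inherits(x, "cc_template")) x$points
  else as.matrix(x)
}

#' Rigidly align a target curve to the template
#'
#' Rotation plus translation (no scaling, no reflection) minimizing the
#' symmetric nearest-point squared distance, refined by iterative closest
#' point (ICP) from a centroid + principal-axis initialization. Size
#' differences are deliberately left in place so that they appear in the
#' deformation markers.
#'
#' @param target curve to align (`cc_curve`, resampled list, or matrix).
#' @param template reference curve.
#' @param max_iters maximum ICP iterations.
#' @param tol relative cost-change convergence threshold.
#' @return list with `theta` (rotation angle, radians), `translation`
#'   (mm), `aligned` (transformed target points), `rms` (symmetric
#'   root-mean-square nearest-point distance) and `iterations`.
#' @export
rigid_align <- function(target, template, max_iters = 50, tol = 1e-10) {
  S <- .as_points(target); Tm <- .as_points(template)
  if (nrow(S) < 8 || nrow(Tm) < 8)
    stop("rigid alignment needs closed curves with at least 8 points")
  sym_cost <- function(P) {
    d2 <- pdist2(P, Tm)
    (sum(apply(d2, 1, min)) + sum(apply(d2, 2, min))) / (nrow(P) + nrow(Tm))
  }
  ## initialization: centroids + principal axes (two orientations)
  cS <- colMeans(S); cT <- colMeans(Tm)
  ang <- function(P, ctr) {
    v <- eigen(stats::cov(sweep(P, 2, ctr)))$vectors[, 1]
    atan2(v[2], v[1])
  }
  base_theta <- ang(Tm, cT) - ang(S, cS)
  best <- NULL
  for (th in c(base_theta, base_theta + pi)) {
    P <- sweep(rotate_points(sweep(S, 2, cS), th), 2, cT, "+")
    cst <- sym_cost(P)
    if (is.null(best) || cst < best$cost)
      best <- list(theta = th, cost = cst)
  }
  theta <- best$theta
  trans <- cT - c(rot2(theta) %*% cS)
  apply_rt <- function(theta, trans) {
    sweep(S %*% t(rot2(theta)), 2, trans, "+")
  }
  P <- apply_rt(theta, trans)
  cost <- sym_cost(P)
  n_up <- 0L
  it <- 0L
  while (it < max_iters) {
    it <- it + 1L
    d2 <- pdist2(P, Tm)
    nn_t <- max.col(-d2, ties.method = "first")       # template nn of each target
    nn_s <- max.col(-t(d2), ties.method = "first")    # target nn of each template
    A <- rbind(S, S[nn_s, , drop = FALSE])            # source points (original frame)
    B <- rbind(Tm[nn_t, , drop = FALSE], Tm)          # matched template points
    cA <- colMeans(A); cB <- colMeans(B)
    H <- crossprod(sweep(A, 2, cA), sweep(B, 2, cB))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
    theta_new <- atan2(R[2, 1], R[1, 1])
    trans_new <- cB - c(R %*% cA)
    P_new <- apply_rt(theta_new, trans_new)
    cost_new <- sym_cost(P_new)
    if (cost_new > cost * (1 + 1e-8) + 1e-12) {
      n_up <- n_up + 1L
      if (n_up >= 5L)
        stop("ICP diverged: symmetric distance increased for 5 consecutive ",
             "iterations (cost ", format(cost_new), ")")
    } else n_up <- 0L
    done <- abs(cost - cost_new) <= tol * max(cost, .Machine$double.eps)
    if (cost_new <= cost) {
      theta <- theta_new; trans <- trans_new; P <- P_new; cost <- cost_new
    }
    if (done) break
  }
  list(theta = theta, translation = trans, aligned = P,
       rms = sqrt(cost), iterations = it)
}

## currents representation of a closed polygon: midpoints + tangents
.currents_repr <- function(pts) polygon_segments(pts)

#' Squared currents distance between two curves
#'
#' Represents each closed curve as a current via its segment midpoints
#' `c_i` and tangent vectors `tau_i`, with Gaussian kernel
#' `exp(-|c_i - c_j|^2 / sigma_W^2)`, and returns
#' `||[a]||^2 + ||[b]||^2 - 2 <[a],[b]>`. Zero when the curves coincide;
#' symmetric; orientation-sensitive (reversing one curve negates its
#' tangents).
#'
#' @param curve_a,curve_b curves (`cc_curve`, template, or matrices).
#' @param sigma_W currents kernel width (mm).
#' @return nonnegative scalar.
#' @export
currents_mismatch <- function(curve_a, curve_b, sigma_W) {
  A <- .currents_repr(.as_points(curve_a))
  B <- .currents_repr(.as_points(curve_b))
  s2 <- sigma_W^2
  ip <- function(u, v) {
    sum(exp(-pdist2(u$center, v$center) / s2) * tcrossprod(u$tangent, v$tangent))
  }
  ip(A, A) + ip(B, B) - 2 * ip(A, B)
}

## gradient of the squared currents distance w.r.t. the vertices of a;
## b is fixed. Returns n x 2.
.currents_grad <- function(pts_a, repr_b, sigma_W) {
  A <- .currents_repr(pts_a)
  s2 <- sigma_W^2
  Gaa <- exp(-pdist2(A$center, A$center) / s2)
  Gab <- exp(-pdist2(A$center, repr_b$center) / s2)
  ## dM/dtau_i
  U <- 2 * (Gaa %*% A$tangent - Gab %*% repr_b$tangent)
  ## dM/dc_i
  Waa <- Gaa * tcrossprod(A$tangent, A$tangent)
  Wab <- Gab * tcrossprod(A$tangent, repr_b$tangent)
  dMdc <- (-4 / s2) * ((rowSums(Waa) * A$center - Waa %*% A$center) -
                         (rowSums(Wab) * A$center - Wab %*% repr_b$center))
  n <- nrow(pts_a)
  prev <- c(n, seq_len(n - 1))
  ## vertex k ends segment k-1 (dtau = +I, dc = 1/2) and starts segment k
  ## (dtau = -I, dc = 1/2)
  (U[prev, , drop = FALSE] - U) + 0.5 * (dMdc[prev, , drop = FALSE] + dMdc)
}

## forward Euler flow of control points under their own momenta
.lddmm_forward <- function(A, x0, sigV2, dt) {
  Tn <- dim(A)[3]
  X <- vector("list", Tn + 1)
  G <- vector("list", Tn)
  X[[1]] <- x0
  Ereg <- 0
  for (t in seq_len(Tn)) {
    Gt <- exp(-pdist2(X[[t]], X[[t]]) / sigV2)
    V <- Gt %*% A[, , t]
    Ereg <- Ereg + dt * sum(A[, , t] * V)
    X[[t + 1]] <- X[[t]] + dt * V
    G[[t]] <- Gt
  }
  list(X = X, G = G, Ereg = Ereg)
}

## adjoint (reverse) sweep: gradient of the total energy w.r.t. momenta
.lddmm_gradient <- function(A, fwd, repr_b, sigV2, sigma_W, lambda, dt) {
  Tn <- dim(A)[3]
  P <- lambda * .currents_grad(fwd$X[[Tn + 1]], repr_b, sigma_W)
  gA <- array(0, dim(A))
  for (t in rev(seq_len(Tn))) {
    Gt <- fwd$G[[t]]
    At <- A[, , t]
    Xt <- fwd$X[[t]]
    gA[, , t] <- dt * (2 * (Gt %*% At) + Gt %*% P)
    C <- tcrossprod(At, P) + tcrossprod(P, At) + 2 * tcrossprod(At, At)
    W <- Gt * C
    gX <- (-2 / sigV2) * (rowSums(W) * Xt - W %*% Xt)
    P <- P + dt * gX
  }
  gA
}

## propagate the 2x2 ambient Jacobian along the flow with the same Euler
## scheme; D stored as columns (d11, d12, d21, d22)
.jacobian_along_flow <- function(A, Xlist, Glist, sigV2, dt) {
  K <- nrow(Xlist[[1]])
  Tn <- dim(A)[3]
  d11 <- rep(1, K); d12 <- rep(0, K); d21 <- rep(0, K); d22 <- rep(1, K)
  for (t in seq_len(Tn)) {
    Gt <- Glist[[t]]
    X <- Xlist[[t]]
    a1 <- A[, 1, t]; a2 <- A[, 2, t]
    M11 <- (-2 / sigV2) * (X[, 1] * (Gt %*% a1) - Gt %*% (a1 * X[, 1]))
    M12 <- (-2 / sigV2) * (X[, 2] * (Gt %*% a1) - Gt %*% (a1 * X[, 2]))
    M21 <- (-2 / sigV2) * (X[, 1] * (Gt %*% a2) - Gt %*% (a2 * X[, 1]))
    M22 <- (-2 / sigV2) * (X[, 2] * (Gt %*% a2) - Gt %*% (a2 * X[, 2]))
    n11 <- d11 + dt * (M11 * d11 + M12 * d21)
    n12 <- d12 + dt * (M11 * d12 + M12 * d22)
    n21 <- d21 + dt * (M21 * d11 + M22 * d21)
    n22 <- d22 + dt * (M21 * d12 + M22 * d22)
    d11 <- n11; d12 <- n12; d21 <- n21; d22 <- n22
  }
  cbind(d11, d12, d21, d22)
}

#' LDDMM matching of the template curve onto an aligned target
#'
#' Minimizes the time-discretized LDDMM energy
#' `sum_t dt sum_ij alpha_i(t) . alpha_j(t) K_V(x_i(t), x_j(t)) +
#' lambda * currents_mismatch(phi_1(template), target)` over momenta
#' supported at the template points, with Gaussian velocity kernel
#' `K_V(x, y) = exp(-|x - y|^2 / sigma_V^2)`, explicit Euler flow, and
#' gradient descent with Armijo backtracking. The 2x2 ambient Jacobian
#' of the transport is integrated along the flow with the same scheme and
#' its determinant at each template point is the deformation marker `J`:
#' `J > 1` is local outward deformation (expansion), `J < 1` inward.
#'
#' @param template a `cc_template` (or K x 2 matrix).
#' @param target the rigidly aligned target curve (matrix or `cc_curve`).
#' @param cfg a [registration_config()].
#' @return a `cc_registration`: momenta, deformed template, per-point
#'   Jacobians and markers, energies and convergence information.
#' @export
lddmm_match <- function(template, target, cfg = registration_config()) {
  x0 <- .as_points(template)
  tg <- .as_points(target)
  K <- nrow(x0)
  diag_bb <- sqrt(sum((apply(x0, 2, max) - apply(x0, 2, min))^2))
  sigma_V <- cfg$sigma_V %||% (diag_bb / 8)
  sigma_W <- cfg$sigma_W %||% (sigma_V / 2)
  sigV2 <- sigma_V^2
  Tn <- cfg$n_timesteps
  dt <- 1 / Tn
  repr_b <- .currents_repr(tg)
  M0 <- currents_mismatch(x0, tg, sigma_W)
  lambda <- cfg$lambda_match %||% (if (M0 > 1e-12) K / M0 else 1)

  A <- array(0, dim = c(K, 2, Tn))
  fwd <- .lddmm_forward(A, x0, sigV2, dt)
  energy <- function(fwd_state) {
    fwd_state$Ereg +
      lambda * currents_mismatch(fwd_state$X[[Tn + 1]], tg, sigma_W)
  }
  E <- energy(fwd)
  E0 <- E
  trace <- E
  step <- NULL
  it <- 0L
  converged <- FALSE
  while (it < cfg$max_iters) {
    it <- it + 1L
    g <- .lddmm_gradient(A, fwd, repr_b, sigV2, sigma_W, lambda, dt)
    gnorm2 <- sum(g^2)
    if (!is.finite(gnorm2)) stop("non-finite gradient in LDDMM matching")
    if (gnorm2 < 1e-30) { converged <- TRUE; break }
    if (is.null(step)) step <- 0.1 * sigma_V / sqrt(max(gnorm2, 1e-30))
    accepted <- FALSE
    for (ls in 1:40) {
      A_try <- A - step * g
      fwd_try <- .lddmm_forward(A_try, x0, sigV2, dt)
      E_try <- energy(fwd_try)
      if (is.finite(E_try) && E_try <= E - 1e-4 * step * gnorm2) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    dec <- (E - E_try) / max(abs(E), .Machine$double.eps)
    A <- A_try; fwd <- fwd_try; E <- E_try
    trace <- c(trace, E)
    step <- step * 1.5
    if (dec < cfg$rel_tol) { converged <- TRUE; break }
  }
  if (!is.finite(E)) stop("non-finite energy in LDDMM matching")
  if (!converged)
    warning("LDDMM matching did not converge within ", cfg$max_iters,
            " iterations (relative decrease ", format(cfg$rel_tol), ")")
  D <- .jacobian_along_flow(A, fwd$X, fwd$G, sigV2, dt)
  markers <- D[, 1] * D[, 4] - D[, 2] * D[, 3]
  if (any(markers <= 0))
    stop("non-positive deformation marker; increase n_timesteps or sigma_V")
  jac <- aperm(array(c(D[, 1], D[, 3], D[, 2], D[, 4]),
                     dim = c(K, 2, 2)), c(2, 3, 1))
  structure(list(momenta = A,
                 deformed_template = fwd$X[[Tn + 1]],
                 jacobians = jac,
                 markers = as.numeric(markers),
                 labels = if (inherits(template, "cc_template"))
                   template$labels else NULL,
                 final_energy = E, initial_energy = E0,
                 matching_residual =
                   currents_mismatch(fwd$X[[Tn + 1]], tg, sigma_W),
                 initial_mismatch = M0,
                 sigma_V = sigma_V, sigma_W = sigma_W, lambda = lambda,
                 n_timesteps = Tn, iterations = it,
                 converged = converged, energy_trace = trace),
            class = "cc_registration")
}

#' @export
print.cc_registration <- function(x, ...) {
  cat("<cc_registration> ", length(x$markers), " points, ",
      x$iterations, " iterations, energy ", format(x$final_energy),
      if (x$converged) " (converged)" else " (NOT converged)",
      "\n  markers: ", paste(format(range(x$markers), digits = 4),
                             collapse = " .. "),
      ", mean ", format(mean(x$markers), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Re-derive Jacobians and markers from a completed flow
#'
#' Integrates `dD/dt = (grad v_t)(phi_t(x)) D` with `D(0) = I` alongside
#' the point flow, using the same explicit Euler scheme and timesteps as
#' the matching itself.
#'
#' @param momenta K x 2 x T momenta array (e.g. `$momenta` of a
#'   registration result), or a `cc_registration`.
#' @param template template points the momenta are supported on (ignored
#'   when a full registration result is given).
#' @param cfg the [registration_config()] used (for `sigma_V`); when a
#'   `cc_registration` is given its stored kernel width is used.
#' @return list with `jacobians` (2 x 2 x K), `markers` (length K) and
#'   `trajectory` (list of point sets).
#' @export
propagate_jacobian <- function(momenta, template = NULL, cfg = NULL) {
  if (inherits(momenta, "cc_registration")) {
    if (is.null(template))
      stop("supply the template points used for this registration")
    sigma_V <- momenta$sigma_V
    A <- momenta$momenta
    x0 <- .as_points(template)
  } else {
    A <- momenta
    if (is.null(template)) stop("template points required")
    x0 <- .as_points(template)
    sigma_V <- ((if (!is.null(cfg)) cfg$sigma_V else NULL) %||%
                  (sqrt(sum((apply(x0, 2, max) - apply(x0, 2, min))^2)) / 8))
  }
  sigV2 <- sigma_V^2
  dt <- 1 / dim(A)[3]
  fwd <- .lddmm_forward(A, x0, sigV2, dt)
  D <- .jacobian_along_flow(A, fwd$X, fwd$G, sigV2, dt)
  markers <- D[, 1] * D[, 4] - D[, 2] * D[, 3]
  if (any(markers <= 0))
    stop("non-positive marker; increase n_timesteps or sigma_V")
  jac <- aperm(array(c(D[, 1], D[, 3], D[, 2], D[, 4]),
                     dim = c(nrow(x0), 2, 2)), c(2, 3, 1))
  list(jacobians = jac, markers = as.numeric(markers), trajectory = fwd$X)
}

#' Integrate points and Jacobians through an arbitrary velocity field
#'
#' Generic explicit-Euler integrator used for numerical verification of
#' the Jacobian transport: flows points through a user-supplied
#' (possibly time-varying) velocity field and simultaneously integrates
#' the 2x2 Jacobian `dD/dt = (grad v)(x) D`.
#'
#' @param x0 n x 2 starting points.
#' @param velocity function `(x, t) -> n x 2` velocities.
#' @param velocity_grad function `(x, t) -> list of 2x2` Jacobians of the
#'   field at each row of `x`.
#' @param n_steps Euler steps over `t` in `[t0, t1]`.
#' @param t0,t1 integration interval.
#' @param D0 optional list of initial 2x2 Jacobians (defaults to
#'   identity).
#' @return list with `points` and `jacobians` (list of 2x2 matrices).
#' @export
integrate_flow <- function(x0, velocity, velocity_grad, n_steps = 50,
                           t0 = 0, t1 = 1, D0 = NULL) {
  x <- as.matrix(x0)
  n <- nrow(x)
  D <- D0 %||% replicate(n, diag(2), simplify = FALSE)
  dt <- (t1 - t0) / n_steps
  for (k in seq_len(n_steps)) {
    t <- t0 + (k - 1) * dt
    gr <- velocity_grad(x, t)
    for (i in seq_len(n)) D[[i]] <- D[[i]] + dt * gr[[i]] %*% D[[i]]
    x <- x + dt * velocity(x, t)
  }
  list(points = x, jacobians = D)
}

#' Register every cohort curve to the template
#'
#' For each curve: resample to the template discretization, rigidly align
#' to the template, run the LDDMM matching, and collect the pointwise
#' deformation markers.
#'
#' @param curves named list of `cc_curve` objects.
#' @param template a `cc_template`.
#' @param cfg a [registration_config()].
#' @param rigid logical; disable to skip the rigid prestep.
#' @param workers parallel workers for per-subject registrations.
#' @return a `cc_marker_table`: `markers` (subjects x K matrix), `region`
#'   (template point labels), `areas` (per-subject curve areas, mm^2,
#'   shoelace), `pixel_areas`, `template` metadata and per-subject
#'   `diagnostics`.
#' @export
register_cohort <- function(curves, template, cfg = registration_config(),
                            rigid = TRUE, workers = 1) {
  K <- template$K
  align_one <- function(cv) {
    rs <- resample_closed_curve(cv, K)
    if (rigid) rigid_align(rs$points, template) else
      list(theta = 0, translation = c(0, 0), aligned = rs$points,
           rms = NA_real_, iterations = 0L)
  }
  aligned <- lapply(curves, align_one)
  ## one study-wide matching weight: per-subject normalization would tie
  ## the deformation/matching trade-off (and hence the marker noise) to
  ## each subject's distance from the template
  if (is.null(cfg$lambda_match)) {
    diag_bb <- sqrt(sum((apply(template$points, 2, max) -
                           apply(template$points, 2, min))^2))
    sW <- cfg$sigma_W %||% ((cfg$sigma_V %||% (diag_bb / 8)) / 2)
    M0 <- vapply(aligned, function(al)
      currents_mismatch(template$points, al$aligned, sW), numeric(1))
    M0 <- M0[M0 > 1e-12]
    cfg$lambda_match <- if (length(M0)) K / stats::median(M0) else 1
  }
  one <- function(cv, al) {
    reg <- lddmm_match(template, al$aligned, cfg)
    list(markers = reg$markers,
         area = abs(polygon_signed_area(cv$points)),
         pixel_area = cv$pixel_area_mm2,
         diag = list(subject_id = as.character(cv$subject_id),
                     rigid_theta = al$theta,
                     rigid_translation = al$translation,
                     rigid_rms = al$rms,
                     final_energy = reg$final_energy,
                     matching_residual = reg$matching_residual,
                     iterations = reg$iterations,
                     converged = reg$converged))
  }
  res <- if (workers > 1)
    parallel::mclapply(seq_along(curves),
                       function(i) one(curves[[i]], aligned[[i]]),
                       mc.cores = workers)
  else lapply(seq_along(curves),
              function(i) one(curves[[i]], aligned[[i]]))
  ids <- vapply(curves, function(cv) as.character(cv$subject_id),
                character(1))
  markers <- do.call(rbind, lapply(res, `[[`, "markers"))
  rownames(markers) <- ids
  structure(list(markers = markers,
                 region = template$labels,
                 subject_id = ids,
                 areas = vapply(res, `[[`, numeric(1), "area"),
                 pixel_areas = vapply(res, `[[`, numeric(1), "pixel_area"),
                 template_area_mm2 = template$curve_area_mm2,
                 template_subject = template$subject_id,
                 diagnostics = lapply(res, `[[`, "diag")),
            class = "cc_marker_table")
}

#' @export
print.cc_marker_table <- function(x, ...) {
  cat("<cc_marker_table> ", nrow(x$markers), " subjects x ",
      ncol(x$markers), " template points; mean marker ",
      format(mean(x$markers), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write a cohort marker table as CSV
#'
#' Long dialect `subject_id,point_index,region,marker`.
#' @param mtab a `cc_marker_table`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_marker_table <- function(mtab, path) {
  K <- ncol(mtab$markers)
  df <- data.frame(subject_id = rep(mtab$subject_id, each = K),
                   point_index = rep(seq_len(K), length(mtab$subject_id)),
                   region = rep(mtab$region, length(mtab$subject_id)),
                   marker = as.vector(t(mtab$markers)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  ## areas sidecar keeps the per-subject curve areas with the table
  ap <- paste0(path, ".areas.csv")
  utils::write.csv(data.frame(subject_id = mtab$subject_id,
                              curve_area_mm2 = mtab$areas,
                              pixel_area_mm2 = mtab$pixel_areas,
                              stringsAsFactors = FALSE),
                   ap, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a marker table written by [write_marker_table()]
#' @param path the CSV path.
#' @param template_area_mm2 optional template curve area to attach.
#' @return a `cc_marker_table` (without registration diagnostics).
#' @export
read_marker_table <- function(path, template_area_mm2 = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$subject_id)
  K <- max(df$point_index)
  markers <- matrix(NA_real_, length(ids), K, dimnames = list(ids, NULL))
  for (sid in ids) {
    d <- df[df$subject_id == sid, ]
    markers[sid, d$point_index] <- d$marker
  }
  region <- df$region[df$subject_id == ids[1]][order(df$point_index[df$subject_id == ids[1]])]
  ar <- utils::read.csv(paste0(path, ".areas.csv"), stringsAsFactors = FALSE)
  ar <- ar[match(ids, ar$subject_id), ]
  structure(list(markers = markers, region = region, subject_id = ids,
                 areas = ar$curve_area_mm2, pixel_areas = ar$pixel_area_mm2,
                 template_area_mm2 = template_area_mm2,
                 template_subject = NA_character_, diagnostics = NULL),
            class = "cc_marker_table")
}
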