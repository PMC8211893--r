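# Rigid alignment, currents data term, LDDMM matching and Jacobian
# transport.

## clockwise (y-up) ellipse polygon; the idealized closed curve for
## oracles that assume the outline normal is radial
ellipse_curve <- function(K = 80, a = 25, b = 18) {
  th <- -2 * pi * (seq_len(K) - 1) / K
  cbind(a * cos(th), b * sin(th))
}

test_that("rigid alignment exactly recovers a rigid motion and is identity-stable", {
  tpl <- fixture_template(60)
  moved <- ccmorph:::rotate_points(tpl$points, 10 * pi / 180) +
    matrix(c(3, -2), nrow(tpl$points), 2, byrow = TRUE)
  al <- rigid_align(moved, tpl)
  expect_lt(al$rms, 1e-6)
  expect_lt(max(abs(al$aligned - tpl$points)), 1e-5)

  id <- rigid_align(tpl$points, tpl)
  expect_lt(abs(id$theta %% (2 * pi)), 1e-8)
  expect_lt(max(abs(id$translation)), 1e-8)
})

test_that("rigid alignment leaves the scale residual in place (no scaling removed)", {
  ## near-circular curve: the scale residual equals the radial
  ## displacement, so the analytic prediction 0.2 * mean radius applies
  tpl <- ellipse_curve(60, a = 21, b = 19)
  scaled <- tpl * 1.2
  al <- rigid_align(scaled, tpl)
  d2 <- ccmorph:::pdist2(al$aligned, tpl)
  mnd <- mean(sqrt(apply(d2, 1, min)))
  rbar <- mean(sqrt(rowSums(tpl^2)))
  expect_lt(abs(mnd - 0.2 * rbar) / (0.2 * rbar), 0.25)
})

test_that("currents mismatch matches the direct double-sum oracle and its limits", {
  set.seed(4)
  a <- cbind(cos(2 * pi * (0:19) / 20), sin(2 * pi * (0:19) / 20)) +
    matrix(rnorm(40, 0, 0.03), 20, 2)
  b <- a * 1.3 + 0.2
  sw <- 0.7
  ## brute-force double sum
  ip_oracle <- function(p, q) {
    sp <- ccmorph:::polygon_segments(p); sq <- ccmorph:::polygon_segments(q)
    tot <- 0
    for (i in seq_len(nrow(p))) for (j in seq_len(nrow(q)))
      tot <- tot + exp(-sum((sp$center[i, ] - sq$center[j, ])^2) / sw^2) *
        sum(sp$tangent[i, ] * sq$tangent[j, ])
    tot
  }
  m_oracle <- ip_oracle(a, a) + ip_oracle(b, b) - 2 * ip_oracle(a, b)
  expect_equal(currents_mismatch(a, b, sw), m_oracle, tolerance = 1e-10)
  expect_equal(currents_mismatch(a, b, sw), currents_mismatch(b, a, sw),
               tolerance = 1e-12)
  ## identical curves: zero
  expect_lt(abs(currents_mismatch(a, a, sw)), 1e-12)
  ## reversed orientation: tangents negate, mismatch = 4 ||[a]||^2
  expect_equal(currents_mismatch(a, a[nrow(a):1, ], sw),
               4 * ip_oracle(a, a), tolerance = 1e-8)
  ## far-separated curves: cross kernel vanishes
  far <- b + 100
  expect_equal(currents_mismatch(a, far, sw),
               ip_oracle(a, a) + ip_oracle(far, far), tolerance = 1e-6)
})

test_that("the analytic energy gradient matches finite differences", {
  set.seed(7)
  K <- 12; Tn <- 5
  x0 <- cbind(10 * cos(2 * pi * (0:(K - 1)) / K),
              10 * sin(2 * pi * (0:(K - 1)) / K))
  tgt <- x0 * 1.15 + matrix(rnorm(2 * K, 0, 0.1), K, 2)
  sigV2 <- 25; sw <- 2.5; lambda <- 3
  A <- array(rnorm(K * 2 * Tn, 0, 0.05), dim = c(K, 2, Tn))
  dt <- 1 / Tn
  repr_b <- ccmorph:::.currents_repr(tgt)
  energy <- function(Aa) {
    fwd <- ccmorph:::.lddmm_forward(Aa, x0, sigV2, dt)
    fwd$Ereg + lambda * currents_mismatch(fwd$X[[Tn + 1]], tgt, sw)
  }
  fwd <- ccmorph:::.lddmm_forward(A, x0, sigV2, dt)
  g <- ccmorph:::.lddmm_gradient(A, fwd, repr_b, sigV2, sw, lambda, dt)
  h <- 1e-6
  for (probe in list(c(1, 1, 1), c(5, 2, 3), c(12, 1, 5), c(7, 2, 2))) {
    Ap <- A; Ap[probe[1], probe[2], probe[3]] <- Ap[probe[1], probe[2], probe[3]] + h
    Am <- A; Am[probe[1], probe[2], probe[3]] <- Am[probe[1], probe[2], probe[3]] - h
    fd <- (energy(Ap) - energy(Am)) / (2 * h)
    expect_equal(g[probe[1], probe[2], probe[3]], fd, tolerance = 1e-4)
  }
})

test_that("matching the template to itself returns unit markers immediately", {
  tpl <- fixture_template(60)
  reg <- lddmm_match(tpl, tpl$points)
  expect_true(reg$converged)
  expect_true(all(abs(reg$markers - 1) < 1e-8))
  expect_lte(reg$final_energy, reg$initial_energy)
})

test_that("zero momenta give identity Jacobians and unit markers", {
  tpl <- fixture_template(60)
  A <- array(0, dim = c(60, 2, 10))
  pj <- propagate_jacobian(A, tpl)
  expect_true(all(abs(pj$markers - 1) < 1e-14))
  expect_equal(pj$jacobians[, , 7], diag(2))
})

test_that("a localized inward dent produces a sub-unit marker at the dent location", {
  ## simple convex curve: no second boundary sheet nearby, so the
  ## marker minimum must sit on the dented arc itself
  pts <- ellipse_curve(80)
  u <- ccmorph:::polygon_arc_positions(pts) /
    ccmorph:::polygon_perimeter(pts)
  center <- 0.3
  w <- ccmorph:::effect_window(u, c(center - 0.05, center + 0.05))
  nrm <- ccmorph:::outline_outward_normals(pts)
  tgt <- pts - 1.5 * w * nrm
  reg <- suppressWarnings(
    lddmm_match(pts, tgt, registration_config(max_iters = 150,
                                              rel_tol = 1e-6)))
  kmin <- which.min(reg$markers)
  expect_lt(reg$markers[kmin], 1)
  per <- ccmorph:::polygon_perimeter(pts)
  expect_lte(ccmorph:::cyclic_frac_dist(u[kmin], center),
             reg$sigma_V / per)
  ## energy is non-increasing across accepted steps
  expect_true(all(diff(reg$energy_trace) <= 1e-12))
})

test_that("within the corpus-callosum band a genu dent also registers on the facing boundary", {
  ## the band is thinner than sigma_V, so an outer-genu dent compresses
  ## the facing inner boundary as well: markers drop inside the window
  ## and the global minimum stays Euclidean-close to the dent
  tpl <- fixture_template(80)
  u <- template_arc_fracs(tpl)
  gidx <- which(tpl$labels == "gCC")
  center <- u[gidx[round(length(gidx) / 2)]]
  w <- ccmorph:::effect_window(u, c((center - 0.05) %% 1,
                                    (center + 0.05) %% 1))
  nrm <- ccmorph:::outline_outward_normals(tpl$points)
  tgt <- tpl$points - 1.5 * w * nrm
  reg <- suppressWarnings(
    lddmm_match(tpl, tgt, registration_config(max_iters = 150,
                                              rel_tol = 1e-6)))
  expect_true(all(reg$markers[w > 0.5] < 1))
  kmin <- which.min(reg$markers)
  cpt <- tpl$points[which.min(ccmorph:::cyclic_frac_dist(u, center)), ]
  expect_lte(sqrt(sum((tpl$points[kmin, ] - cpt)^2)), reg$sigma_V)
})

test_that("Jacobian transport obeys the cocycle property over split flows", {
  tpl <- fixture_template(40)
  set.seed(9)
  K <- 40; Tn <- 10
  A <- array(rnorm(K * 2 * Tn, 0, 0.08), dim = c(K, 2, Tn))
  sigma_V <- sqrt(sum((apply(tpl$points, 2, max) -
                         apply(tpl$points, 2, min))^2)) / 8
  sigV2 <- sigma_V^2
  dt <- 1 / Tn
  fwd <- ccmorph:::.lddmm_forward(A, tpl$points, sigV2, dt)
  D_full <- ccmorph:::.jacobian_along_flow(A, fwd$X, fwd$G, sigV2, dt)

  ## same step sequence split in two: D = D_second %*% D_first
  A1 <- A[, , 1:5, drop = FALSE]
  A2 <- A[, , 6:10, drop = FALSE]
  f1 <- ccmorph:::.lddmm_forward(A1, tpl$points, sigV2, dt)
  D1 <- ccmorph:::.jacobian_along_flow(A1, f1$X, f1$G, sigV2, dt)
  x_mid <- f1$X[[6]]
  f2 <- ccmorph:::.lddmm_forward(A2, x_mid, sigV2, dt)
  D2 <- ccmorph:::.jacobian_along_flow(A2, f2$X, f2$G, sigV2, dt)
  comp <- cbind(D2[, 1] * D1[, 1] + D2[, 2] * D1[, 3],
                D2[, 1] * D1[, 2] + D2[, 2] * D1[, 4],
                D2[, 3] * D1[, 1] + D2[, 4] * D1[, 3],
                D2[, 3] * D1[, 2] + D2[, 4] * D1[, 4])
  expect_lt(max(abs(comp - D_full)), 1e-6)
  ## endpoint of the composed flow matches too
  expect_lt(max(abs(f2$X[[6]] - fwd$X[[11]])), 1e-10)
})

test_that("markers agree with a brute-force tiny-square area-ratio oracle", {
  tpl <- fixture_template(40)
  u <- template_arc_fracs(tpl)
  w <- ccmorph:::effect_window(u, c(0.35, 0.5))
  tgt <- tpl$points - 1.5 * w * ccmorph:::outline_outward_normals(tpl$points)
  reg <- suppressWarnings(
    lddmm_match(tpl, tgt, registration_config(max_iters = 80,
                                              rel_tol = 1e-5)))
  ## re-run the flow to recover control-point trajectories, then flow a
  ## tiny square at selected template points through the same velocity
  sigV2 <- reg$sigma_V^2
  Tn <- reg$n_timesteps
  dt <- 1 / Tn
  fwd <- ccmorph:::.lddmm_forward(reg$momenta, tpl$points, sigV2, dt)
  eps <- 1e-3
  for (k in c(5, which.min(reg$markers), 30)) {
    sq <- rbind(tpl$points[k, ] + c(-eps, -eps),
                tpl$points[k, ] + c(eps, -eps),
                tpl$points[k, ] + c(eps, eps),
                tpl$points[k, ] + c(-eps, eps))
    for (t in seq_len(Tn)) {
      G <- exp(-ccmorph:::pdist2(sq, fwd$X[[t]]) / sigV2)
      sq <- sq + dt * G %*% reg$momenta[, , t]
    }
    ratio <- abs(ccmorph:::polygon_signed_area(sq)) / (2 * eps)^2
    expect_lt(abs(ratio - reg$markers[k]) / reg$markers[k], 0.02)
  }
})

test_that("energy, flow and markers are equivariant under a common rotation", {
  tpl <- fixture_template(40)
  set.seed(15)
  A <- array(rnorm(40 * 2 * 10, 0, 0.1), dim = c(40, 2, 10))
  R <- ccmorph:::rot2(0.6)
  A_rot <- A
  for (t in 1:10) A_rot[, , t] <- A[, , t] %*% t(R)
  ## markers of the transported Jacobian are rotation-invariant (the
  ## kernel width is pinned: the bounding-box default is axis-aligned)
  cfgV <- registration_config(sigma_V = 7)
  pj1 <- propagate_jacobian(A, tpl, cfgV)
  pj2 <- propagate_jacobian(A_rot, tpl$points %*% t(R), cfgV)
  expect_lt(max(abs(pj1$markers - pj2$markers)), 1e-9)
  ## energy of the matching problem is rotation-invariant
  u <- template_arc_fracs(tpl)
  w <- ccmorph:::effect_window(u, c(0.3, 0.45))
  tgt <- tpl$points - 1.2 * w * ccmorph:::outline_outward_normals(tpl$points)
  sigV2 <- 30; sw <- 3; dt <- 0.1
  f1 <- ccmorph:::.lddmm_forward(A, tpl$points, sigV2, dt)
  f2 <- ccmorph:::.lddmm_forward(A_rot, tpl$points %*% t(R), sigV2, dt)
  e1 <- f1$Ereg + currents_mismatch(f1$X[[11]], tgt, sw)
  e2 <- f2$Ereg + currents_mismatch(f2$X[[11]], tgt %*% t(R), sw)
  expect_equal(e1, e2, tolerance = 1e-10)

  ## end-to-end registrations agree up to optimizer path noise
  cfg <- registration_config(max_iters = 60, rel_tol = 1e-5)
  reg1 <- suppressWarnings(lddmm_match(tpl, tgt, cfg))
  tpl_rot <- tpl
  tpl_rot$points <- tpl$points %*% t(R)
  reg2 <- suppressWarnings(lddmm_match(tpl_rot, tgt %*% t(R), cfg))
  expect_lt(max(abs(reg1$markers - reg2$markers)), 0.05)
})
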