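# Pointwise GLM, Freedman-Lane permutation inference, Westfall-Young
# FWER, interaction testing, Cohen's d, area analysis.

toy_cov <- function(n, groups = NULL, genders = NULL, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("T%02d", seq_len(n)),
             group = groups %||% rep(c("FES", "HC"), length.out = n),
             gender = genders %||% rep(c("F", "M", "M", "F"),
                                       length.out = n),
             age = round(runif(n, 18, 40), 1),
             tiv = round(rnorm(n, 1.4e6, 1e5)),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("an exactly linear group effect is recovered with zero residuals", {
  cov <- toy_cov(10)
  des <- make_design(cov, covariate_cols = character(0))
  gamma <- des$X[, "group"]
  Y <- matrix(2, 10, 4) + 0.5 * gamma
  fit <- fit_pointwise_glm(Y, des)
  expect_equal(unname(fit$beta1), rep(0.5, 4), tolerance = 1e-12)
  expect_lt(max(abs(fit$residuals)), 1e-12)
})

test_that("pointwise OLS matches the normal-equations oracle", {
  cov <- toy_cov(8, seed = 3)
  des <- make_design(cov)
  set.seed(5)
  Y <- matrix(rnorm(8 * 6), 8, 6)
  rownames(Y) <- des$covariates$subject_id
  fit <- fit_pointwise_glm(Y, des)
  X <- des$X
  oracle <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_lt(max(abs(fit$beta - oracle)), 1e-10)
  ## t statistic against R's lm
  lmfit <- summary(stats::lm(Y[, 1] ~ 0 + X))
  expect_equal(unname(fit$t[1]),
               unname(lmfit$coefficients["Xgroup", "t value"]),
               tolerance = 1e-10)
})

test_that("degenerate designs are rejected with the offending columns named", {
  cov <- toy_cov(8)
  cov$group <- "HC"
  expect_error(make_design(cov), "collinear.*group")
  cov2 <- toy_cov(8)
  cov2$age <- 7  # constant column collides with the intercept
  expect_error(make_design(cov2), "collinear")
})

test_that("exhaustive permutation p equals the explicit group-assignment enumeration", {
  set.seed(11)
  cov <- toy_cov(6, groups = rep(c("FES", "HC"), each = 3))
  Y <- matrix(rnorm(6 * 3), 6, 3)
  rownames(Y) <- cov$subject_id
  des <- make_design(cov, covariate_cols = character(0))
  pi <- suppressMessages(permutation_inference(Y, des, n_perm = 10000,
                                               seed = 1))
  expect_true(pi$exhaustive)
  ## oracle: all 20 assignments of 3 subjects to FES, two-sample t
  Yc <- Y[match(des$covariates$subject_id, rownames(Y)), , drop = FALSE]
  combs <- utils::combn(6, 3)
  p_oracle <- sapply(seq_len(ncol(Yc)), function(k) {
    tt <- apply(combs, 2, function(ix) {
      abs(stats::t.test(Yc[ix, k], Yc[-ix, k], var.equal = TRUE)$statistic)
    })
    obs <- abs(stats::t.test(Yc[des$X[, "group"] == 1, k],
                             Yc[des$X[, "group"] == 0, k],
                             var.equal = TRUE)$statistic)
    mean(tt >= obs - 1e-12)
  })
  expect_equal(unname(pi$p_raw), p_oracle, tolerance = 1e-12)
})

test_that("Monte-Carlo p-values sit within 3 standard errors of the exhaustive p", {
  for (tc in list(list(n = 6, n1 = 3, seed = 2),
                    list(n = 8, n1 = 4, seed = 4))) {
    set.seed(tc$seed)
    cov <- toy_cov(tc$n, groups = rep(c("FES", "HC"),
                                        c(tc$n1, tc$n - tc$n1)))
    Y <- matrix(rnorm(tc$n * 2), tc$n, 2) +
      0.8 * (cov$group == "FES")
    rownames(Y) <- cov$subject_id
    des <- make_design(cov, covariate_cols = character(0))
    ex <- suppressMessages(permutation_inference(Y, des,
                                                 n_perm = 50000, seed = 1))
    expect_true(ex$exhaustive)
    mc_n <- 500
    mc <- permutation_inference(Y, des, n_perm = mc_n, seed = 99)
    expect_false(mc$exhaustive)
    se <- sqrt(ex$p_raw * (1 - ex$p_raw) / mc_n)
    expect_true(all(abs(mc$p_raw - ex$p_raw) <= 3 * se + 2 / mc_n))
  }
})

test_that("add-one p-values are bounded away from zero and FWER dominates raw", {
  set.seed(21)
  cov <- toy_cov(20)
  Y <- matrix(rnorm(20 * 15), 20, 15)
  rownames(Y) <- cov$subject_id
  des <- make_design(cov)
  pi <- permutation_inference(Y, des, n_perm = 200, seed = 7)
  expect_true(all(pi$p_raw >= 1 / 201))
  expect_true(all(pi$p_raw <= 1))
  expect_true(all(pi$p_fwer >= pi$p_raw - 1e-15))
  ## single-step max-statistic identity: omnibus p = min corrected p
  expect_equal(pi$omnibus_p, min(pi$p_fwer), tolerance = 1e-15)
})

test_that("permutation p-values are invariant to the order subjects arrive in", {
  set.seed(31)
  cov <- toy_cov(16)
  Y <- matrix(rnorm(16 * 8), 16, 8)
  rownames(Y) <- cov$subject_id
  p1 <- permutation_inference(Y, make_design(cov), n_perm = 300, seed = 5)
  shuf <- sample(16)
  p2 <- permutation_inference(Y[shuf, ], make_design(cov[shuf, ]),
                              n_perm = 300, seed = 5)
  expect_identical(p1$p_raw, p2$p_raw)
  expect_identical(p1$omnibus_p, p2$omnibus_p)
})

test_that("Cohen's d matches the pooled-SD closed form and rejects degenerate input", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), 1, tolerance = 1e-12)
  expect_equal(cohens_d(c(5, 6, 7, 8), c(5, 6, 7, 8)), 0)
  expect_error(cohens_d(c(0, 0), c(0, 0)), "pooled")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
  ## hand-computed asymmetric case: means 10, 12; pooled sd over
  ## (n-1)-weighted variances
  a <- c(8, 10, 12); b <- c(11, 12, 13)
  sp <- sqrt(((2) * stats::var(a) + (2) * stats::var(b)) / 4)
  expect_equal(cohens_d(a, b), abs(mean(a) - mean(b)) / sp,
               tolerance = 1e-12)
})

test_that("the interaction test needs full cells and is centered under symmetric effects", {
  cov <- toy_cov(12)
  cov$gender[cov$group == "FES"] <- "F"  # empty FES-male cell
  Y <- matrix(rnorm(12 * 2), 12, 2)
  rownames(Y) <- cov$subject_id
  expect_error(interaction_test(Y, cov, n_perm = 100, seed = 1),
               "cells")

  ## identical effect in both genders: interaction coefficient centered 0
  betas <- vapply(1:30, function(i) {
    cv <- toy_cov(24, seed = 100 + i)
    set.seed(200 + i)
    y <- matrix(rnorm(24), 24, 1) + 0.6 * (cv$group == "FES")
    rownames(y) <- cv$subject_id
    fit <- fit_pointwise_glm(y, make_design(cv, interaction = TRUE))
    unname(fit$beta1)
  }, numeric(1))
  expect_gt(stats::t.test(betas)$p.value, 0.001)
})

test_that("the interaction test detects a female-only effect (power simulation)", {
  hits <- vapply(1:20, function(i) {
    cv <- toy_cov(100, groups = rep(c("FES", "HC"), each = 50),
                  genders = rep(rep(c("F", "M"), each = 25), 2),
                  seed = 300 + i)
    set.seed(400 + i)
    eff <- 0.25 * (cv$group == "FES" & cv$gender == "F")
    Y <- matrix(rnorm(100 * 5, sd = 0.15), 100, 5) - outer(eff, rep(1, 5))
    rownames(Y) <- cv$subject_id
    it <- interaction_test(Y, cv, n_perm = 300, seed = 500 + i)
    it$omnibus_p <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("area analysis reports the FES minus HC adjusted difference with its sign", {
  cv <- toy_cov(24, seed = 9)
  set.seed(10)
  base_area <- 700 + 50 * scale(cv$tiv)[, 1]
  areas <- data.frame(subject_id = cv$subject_id,
                      CC = base_area - 30 * (cv$group == "FES") + rnorm(24, 0, 5),
                      gCC = 190 - 20 * (cv$group == "FES") + rnorm(24, 0, 4),
                      bCC = 290 + rnorm(24, 0, 4),
                      sCC = 215 + rnorm(24, 0, 4),
                      stringsAsFactors = FALSE)
  res <- area_group_analysis(areas, cv, scope = "all", n_perm = 300,
                             seed = 2)
  expect_identical(res$structure, c("CC", "gCC", "bCC", "sCC"))
  expect_lt(res$group_difference[res$structure == "CC"], 0)
  expect_lt(res$group_difference[res$structure == "gCC"], 0)
  expect_lt(res$p[res$structure == "gCC"], 0.05)
  expect_gt(res$p[res$structure == "bCC"], 0.05)
})

test_that("null p-values are uniform across replicates (KS calibration)", {
  ps <- matrix(NA_real_, 200, 4)
  for (i in 1:200) {
    cv <- toy_cov(20, seed = 600 + i)
    set.seed(700 + i)
    areas <- data.frame(subject_id = cv$subject_id,
                        CC = rnorm(20, 700, 40), gCC = rnorm(20, 190, 15),
                        bCC = rnorm(20, 290, 20), sCC = rnorm(20, 215, 18),
                        stringsAsFactors = FALSE)
    res <- area_group_analysis(areas, cv, scope = "all", n_perm = 400,
                               seed = 800 + i)
    ps[i, ] <- res$p
  }
  for (k in 1:4)
    expect_gt(suppressWarnings(stats::ks.test(ps[, k], "punif"))$p.value,
              0.01)
})

test_that("genu-localized effects rank the genu area p below the other sub-regions", {
  wins <- vapply(1:20, function(i) {
    co <- generate_cohort(synthetic_config(n_per_cell = 8,
                                           effect_gender_ratio = 1,
                                           seed = 900 + i))
    a <- cohort_areas(co)
    res <- area_group_analysis(a, co$covariates, scope = "all",
                               n_perm = 200, seed = 950 + i)
    p <- stats::setNames(res$p, res$structure)
    p[["gCC"]] < p[["bCC"]] && p[["gCC"]] < p[["sCC"]]
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("summaries of significant points handle empty and uniform cases", {
  st <- structure(list(p_fwer = rep(0.5, 10), cohens_d = rep(0.3, 10),
                       region = rep("gCC", 10)),
                  class = "cc_pointwise_stats")
  s <- summarize_significant(st)
  expect_identical(s$n_significant, 0L)
  expect_true(is.na(s$mean_d))
  st$p_fwer <- rep(0.01, 10)
  st$cohens_d <- rep(0.5, 10)
  s2 <- summarize_significant(st)
  expect_identical(s2$n_significant, 10L)
  expect_equal(s2$mean_d, 0.5)
  expect_equal(s2$sd_d, 0)
  expect_identical(length(s2$clusters), 1L)
})
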