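#' Build the covariate-adjusted design matrix
#'
#' Columns: intercept, the FES group indicator `gamma` (1 = FES, 0 = HC),
#' and scope-appropriate covariates — age, gender and TIV for the full
#' cohort, age and TIV within a single gender. With `interaction = TRUE`
#' (full scope only) gender and group enter as main factors together with
#' their product column.
#'
#' @param covariates data frame with `subject_id, group, gender, age, tiv`.
#' @param scope `"all"`, `"female"` or `"male"`.
#' @param interaction include the gender-by-group product column.
#' @param covariate_cols nuisance covariates to adjust for; defaults to
#'   age, gender and TIV in the full cohort and age and TIV within a
#'   single gender. Use `character(0)` for an unadjusted comparison.
#' @return a `cc_design`: list with `X` (model matrix), `test_col` (the
#'   tested coefficient), `covariates` (the scoped, canonically ordered
#'   rows) and `scope`.
#' @export
make_design <- function(covariates, scope = c("all", "female", "male"),
                        interaction = FALSE, covariate_cols = NULL) {
  scope <- match.arg(scope)
  cov <- covariates
  if (scope != "all") {
    g <- if (scope == "female") "F" else "M"
    cov <- cov[cov$gender == g, , drop = FALSE]
    if (!nrow(cov)) stop("no subjects of gender ", g, " in the cohort")
  }
  ## canonical subject order: permutation p-values must not depend on the
  ## order rows arrive in
  cov <- cov[order(cov$subject_id), , drop = FALSE]
  gamma <- as.numeric(cov$group == "FES")
  ## standardize continuous nuisance covariates: a full-rank linear
  ## reparameterization that leaves the tested coefficient and the
  ## permutation p-values unchanged but keeps the normal equations
  ## well-conditioned (TIV is of order 1e6)
  zs <- function(v) {
    s <- stats::sd(v)
    if (is.finite(s) && s > 0) (v - mean(v)) / s else v - mean(v)
  }
  if (interaction) {
    if (scope != "all") stop("interaction model requires the full cohort")
    cells <- table(cov$group, cov$gender)
    if (any(cells == 0) || !all(dim(cells) == c(2, 2)))
      stop("all four gender x group cells must be nonempty for the ",
           "interaction model")
    gender <- as.numeric(cov$gender == "F")
    X <- cbind(intercept = 1, gender = gender, group = gamma,
               gender_x_group = gender * gamma,
               age = zs(cov$age), tiv = zs(cov$tiv))
    test_col <- "gender_x_group"
  } else {
    if (is.null(covariate_cols))
      covariate_cols <- if (scope == "all") c("age", "gender", "tiv") else
        c("age", "tiv")
    X <- cbind(intercept = 1, group = gamma)
    for (cc in covariate_cols) {
      v <- if (cc == "gender") as.numeric(cov$gender == "F") else
        zs(cov[[cc]])
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- cc
    }
    test_col <- "group"
  }
  if (!all(is.finite(X))) stop("non-finite covariate values in design")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  structure(list(X = X, test_col = test_col, covariates = cov,
                 scope = scope), class = "cc_design")
}

#' Pointwise ordinary least squares on deformation markers
#'
#' Fits `J_k = beta_0 + beta_1 gamma + sum_cov alpha_cov X_cov + eps_k`
#' at every template point simultaneously and returns the tested
#' coefficient, its t statistic and the residuals (retained for
#' permutation inference).
#'
#' @param Y n x K response matrix (markers) or a `cc_marker_table`.
#' @param design a `cc_design`; rows must correspond to `Y` subjects.
#' @return list with `beta` (p x K), `beta1`, `t`, `se`, `residuals`,
#'   `sigma2`, `df`.
#' @export
fit_pointwise_glm <- function(Y, design) {
  Y <- .marker_matrix(Y, design)
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2) stop("too few subjects for the design (n <= rank + 2)")
  XtXi <- solve(crossprod(X))
  PX <- XtXi %*% t(X)
  beta <- PX %*% Y
  fitted <- X %*% beta
  res <- Y - fitted
  df <- n - p
  sigma2 <- colSums(res^2) / df
  j <- match(design$test_col, colnames(X))
  se <- sqrt(sigma2 * XtXi[j, j])
  tstat <- beta[j, ] / se
  list(beta = beta, beta1 = beta[j, ], t = tstat, se = se,
       residuals = res, sigma2 = sigma2, df = df)
}

## align a marker matrix (or cc_marker_table) to the design's canonical
## subject order
.marker_matrix <- function(Y, design) {
  if (inherits(Y, "cc_marker_table")) {
    idx <- match(design$covariates$subject_id, Y$subject_id)
    if (anyNA(idx)) stop("marker table is missing subjects in the design")
    Y <- Y$markers[idx, , drop = FALSE]
  } else {
    Y <- as.matrix(Y)
    if (!is.null(rownames(Y))) {
      idx <- match(design$covariates$subject_id, rownames(Y))
      if (!anyNA(idx)) Y <- Y[idx, , drop = FALSE]
    }
  }
  if (nrow(Y) != nrow(design$X))
    stop("response rows do not match design rows")
  Y
}

## all permutations of 1..n (n small), as an n! x n matrix
.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(rep(k, nrow(sub)), sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Permutation inference with max-statistic FWER control
#'
#' Freedman-Lane scheme: the reduced model (all design columns except the
#' tested one) is fitted, its residual rows are permuted and added back
#' to the reduced fit, the full model is refitted on each reconstructed
#' response, and the resulting null t statistics are collected. Raw
#' p-values use the add-one estimator `(1 + b) / (1 + m)`; family-wise
#' corrected p-values use the single-step Westfall-Young max-|t|
#' distribution, whose exceedance at the observed max-|t| is also the
#' omnibus p for the overall shape difference (so `omnibus_p` equals the
#' minimum corrected p-value by construction). When `n!` does not exceed
#' `n_perm` the scheme switches to exhaustive enumeration of all row
#' permutations and p-values become exact proportions.
#'
#' @param Y n x K response matrix or `cc_marker_table`.
#' @param design a `cc_design`.
#' @param n_perm Monte Carlo permutations (>= 100).
#' @param seed RNG seed for the permutation stream.
#' @return a list with `p_raw`, `p_fwer`, `omnibus_p`, `t_obs`, `beta1`,
#'   `max_t_null`, `n_permutations`, `exhaustive`, `seed`.
#' @export
permutation_inference <- function(Y, design, n_perm = 10000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  Y <- .marker_matrix(Y, design)
  X <- design$X
  n <- nrow(X)
  j <- match(design$test_col, colnames(X))
  obs <- fit_pointwise_glm(Y, design)
  ## reduced model: everything but the tested column
  Z <- X[, -j, drop = FALSE]
  HZ <- Z %*% solve(crossprod(Z)) %*% t(Z)
  fit_z <- HZ %*% Y
  res_z <- Y - fit_z

  exhaustive <- factorial(n) <= n_perm
  if (exhaustive) {
    message("n_perm = ", n_perm, " exceeds the ", factorial(n),
            " distinct permutations of ", n,
            " subjects; using exhaustive enumeration")
    perms <- .all_permutations(n)
  } else {
    set.seed(as.integer(seed %% .Machine$integer.max))
    perms <- t(vapply(seq_len(n_perm), function(i) sample.int(n),
                      integer(n)))
  }
  m <- nrow(perms)
  XtXi <- solve(crossprod(X))
  PX <- XtXi %*% t(X)
  ctt <- XtXi[j, j]
  p <- ncol(X)
  df <- n - p
  t_obs <- obs$t
  abs_t <- abs(t_obs)
  ## tie guard: the identity permutation reproduces the observed t up to
  ## floating-point noise and must count as an exceedance
  ge <- function(x, y) x >= y - 1e-8 * (y + 1)
  count_raw <- numeric(length(t_obs))
  max_null <- numeric(m)
  for (b in seq_len(m)) {
    Yp <- fit_z + res_z[perms[b, ], , drop = FALSE]
    Bp <- PX %*% Yp
    rss <- colSums(Yp^2) - colSums(Bp * (crossprod(X, Yp)))
    rss[rss < 0] <- 0
    tp <- abs(Bp[j, ]) / sqrt(pmax(rss / df, 1e-300) * ctt)
    count_raw <- count_raw + ge(tp, abs_t)
    max_null[b] <- max(tp)
  }
  if (exhaustive) {
    p_raw <- count_raw / m
    p_fwer <- vapply(abs_t, function(a) mean(ge(max_null, a)), numeric(1))
    omnibus <- mean(ge(max_null, max(abs_t)))
  } else {
    p_raw <- (1 + count_raw) / (1 + m)
    p_fwer <- vapply(abs_t, function(a) (1 + sum(ge(max_null, a))) / (1 + m),
                     numeric(1))
    omnibus <- (1 + sum(ge(max_null, max(abs_t)))) / (1 + m)
  }
  list(p_raw = p_raw, p_fwer = p_fwer, omnibus_p = omnibus,
       t_obs = t_obs, beta1 = obs$beta1, max_t_null = max_null,
       n_permutations = m, exhaustive = exhaustive, seed = seed)
}

#' Cohen's d (pooled standard deviation)
#'
#' `|mean(a) - mean(b)| / s_pooled` with the usual `(n - 1)`-weighted
#' pooled standard deviation. Roughly: 0.2 small, 0.5 medium, 0.8 large.
#'
#' @param group_a,group_b numeric vectors (each length >= 2).
#' @return nonnegative scalar.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation; d undefined")
  abs(mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Gender-by-group interaction test
#'
#' Permutation test of the gender-by-group product coefficient in the
#' model with both main factors plus age and TIV, using the same
#' Freedman-Lane machinery (reduced model = main effects + covariates).
#' For a multi-column response the pointwise p-values come with a
#' max-statistic corrected set and an omnibus interaction p.
#'
#' @param Y response: n x K marker matrix, `cc_marker_table`, or a
#'   single column (e.g. areas).
#' @param covariates cohort covariate data frame.
#' @param n_perm,seed as in [permutation_inference()].
#' @return list with `p` (pointwise raw), `p_fwer`, `omnibus_p`, `beta`
#'   (the interaction coefficient per point) and the design used.
#' @export
interaction_test <- function(Y, covariates, n_perm = 10000, seed = 1) {
  design <- make_design(covariates, scope = "all", interaction = TRUE)
  pi <- permutation_inference(Y, design, n_perm = n_perm, seed = seed)
  list(p = pi$p_raw, p_fwer = pi$p_fwer, omnibus_p = pi$omnibus_p,
       beta = pi$beta1, t = pi$t_obs, design = design,
       n_permutations = pi$n_permutations)
}

#' Pointwise covariate-adjusted shape comparison
#'
#' The full pointwise analysis for one scope: OLS fit of the group
#' coefficient at every template point, Freedman-Lane permutation
#' p-values, Westfall-Young FWER correction, omnibus shape p, and raw
#' (unadjusted) Cohen's d per point. The reported `effect` is
#' `-beta_1`, so a positive value means inward deformation in the
#' patient group.
#'
#' @param mtab a `cc_marker_table` (or n x K matrix with subject ids as
#'   row names).
#' @param covariates cohort covariate data frame.
#' @param scope `"all"`, `"female"` or `"male"`.
#' @param n_perm,seed permutation settings.
#' @return a `cc_pointwise_stats` with per-point `beta1`, `effect`, `t`,
#'   `p_raw`, `p_fwer`, `cohens_d`, `region`, plus `omnibus_p` and
#'   bookkeeping fields.
#' @export
pointwise_shape_analysis <- function(mtab, covariates,
                                     scope = c("all", "female", "male"),
                                     n_perm = 10000, seed = 1) {
  scope <- match.arg(scope)
  design <- make_design(covariates, scope = scope)
  Y <- .marker_matrix(mtab, design)
  pi <- permutation_inference(Y, design, n_perm = n_perm, seed = seed)
  grp <- design$covariates$group
  d <- vapply(seq_len(ncol(Y)), function(k) {
    cohens_d(Y[grp == "FES", k], Y[grp == "HC", k])
  }, numeric(1))
  region <- if (inherits(mtab, "cc_marker_table")) mtab$region else
    rep(NA_character_, ncol(Y))
  structure(list(beta1 = pi$beta1, effect = -pi$beta1, t = pi$t_obs,
                 p_raw = pi$p_raw, p_fwer = pi$p_fwer, cohens_d = d,
                 region = region, omnibus_p = pi$omnibus_p,
                 scope = scope, n_permutations = pi$n_permutations,
                 exhaustive = pi$exhaustive, seed = seed,
                 n_subjects = nrow(Y)),
            class = "cc_pointwise_stats")
}

#' @export
print.cc_pointwise_stats <- function(x, ...) {
  nsig <- sum(x$p_fwer <= 0.05)
  cat("<cc_pointwise_stats> scope ", x$scope, ": ", length(x$t),
      " points, ", x$n_subjects, " subjects, ", x$n_permutations,
      " permutations\n  omnibus p = ", format(x$omnibus_p, digits = 4),
      "; ", nsig, " points with FWER p <= 0.05\n", sep = "")
  invisible(x)
}

#' Covariate-adjusted group comparison of regional areas
#'
#' One linear model + permutation test per structure (CC, gCC, bCC,
#' sCC): the adjusted FES - HC difference (the group coefficient),
#' its permutation p-value, and raw Cohen's d, per analysis scope.
#' No correction is applied across the four structures (each is
#' reported per structure).
#'
#' @param areas data frame with columns `subject_id, CC, gCC, bCC, sCC`
#'   (mm^2), e.g. from [region_areas()] per subject.
#' @param covariates cohort covariate data frame.
#' @param scope `"all"`, `"female"` or `"male"`.
#' @param n_perm,seed permutation settings.
#' @return data frame with one row per structure: group means and SDs,
#'   permutation `p`, `cohens_d`, and `group_difference` (adjusted,
#'   FES - HC, mm^2).
#' @export
area_group_analysis <- function(areas, covariates,
                                scope = c("all", "female", "male"),
                                n_perm = 10000, seed = 1) {
  scope <- match.arg(scope)
  design <- make_design(covariates, scope = scope)
  ids <- design$covariates$subject_id
  idx <- match(ids, areas$subject_id)
  if (anyNA(idx)) stop("areas table is missing subjects")
  structures <- c("CC", "gCC", "bCC", "sCC")
  Y <- as.matrix(areas[idx, structures])
  pi <- permutation_inference(Y, design, n_perm = n_perm, seed = seed)
  grp <- design$covariates$group
  d <- vapply(structures, function(s) {
    cohens_d(Y[grp == "FES", s], Y[grp == "HC", s])
  }, numeric(1))
  data.frame(structure = structures,
             hc_mean = colMeans(Y[grp == "HC", , drop = FALSE]),
             hc_sd = apply(Y[grp == "HC", , drop = FALSE], 2, stats::sd),
             fes_mean = colMeans(Y[grp == "FES", , drop = FALSE]),
             fes_sd = apply(Y[grp == "FES", , drop = FALSE], 2, stats::sd),
             p = pi$p_raw,
             cohens_d = unname(d),
             group_difference = pi$beta1,
             scope = scope,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize significant template points
#'
#' Points with FWER-corrected p at or below `alpha`, their per-region
#' counts, the mean and SD of Cohen's d over the significant set, and
#' the cyclic arc clusters they form.
#'
#' @param stats a `cc_pointwise_stats`.
#' @param alpha significance level (default 0.05).
#' @return list with `significant` (indices), `n_significant`,
#'   `region_counts`, `mean_d`, `sd_d` (both `NA` when the set is
#'   empty) and `clusters` (list of cyclic index runs).
#' @export
summarize_significant <- function(stats, alpha = 0.05) {
  sig <- which(stats$p_fwer <= alpha)
  K <- length(stats$p_fwer)
  counts <- table(factor(stats$region[sig], levels = cc_region_levels()))
  clusters <- list()
  if (length(sig)) {
    flag <- seq_len(K) %in% sig
    runs <- label_runs(ifelse(flag, "sig", "ns"))
    clusters <- lapply(Filter(function(r) r$label == "sig", runs),
                       `[[`, "idx")
  }
  list(significant = sig, n_significant = length(sig),
       region_counts = as.vector(counts) |>
         stats::setNames(cc_region_levels()),
       mean_d = if (length(sig)) mean(stats$cohens_d[sig]) else NA_real_,
       sd_d = if (length(sig)) stats::sd(stats$cohens_d[sig]) else NA_real_,
       clusters = clusters, alpha = alpha)
}

#' Write pointwise statistics as CSV
#'
#' Dialect `point_index,region,beta1,effect,t,p_raw,p_fwer,cohens_d`.
#' @param stats a `cc_pointwise_stats`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pointwise_stats <- function(stats, path) {
  df <- data.frame(point_index = seq_along(stats$t),
                   region = stats$region, beta1 = stats$beta1,
                   effect = stats$effect, t = stats$t,
                   p_raw = stats$p_raw, p_fwer = stats$p_fwer,
                   cohens_d = stats$cohens_d, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
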