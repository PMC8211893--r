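#' Configuration of an end-to-end pipeline run
#'
#' @param outdir output directory for all stage outputs and the manifest.
#' @param synthetic a [synthetic_config()] describing the cohort to
#'   simulate, or `NULL` when `input_dir` points at an existing cohort
#'   (masks + covariates CSV in the layout written by [write_cohort()]).
#' @param input_dir optional directory with pre-existing cohort data.
#' @param registration a [registration_config()].
#' @param K template discretization (default 200 points).
#' @param n_perm permutations for every statistical test (default
#'   10000).
#' @param alpha significance level for FWER-corrected maps and the
#'   interaction gate (default 0.05).
#' @param interaction_gate run per-gender post-hoc comparisons only when
#'   the interaction p is at or below this level; they are always
#'   computed, the gate is recorded (default 0.05).
#' @param seed master seed; stage-specific seeds derive from it.
#' @param workers parallel workers for per-subject registrations.
#' @return an object of class `cc_run_config`.
#' @export
run_config <- function(outdir,
                       synthetic = synthetic_config(),
                       input_dir = NULL,
                       registration = registration_config(),
                       K = 200, n_perm = 10000, alpha = 0.05,
                       interaction_gate = 0.05, seed = 1, workers = 1) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 100, K >= 8, workers >= 1)
  if (is.null(synthetic) && is.null(input_dir))
    stop("either a synthetic config or an input_dir is required")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  structure(list(outdir = outdir, synthetic = synthetic,
                 input_dir = input_dir, registration = registration,
                 K = as.integer(K), n_perm = as.integer(n_perm),
                 alpha = alpha, interaction_gate = interaction_gate,
                 seed = as.integer(seed), workers = as.integer(workers)),
            class = "cc_run_config")
}

.manifest_path <- function(outdir) file.path(outdir, "manifest.json")

.read_manifest <- function(outdir) {
  p <- .manifest_path(outdir)
  if (!file.exists(p)) return(NULL)
  jsonlite::read_json(p, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

## a stage is current when its input hash matches the previous manifest
## and every recorded output file still exists with the recorded hash
.stage_current <- function(manifest, name, input_hash) {
  st <- manifest$stages[[name]]
  if (is.null(st) || !identical(st$input_hash, input_hash)) return(FALSE)
  files <- names(st$outputs)
  all(vapply(files, function(f)
    file.exists(f) && identical(unname(file_hash(f)), st$outputs[[f]]),
    logical(1)))
}

.record_stage <- function(stages, name, input_hash, files, elapsed,
                          skipped = FALSE) {
  stages[[name]] <- list(input_hash = input_hash,
                         outputs = as.list(stats::setNames(
                           vapply(files, file_hash, character(1)), files)),
                         elapsed_s = round(elapsed, 3),
                         skipped = skipped)
  stages
}

#' Run the full shape-analysis pipeline
#'
#' Executes, in order: cohort simulation (or ingestion), mid-sagittal
#' curve extraction, template selection, rigid + LDDMM registration, and
#' gender-stratified statistics. Stages whose inputs are unchanged since
#' the previous run in the same output directory are skipped based on
#' content hashes; a JSON manifest records configuration, seeds, package
#' version, and per-stage output hashes and timings. Identical
#' configuration and seed give identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the `manifest`, the statistics results
#'   (`stats`), and the paths of all stage outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cc_run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prev <- .read_manifest(outdir) %||% list(stages = list())
  stages <- list()
  t_all <- proc.time()[3]

  ## ---- stage 1: simulate (or ingest) -------------------------------
  covp <- file.path(outdir, "covariates.csv")
  h1 <- object_hash(list("simulate", config$synthetic, config$input_dir))
  mask_dir <- file.path(outdir, "masks")
  if (.stage_current(prev, "simulate", h1)) {
    stages <- .record_stage(stages, "simulate", h1,
                            names(prev$stages$simulate$outputs),
                            prev$stages$simulate$elapsed_s, skipped = TRUE)
  } else {
    t0 <- proc.time()[3]
    if (!is.null(config$input_dir)) {
      dir.create(mask_dir, showWarnings = FALSE)
      src <- list.files(file.path(config$input_dir, "masks"),
                        full.names = TRUE)
      file.copy(src, mask_dir, overwrite = TRUE)
      file.copy(file.path(config$input_dir, "covariates.csv"), covp,
                overwrite = TRUE)
    } else {
      cohort <- generate_cohort(config$synthetic)
      write_cohort(cohort, outdir)
    }
    files <- c(list.files(mask_dir, full.names = TRUE), covp)
    files <- c(files, Filter(file.exists,
                             file.path(outdir, "synthetic_config.json")))
    stages <- .record_stage(stages, "simulate", h1, files,
                            proc.time()[3] - t0)
  }

  ## ---- stage 2: extract curves and areas ---------------------------
  mask_files <- sort(list.files(mask_dir, full.names = TRUE))
  h2 <- object_hash(list("extract", stages$simulate$outputs))
  curvesp <- file.path(outdir, "curves.csv")
  areasp <- file.path(outdir, "areas.csv")
  extract_files <- c(curvesp, paste0(curvesp, ".json"), areasp)
  if (.stage_current(prev, "extract", h2)) {
    stages <- .record_stage(stages, "extract", h2, extract_files,
                            prev$stages$extract$elapsed_s, skipped = TRUE)
  } else {
    t0 <- proc.time()[3]
    curves <- list()
    areas <- list()
    for (f in mask_files) {
      sid <- sub("\\.nii(\\.gz)?$", "", basename(f))
      sl <- extract_midsagittal(f)
      curves[[sid]] <- trace_boundary(sl, subject_id = sid)
      areas[[sid]] <- c(subject_id = sid, region_areas(sl))
    }
    write_curves_csv(curves, curvesp)
    adf <- do.call(rbind, lapply(areas, function(a)
      data.frame(subject_id = a[["subject_id"]],
                 CC = as.numeric(a[["CC"]]), gCC = as.numeric(a[["gCC"]]),
                 bCC = as.numeric(a[["bCC"]]), sCC = as.numeric(a[["sCC"]]),
                 stringsAsFactors = FALSE)))
    utils::write.csv(adf, areasp, row.names = FALSE, quote = FALSE)
    stages <- .record_stage(stages, "extract", h2, extract_files,
                            proc.time()[3] - t0)
  }

  ## ---- stage 3: template selection ---------------------------------
  h3 <- object_hash(list("template", stages$extract$outputs, config$K))
  tmplp <- file.path(outdir, "template.csv")
  if (.stage_current(prev, "template", h3)) {
    stages <- .record_stage(stages, "template", h3,
                            c(tmplp, paste0(tmplp, ".json")),
                            prev$stages$template$elapsed_s, skipped = TRUE)
  } else {
    t0 <- proc.time()[3]
    curves <- .reload_curves(curvesp, areasp)
    template <- select_template(curves, K = config$K)
    write_template(template, tmplp)
    stages <- .record_stage(stages, "template", h3,
                            c(tmplp, paste0(tmplp, ".json")),
                            proc.time()[3] - t0)
  }

  ## ---- stage 4: registration ---------------------------------------
  h4 <- object_hash(list("register", stages$template$outputs,
                         stages$extract$outputs,
                         unclass(config$registration)))
  markp <- file.path(outdir, "markers.csv")
  regp <- file.path(outdir, "registrations.json")
  if (.stage_current(prev, "register", h4)) {
    stages <- .record_stage(stages, "register", h4,
                            c(markp, paste0(markp, ".areas.csv"), regp),
                            prev$stages$register$elapsed_s, skipped = TRUE)
  } else {
    t0 <- proc.time()[3]
    curves <- .reload_curves(curvesp, areasp)
    template <- read_template(tmplp)
    mtab <- register_cohort(curves, template, config$registration,
                            workers = config$workers)
    write_marker_table(mtab, markp)
    jsonlite::write_json(mtab$diagnostics, regp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    stages <- .record_stage(stages, "register", h4,
                            c(markp, paste0(markp, ".areas.csv"), regp),
                            proc.time()[3] - t0)
  }

  ## ---- stage 5: statistics -----------------------------------------
  h5 <- object_hash(list("stats", stages$register$outputs,
                         stages$extract$outputs, config$n_perm,
                         config$alpha, config$interaction_gate,
                         config$seed))
  statfiles <- c(file.path(outdir, paste0("shape_stats_",
                                          c("all", "female", "male"),
                                          ".csv")),
                 file.path(outdir, paste0("area_stats_",
                                          c("all", "female", "male"),
                                          ".csv")),
                 file.path(outdir, "summary.json"))
  if (.stage_current(prev, "stats", h5)) {
    stages <- .record_stage(stages, "stats", h5, statfiles,
                            prev$stages$stats$elapsed_s, skipped = TRUE)
    res <- jsonlite::read_json(file.path(outdir, "summary.json"),
                               simplifyVector = TRUE)
  } else {
    t0 <- proc.time()[3]
    template <- read_template(tmplp)
    mtab <- read_marker_table(markp, template$curve_area_mm2)
    areas <- utils::read.csv(areasp, stringsAsFactors = FALSE)
    cov <- utils::read.csv(covp, stringsAsFactors = FALSE)
    gs <- gender_stratified_run(mtab, areas, cov,
                                n_perm = config$n_perm,
                                alpha = config$alpha,
                                interaction_gate = config$interaction_gate,
                                seed = config$seed)
    for (sc in c("all", "female", "male"))
      write_pointwise_stats(gs$shape[[sc]],
                            file.path(outdir,
                                      paste0("shape_stats_", sc, ".csv")))
    for (sc in c("all", "female", "male"))
      utils::write.csv(gs$areas[[sc]],
                       file.path(outdir, paste0("area_stats_", sc, ".csv")),
                       row.names = FALSE, quote = FALSE)
    res <- list(omnibus_p = lapply(gs$shape, `[[`, "omnibus_p"),
                interaction_p_shape = gs$interaction$shape$omnibus_p,
                interaction_p_area = as.list(stats::setNames(
                  gs$interaction$area$p, gs$interaction$area$structure)),
                gate_passed = gs$gate_passed,
                n_significant = lapply(gs$shape, function(s)
                  sum(s$p_fwer <= config$alpha)),
                n_perm = config$n_perm, alpha = config$alpha,
                seed = config$seed)
    jsonlite::write_json(res, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stages <- .record_stage(stages, "stats", h5, statfiles,
                            proc.time()[3] - t0)
  }

  manifest <- list(package_version =
                     as.character(utils::packageVersion("ccmorph")),
                   seed = config$seed,
                   config_hash = object_hash(unclass(config)),
                   elapsed_s = round(proc.time()[3] - t_all, 3),
                   stages = stages)
  jsonlite::write_json(manifest, .manifest_path(outdir), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, stats = res,
                 paths = list(covariates = covp, curves = curvesp,
                              areas = areasp, template = tmplp,
                              markers = markp,
                              summary = file.path(outdir, "summary.json"))))
}

## reload curves with their pixel areas from the stage CSVs
.reload_curves <- function(curvesp, areasp) {
  curves <- read_curves_csv(curvesp)
  areas <- utils::read.csv(areasp, stringsAsFactors = FALSE)
  for (sid in names(curves)) {
    i <- match(sid, areas$subject_id)
    curves[[sid]]$pixel_area_mm2 <- areas$CC[i]
  }
  curves
}

#' Gender-stratified analysis with interaction gating
#'
#' Runs the gender-by-group interaction test first (shape and areas),
#' then the FES-vs-HC comparisons within the full cohort and within each
#' gender (covarying age and TIV only within a single gender), recording
#' whether the interaction gate passed. The full-cohort result is always
#' produced; the per-gender results are computed and reported together
#' with the gate so downstream consumers can apply it.
#'
#' @param mtab a `cc_marker_table`.
#' @param areas per-subject area data frame (`subject_id, CC, gCC, bCC,
#'   sCC`).
#' @param covariates covariate data frame; must contain both genders.
#' @param n_perm,seed permutation settings.
#' @param alpha significance level.
#' @param interaction_gate gate level for per-gender post-hocs.
#' @return list with `shape` (per-scope `cc_pointwise_stats`), `areas`
#'   (per-scope data frames), `interaction` (shape and area tests) and
#'   `gate_passed`.
#' @export
gender_stratified_run <- function(mtab, areas, covariates, n_perm = 10000,
                                  alpha = 0.05, interaction_gate = 0.05,
                                  seed = 1) {
  for (g in c("F", "M"))
    if (!any(covariates$gender == g))
      stop("gender ", g, " absent from the cohort; ",
           "gender-stratified analysis impossible")
  sA <- subject_stream_seed(seed, "stats", "shape")
  inter_shape <- interaction_test(mtab, covariates, n_perm = n_perm,
                                  seed = sA)
  amat <- areas[, c("subject_id", "CC", "gCC", "bCC", "sCC")]
  Ya <- as.matrix(amat[, -1])
  rownames(Ya) <- amat$subject_id
  inter_area_pi <- interaction_test(Ya, covariates, n_perm = n_perm,
                                    seed = sA)
  inter_area <- data.frame(structure = colnames(Ya),
                           p = inter_area_pi$p,
                           beta = inter_area_pi$beta,
                           stringsAsFactors = FALSE)
  gate <- inter_shape$omnibus_p <= interaction_gate ||
    any(inter_area$p <= interaction_gate)
  shape <- list(); area_res <- list()
  for (sc in c("all", "female", "male")) {
    ssc <- subject_stream_seed(seed, sc, "scope")
    shape[[sc]] <- pointwise_shape_analysis(mtab, covariates, scope = sc,
                                            n_perm = n_perm, seed = ssc)
    area_res[[sc]] <- area_group_analysis(areas, covariates, scope = sc,
                                          n_perm = n_perm, seed = ssc)
  }
  list(shape = shape, areas = area_res,
       interaction = list(shape = inter_shape, area = inter_area),
       gate_passed = gate, interaction_gate = interaction_gate,
       alpha = alpha)
}
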