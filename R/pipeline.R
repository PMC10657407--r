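# End-to-end orchestration: mask -> surface -> centreline -> labels ->
# morphometry -> cohort statistics, with a serialized run manifest so any
# run is reproducible from its configuration and seed.

#' Pipeline run configuration
#'
#' All defaults are serialized into every run manifest, so a manifest plus a
#' seed reproduces a run exactly.
#'
#' @param left_axis unit vector toward the subject's left.
#' @param n_per_path centreline resampling density (vertices per
#'   root-to-leaf path).
#' @param landmark_offset landmark offset in mm.
#' @param eni_mpa_at `"P1"` or `"Pb"` (see [measure_subject()]).
#' @param smooth_iterations surface smoothing iterations for mask inputs.
#' @param centerline_spacing rasterisation spacing for centreline extraction
#'   (NULL = automatic).
#' @param alpha significance level for cohort statistics.
#' @param bonferroni apply Bonferroni correction in cohort statistics.
#' @param seed integer seed for any stochastic stage (generation only; the
#'   measurement stages are deterministic).
#' @param output_dir where artifacts are written (NULL = nowhere).
#' @return A `run_config` list.
#' @export
run_config <- function(left_axis = c(1, 0, 0), n_per_path = 100,
                       landmark_offset = 10, eni_mpa_at = "P1",
                       smooth_iterations = 20, centerline_spacing = NULL,
                       alpha = 0.05, bonferroni = FALSE, seed = 1L,
                       output_dir = NULL) {
  structure(list(left_axis = left_axis, n_per_path = n_per_path,
                 landmark_offset = landmark_offset, eni_mpa_at = eni_mpa_at,
                 smooth_iterations = smooth_iterations,
                 centerline_spacing = centerline_spacing, alpha = alpha,
                 bonferroni = bonferroni, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

stage_log <- function(logenv, subject, stage, t0, warn = NULL) {
  entry <- sprintf("subject=%s stage=%s duration=%.2fs%s", subject, stage,
                   as.numeric(Sys.time()) - t0,
                   if (is.null(warn)) "" else paste0(" warning=", warn))
  logenv$lines <- c(logenv$lines, entry)
}

#' Run the measurement pipeline for one subject
#'
#' Accepts a `pa_tree` (surfaced first), a `surface_mesh`, a `voxel_mask`
#' (surfaced and smoothed first), or a path to an STL/PLY/NIfTI file.
#' Produces the per-subject morphometry record and, if `output_dir` is set,
#' writes surface, centreline (VTP + JSON), record (CSV + JSON) and a stage
#' log. Given a fixed config the result is deterministic.
#'
#' @param config a [run_config()].
#' @param input subject input (see above).
#' @param subject_id identifier carried into the record and file names.
#' @param species species label carried into the record.
#' @return A list: `record` (morphometry record), `labeled` (labeled tree),
#'   `mesh`, `log` (stage lines).
#' @export
run_subject <- function(config, input, subject_id = "subject", species = NA_character_) {
  stopifnot(inherits(config, "run_config"))
  logenv <- new.env()
  logenv$lines <- character(0)

  t0 <- as.numeric(Sys.time())
  mesh <- NULL
  if (is.character(input)) {
    ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", input)))
    input <- switch(ext,
                    stl = read_stl(input),
                    ply = read_ply(input),
                    nii = read_mask_nifti(input),
                    stop("unsupported input format: ", ext))
  }
  if (inherits(input, "pa_tree")) {
    mesh <- surface_from_tree(input)
    stage_log(logenv, subject_id, "surface_from_tree", t0)
  } else if (inherits(input, "voxel_mask")) {
    mesh <- extract_surface(input)
    mesh <- smooth_volume_preserving(mesh, config$smooth_iterations)
    stage_log(logenv, subject_id, "reconstruct", t0)
  } else if (inherits(input, "surface_mesh")) {
    mesh <- input
  } else {
    stop("unsupported input of class ", paste(class(input), collapse = "/"))
  }

  t0 <- as.numeric(Sys.time())
  cl <- extract_centerline(mesh, spacing = config$centerline_spacing)
  stage_log(logenv, subject_id, "centerline", t0)

  t0 <- as.numeric(Sys.time())
  cl <- resample_centerline(cl, config$n_per_path)
  lt <- label_edges(cl, config$left_axis)
  rec <- measure_subject(lt, eni_mpa_at = config$eni_mpa_at,
                         offset = config$landmark_offset,
                         subject_id = subject_id, species = species)
  stage_log(logenv, subject_id, "measure", t0)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    base <- file.path(config$output_dir, subject_id)
    write_stl(mesh, paste0(base, "_surface.stl"))
    write_centerline_vtp(lt, paste0(base, "_centerline.vtp"))
    write_centerline_json(cl, paste0(base, "_centerline.json"))
    df <- as.data.frame(rec)
    write.csv(format(df, digits = 10), paste0(base, "_record.csv"),
              row.names = FALSE)
    jsonlite::write_json(unclass(rec), paste0(base, "_record.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
    writeLines(logenv$lines, paste0(base, "_log.txt"))
  }
  list(record = rec, labeled = lt, mesh = mesh, log = logenv$lines)
}

#' Run a cohort through the pipeline and produce the statistical reports
#'
#' Per-subject failures are caught, logged and skipped so one corrupt input
#' does not abort the batch. With fewer than 3 evaluable subjects in a group,
#' only descriptives are reported and tests are skipped with a warning.
#'
#' @param config a [run_config()].
#' @param subjects named list: each element a list with `input`, optional
#'   `species` and optional `id`.
#' @param reference_species species name used as the comparison reference for
#'   similarity tables (e.g. `"human"`); NULL skips similarity coding.
#' @return A list: `cohort` (record data.frame), `descriptives`,
#'   `similarity` (named list of similarity tables vs the reference),
#'   `failures`, `manifest`.
#' @export
run_cohort <- function(config, subjects, reference_species = NULL) {
  records <- list()
  failures <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    sid <- s$id %||% names(subjects)[i] %||% sprintf("subject%03d", i)
    res <- tryCatch(
      run_subject(config, s$input, subject_id = sid,
                  species = s$species %||% NA_character_),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[sid]] <- conditionMessage(res)
      warning(sprintf("subject %s failed: %s", sid, conditionMessage(res)))
    } else {
      records[[sid]] <- res$record
    }
  }
  if (length(records) == 0) stop("no subject completed the pipeline")
  cohort <- cohort_table(records)
  groups <- split(cohort, cohort$species)
  desc <- describe_cohorts(groups)
  sim <- NULL
  if (!is.null(reference_species) && reference_species %in% names(groups)) {
    ref <- groups[[reference_species]]
    others <- setdiff(names(groups), reference_species)
    sim <- list()
    for (g in others) {
      if (nrow(groups[[g]]) < 3 || nrow(ref) < 3) {
        warning("group too small for similarity testing: ", g)
        next
      }
      sim[[g]] <- similarity_table(groups[[g]], ref, alpha = config$alpha,
                                   bonferroni = config$bonferroni,
                                   m = length(similarity_rows()))
    }
  }
  manifest <- list(config = unclass(config),
                   n_subjects = length(subjects),
                   n_completed = length(records),
                   failures = failures,
                   package_version = as.character(utils::packageVersion("pamorph")))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(format(cohort, digits = 10),
              file.path(config$output_dir, "cohort.csv"), row.names = FALSE)
    write.csv(desc, file.path(config$output_dir, "descriptives.csv"),
              row.names = FALSE)
    if (!is.null(sim)) for (g in names(sim))
      write.csv(sim[[g]], file.path(config$output_dir,
                                    sprintf("similarity_%s.csv", g)),
                row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  list(cohort = cohort, descriptives = desc, similarity = sim,
       failures = failures, manifest = manifest)
}

#' Synthetic cohort records from generator ground truth
#'
#' Draws `n` subjects from a species template and returns their analytic
#' parameter records (no surfacing or centreline extraction), optionally with
#' additive measurement noise. Useful for cohort-scale statistical studies
#' where running the full geometric pipeline per subject is unnecessary.
#'
#' @param template species template passed to [make_tree()].
#' @param n number of subjects.
#' @param seed cohort seed; subject i uses `seed * 1000 + i`.
#' @param species species label in the records (default: the template name).
#' @param noise_sd optional named vector of additive Gaussian noise SDs per
#'   parameter (e.g. `c(D_MPA = 0.3)`), emulating measurement error.
#' @param params overrides forwarded to [make_tree()].
#' @return A cohort data.frame, one row per subject.
#' @export
cohort_from_truth <- function(template, n, seed = 1L, species = template,
                              noise_sd = NULL, params = list()) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- make_tree(template, seed = seed * 1000L + i, params = params)
    t <- tr$truth
    rows[[i]] <- data.frame(
      subject_id = sprintf("%s%03d", species, i), species = species,
      n_side_lpa = t$n_side_lpa %||% NA_integer_,
      n_side_rpa = t$n_side_rpa %||% NA_integer_,
      L_MPA = t$L_MPA, L_LPA = t$L_LPA %||% NA_real_,
      L_RPA = t$L_RPA %||% NA_real_,
      D_MPA = t$D_MPA, D_LPA = t$D_LPA %||% NA_real_,
      D_RPA = t$D_RPA %||% NA_real_,
      alpha = t$alpha %||% NA_real_,
      T_LPA = t$T_LPA %||% NA_real_, T_RPA = t$T_RPA %||% NA_real_,
      CI_LPA = t$CI_LPA %||% NA_real_, CI_RPA = t$CI_RPA %||% NA_real_,
      EnI = t$EnI %||% NA_real_, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (!is.null(noise_sd)) {
    df <- with_seed(seed, {
      for (p in names(noise_sd))
        df[[p]] <- df[[p]] + rnorm(n, 0, noise_sd[[p]])
      df
    })
  }
  df
}
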