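#' Pipeline configuration
#'
#' Validated settings for subject- and group-level runs. Exactly one
#' quantification input source must be given: a reference-region label
#' (`ref_label`) or an arterial `.dft` file (`arterial`).
#'
#' @param pvc `"gtm"`, `"idsurf"` or `"none"`.
#' @param psf_fwhm scanner PSF FWHM in mm (> 0 whenever PVC is enabled).
#' @param quant `"logan"`, `"patlak"`, `"srtm"` or `"suvr"`.
#' @param ref_label integer label id of the reference region.
#' @param arterial path to an arterial `.dft` file.
#' @param t_star minutes, for the graphical models.
#' @param suvr_window minutes, for SUVR.
#' @param coregister logical; disable when inputs are pre-aligned.
#' @param qc_threshold outlier-probability flagging threshold.
#' @param seed integer seed recorded in run provenance.
#' @param write_voxelwise logical; write a voxelwise parametric map.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(pvc = c("gtm", "idsurf", "none"), psf_fwhm = 6.5,
                            quant = c("logan", "patlak", "srtm", "suvr"),
                            ref_label = NULL, arterial = NULL, t_star = 20,
                            suvr_window = c(40, 60), coregister = TRUE,
                            qc_threshold = 0.05, seed = 1,
                            write_voxelwise = TRUE) {
  pvc <- match.arg(pvc)
  quant <- match.arg(quant)
  if (pvc != "none")
    assert_that(psf_fwhm > 0, "psf_fwhm must be > 0 when PVC is enabled")
  assert_that(xor(is.null(ref_label), is.null(arterial)),
              "exactly one of ref_label or arterial must be given")
  if (!is.null(arterial))
    assert_that(file.exists(arterial), "arterial file not found: %s", arterial)
  structure(list(pvc = pvc, psf_fwhm = psf_fwhm, quant = quant,
                 ref_label = ref_label, arterial = arterial, t_star = t_star,
                 suvr_window = suvr_window, coregister = coregister,
                 qc_threshold = qc_threshold, seed = seed,
                 write_voxelwise = write_voxelwise),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  vals <- utils::modifyList(vals, list(...))
  do.call(pipeline_config, vals)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

#' Run the subject-level pipeline for one acquisition
#'
#' Stages: (1) coregistration of the static (time-weighted average) PET to
#' the T1 by NMI, (2) label resampling into native PET space, (3) partial
#' volume correction, (4) kinetic quantification of every non-reference
#' region, (5) per-subject QC metric computation and results reporting. All
#' outputs land under `output_root/sub-<id>/`; re-running with identical
#' inputs reproduces identical files.
#'
#' @param record one row of [discover_bids()] output.
#' @param config a [pipeline_config].
#' @param output_root output directory.
#' @return Invisibly, a list of output paths.
#' @export
run_subject <- function(record, config, output_root) {
  sub_dir <- file.path(output_root, paste0("sub-", record$subject_id))
  dir.create(sub_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("petquant %s", as.character(utils::packageVersion("petquant"))),
                 sprintf("config_hash: %s", config_hash(config)),
                 sprintf("pet: %s", record$pet_path))
  outputs <- list()

  pet <- read_dynamic_pet(record$pet_path, record$sidecar_path)
  static <- time_weighted_average(pet)
  assert_that(!is.na(record$label_path), "no label volume for sub-%s",
              record$subject_id)
  labels <- read_labels(record$label_path)

  qc_rows <- NULL
  if (config$coregister) {
    assert_that(!is.na(record$t1_path), "no T1 image for sub-%s",
                record$subject_id)
    t1 <- read_volume(record$t1_path)
    reg <- rigid_register(static, t1)
    tf <- reg$transform
    outputs$transform <- file.path(sub_dir, "pet-to-t1_transform.txt")
    write_transform(tf, outputs$transform, "pet_world_to_t1_world")
    log_lines <- c(log_lines,
                   sprintf("coregistration NMI: %.6f", reg$similarity))
    t1_to_pet <- transform_invert(tf)
  } else {
    tf <- rigid_transform()
    t1_to_pet <- tf
    t1 <- if (!is.na(record$t1_path)) read_volume(record$t1_path) else NULL
    log_lines <- c(log_lines, "coregistration: disabled (pre-aligned inputs)")
  }
  labels_pet <- resample(labels, t1_to_pet, static, "nearest")
  outputs$labels <- file.path(sub_dir, "labels_space-pet.nii")
  write_volume(volume3d(labels_pet$labels + 0, labels_pet$affine),
               outputs$labels)

  if (!is.null(t1)) {
    t1_in_pet <- resample(t1, t1_to_pet, static, "trilinear")
    m <- auto_mask(static)
    qcm <- coreg_qc_metrics(static, t1_in_pet, m)
    qc_rows <- data.frame(subject_id = record$subject_id,
                          session_id = record$session_id,
                          task_id = record$task_id,
                          stage = "coregistration",
                          metric = qcm$metric, value = qcm$value,
                          stringsAsFactors = FALSE)
  }

  # partial-volume correction
  psf_ <- psf(config$psf_fwhm)
  region_ids <- sort(setdiff(unique(as.integer(labels_pet$labels)), 0L))
  if (config$pvc == "gtm") {
    g <- gtm_correct(pet, labels_pet, psf_)
    tacs <- g$tacs
    observed <- g$observed
    outputs$tacs <- file.path(sub_dir, "tacs_pvc-gtm.csv")
    write_tacs_csv(tacs, outputs$tacs)
    quant_pet <- pet
  } else if (config$pvc == "idsurf") {
    corrected <- idsurf_correct(pet, labels_pet, psf_)
    outputs$pvc_volume <- file.path(sub_dir, "pet_pvc-idsurf.nii")
    write_dynamic_pet(corrected, outputs$pvc_volume)
    observed <- lapply(region_ids, function(id) extract_tac(pet, labels_pet, id))
    names(observed) <- region_names_for(labels_pet, region_ids)
    tacs <- lapply(region_ids, function(id)
      extract_tac(corrected, labels_pet, id))
    names(tacs) <- names(observed)
    outputs$tacs <- file.path(sub_dir, "tacs_pvc-idsurf.csv")
    write_tacs_csv(tacs, outputs$tacs)
    quant_pet <- corrected
  } else {
    observed <- lapply(region_ids, function(id) extract_tac(pet, labels_pet, id))
    names(observed) <- region_names_for(labels_pet, region_ids)
    tacs <- observed
    outputs$tacs <- file.path(sub_dir, "tacs_pvc-none.csv")
    write_tacs_csv(tacs, outputs$tacs)
    quant_pet <- pet
  }
  log_lines <- c(log_lines, sprintf("pvc: %s (fwhm %.3g mm)", config$pvc,
                                    config$psf_fwhm))

  # quantification input
  if (!is.null(config$ref_label)) {
    ref_name <- region_names_for(labels_pet, config$ref_label)
    assert_that(ref_name %in% names(tacs),
                "reference region label %d not present in labels for sub-%s",
                config$ref_label, record$subject_id)
    input <- tacs[[ref_name]]
  } else {
    input <- parse_dft(config$arterial)
    ref_name <- NULL
  }

  fit_one <- function(t) {
    switch(config$quant,
           logan = logan(t, input, config$t_star),
           patlak = patlak(t, input, config$t_star),
           srtm = srtm(t, input),
           suvr = suvr(t, input, config$suvr_window))
  }
  target_names <- setdiff(names(tacs), ref_name)
  fits <- lapply(tacs[target_names], function(t)
    tryCatch(fit_one(t), error = function(e) NULL))

  # long-format results: stage integrals + model parameters
  mk_rows <- function(stage, tl) {
    do.call(rbind, lapply(names(tl), function(nm)
      data.frame(subject_id = record$subject_id,
                 session_id = record$session_id, task_id = record$task_id,
                 run_id = record$run_id, stage = stage, region = nm,
                 metric = "integral",
                 value = tac_integral(tl[[nm]],
                                      max(tl[[nm]]$frame_mid_times)),
                 stringsAsFactors = FALSE)))
  }
  rows <- rbind(mk_rows("coregistration", observed), mk_rows("pvc", tacs))
  for (nm in target_names) {
    f <- fits[[nm]]
    params <- if (is.null(f)) stats::setNames(list(NA_real_), config$quant)
    else f$parameters
    rows <- rbind(rows, data.frame(
      subject_id = record$subject_id, session_id = record$session_id,
      task_id = record$task_id, run_id = record$run_id,
      stage = "quantification", region = nm, metric = names(params),
      value = unlist(params), stringsAsFactors = FALSE))
  }
  outputs$results <- file.path(sub_dir, "regional_results.csv")
  write_vertical_csv(rows, outputs$results)

  # voxelwise parametric map
  if (config$write_voxelwise) {
    pm <- voxelwise_map(quant_pet, input, config$quant,
                        t_star = config$t_star, window = config$suvr_window)
    outputs$param_map <- file.path(sub_dir,
                                   sprintf("param_%s.nii", pm$parameter))
    write_volume(pm$map, outputs$param_map)
    if (!is.null(qc_rows)) {
      qcm <- tryCatch(
        coreg_qc_metrics(static, pm$map, auto_mask(static)),
        error = function(e) NULL)
      if (!is.null(qcm))
        qc_rows <- rbind(qc_rows, data.frame(
          subject_id = record$subject_id, session_id = record$session_id,
          task_id = record$task_id, stage = "quantification",
          metric = qcm$metric, value = qcm$value, stringsAsFactors = FALSE))
    }
  }

  if (!is.null(qc_rows)) {
    outputs$qc <- file.path(sub_dir, "qc_values.csv")
    qc_rows$value <- qc_rows$value  # numeric; formatted on write
    utils::write.csv(transform(qc_rows, value = format_num(value)),
                     outputs$qc, row.names = FALSE, quote = FALSE)
  }
  log_lines <- c(log_lines, sprintf("quantification: %s", config$quant),
                 "status: completed")
  outputs$log <- file.path(sub_dir, "run_log.txt")
  writeLines(log_lines, outputs$log)
  invisible(outputs)
}

write_tacs_csv <- function(tacs, path) {
  rows <- do.call(rbind, lapply(names(tacs), function(nm) {
    t <- tacs[[nm]]
    data.frame(frame_start = t$frame_mid_times - t$frame_durations / 2,
               frame_duration = t$frame_durations, region = nm,
               activity = t$activity, stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$region, rows$frame_start), , drop = FALSE]
  rows$frame_start <- format_num(rows$frame_start)
  rows$frame_duration <- format_num(rows$frame_duration)
  rows$activity <- format_num(rows$activity)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run all subject-level analyses under a BIDS root
#'
#' Subjects run independently; a stage error aborts that subject only and is
#' recorded in the run summary.
#'
#' @param input_dir BIDS root.
#' @param output_root output directory.
#' @param config a [pipeline_config].
#' @param participant_labels optional subject-id filter.
#' @return A data frame (subject_id, status, message), invisibly; attribute
#'   `exit_code` is 0 when every subject succeeded, 2 otherwise.
#' @export
run_participant_level <- function(input_dir, output_root, config,
                                  participant_labels = NULL) {
  records <- discover_bids(input_dir)
  if (!is.null(participant_labels))
    records <- records[records$subject_id %in% participant_labels, ,
                       drop = FALSE]
  assert_that(nrow(records) > 0, "no matching subjects")
  status <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    res <- tryCatch({
      run_subject(rec, config, output_root)
      list(status = "ok", message = "")
    }, error = function(e) list(status = "failed",
                                message = conditionMessage(e)))
    data.frame(subject_id = rec$subject_id, status = res$status,
               message = res$message, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, status)
  attr(out, "exit_code") <- if (all(out$status == "ok")) 0L else 2L
  dir.create(output_root, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out, file.path(output_root, "participants_status.csv"),
                   row.names = FALSE, quote = TRUE)
  invisible(out)
}

#' Run the group-level analyses
#'
#' Aggregates the per-subject regional results into per-stage vertical CSVs
#' and group descriptives, and runs the automated KDE QC across subjects
#' (skipped with a warning below 5 subjects; descriptives are still
#' produced).
#'
#' @param output_root directory holding completed `sub-*` outputs.
#' @param config a [pipeline_config].
#' @return Invisibly, a list of output paths.
#' @export
run_group <- function(output_root, config) {
  res_files <- sort(list.files(output_root, pattern = "^regional_results\\.csv$",
                               recursive = TRUE, full.names = TRUE))
  assert_that(length(res_files) >= 1, "no completed subjects under %s",
              output_root)
  rows <- do.call(rbind, lapply(res_files, read_vertical_csv))
  res_dir <- file.path(output_root, "results")
  qc_dir <- file.path(output_root, "qc")
  dir.create(res_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(qc_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  for (st in sort(unique(rows$stage))) {
    p <- file.path(res_dir, sprintf("%s_results.csv", st))
    write_vertical_csv(rows[rows$stage == st, , drop = FALSE], p)
    outputs[[st]] <- p
  }
  desc <- group_descriptives(rows, group_by = "task")
  outputs$descriptives <- file.path(res_dir, "group_descriptives.csv")
  desc_fmt <- desc
  for (cl in c("mean", "sd", "min", "max")) desc_fmt[[cl]] <- format_num(desc[[cl]])
  utils::write.csv(desc_fmt, outputs$descriptives, row.names = FALSE,
                   quote = FALSE)

  qc_files <- sort(list.files(output_root, pattern = "^qc_values\\.csv$",
                              recursive = TRUE, full.names = TRUE))
  n_sub <- length(qc_files)
  if (n_sub >= 5) {
    qc <- do.call(rbind, lapply(qc_files, function(f)
      utils::read.csv(f, stringsAsFactors = FALSE,
                      colClasses = c(subject_id = "character"))))
    scored <- group_qc(qc, threshold = config$qc_threshold)
    outputs$qc <- file.path(qc_dir, "qc_metrics.csv")
    for (cl in c("value", "density", "probability"))
      scored[[cl]] <- format_num(scored[[cl]])
    utils::write.csv(scored, outputs$qc, row.names = FALSE, quote = FALSE)
  } else {
    warn_pq("automated QC skipped: %d subjects < 5", n_sub)
  }
  writeLines(c(sprintf("petquant %s",
                       as.character(utils::packageVersion("petquant"))),
               sprintf("config_hash: %s", config_hash(config)),
               sprintf("subjects: %d", n_sub)),
             file.path(output_root, "group_log.txt"))
  invisible(outputs)
}
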