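#' Regional summary of a parametric map, dynamic series, or TAC set
#'
#' Reduces the input to one long-format result row per region x metric:
#' for a 3D parametric map the plain regional mean, for a dynamic series the
#' duration-weighted mean activity per region, and for a set of regional TACs
#' their 0-anchored integrals. Background (label 0) is excluded.
#'
#' @param x a [volume3d], [dynamic_pet], or named list of [tac]s.
#' @param labels a [label_volume] on the data grid (unused for TAC lists).
#' @param stage analysis stage label for the rows.
#' @param metric metric name for the rows.
#' @param subject_id,session_id,task_id,run_id BIDS entities for the rows.
#' @return A data frame with columns `subject_id`, `session_id`, `task_id`,
#'   `run_id`, `stage`, `region`, `metric`, `value`.
#' @export
regional_summary <- function(x, labels = NULL, stage = "quantification",
                             metric = "mean", subject_id = NA_character_,
                             session_id = NA_character_,
                             task_id = NA_character_, run_id = NA_character_) {
  if (inherits(x, "volume3d") || inherits(x, "dynamic_pet")) {
    assert_that(!is.null(labels), "labels required for volumetric input")
    ids <- sort(setdiff(unique(as.integer(labels$labels)), 0L))
    lab_vec <- as.integer(labels$labels)
    if (inherits(x, "volume3d")) {
      assert_that(all(dim(x$data) == dim(labels$labels)),
                  "labels must be on the data grid")
      vals <- vapply(ids, function(id) mean(x$data[lab_vec == id]), numeric(1))
    } else {
      assert_that(all(dim(x$frames)[1:3] == dim(labels$labels)),
                  "labels must be on the data grid")
      w <- x$frame_durations / sum(x$frame_durations)
      flat <- matrix(x$frames, ncol = dim(x$frames)[4])
      vw <- as.numeric(flat %*% w)
      vals <- vapply(ids, function(id) mean(vw[lab_vec == id]), numeric(1))
    }
    regions <- region_names_for(labels, ids)
    sup <- if (inherits(x, "volume3d")) any(x$data != 0) else any(x$frames != 0)
    assert_that(length(ids) > 0 && sup,
                "no overlap between labels and data support")
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "tac"))) {
    regions <- names(x) %||% vapply(x, function(t) t$source, character(1))
    vals <- vapply(x, function(t)
      tac_integral(t, max(t$frame_mid_times)), numeric(1))
  } else {
    stop_pq("unsupported input type for regional_summary")
  }
  data.frame(subject_id = subject_id, session_id = session_id,
             task_id = task_id, run_id = run_id, stage = stage,
             region = regions, metric = metric, value = as.numeric(vals),
             stringsAsFactors = FALSE, row.names = NULL)
}

region_names_for <- function(labels, ids) {
  nm <- names(labels$name_map)[match(ids, as.integer(labels$name_map))]
  nm[is.na(nm)] <- paste0("region", ids[is.na(nm)])
  nm
}

#' Group-level descriptive statistics of result rows
#'
#' Mean, standard deviation, min, max and n per (grouping entities, region,
#' metric). `sd` is reported as 0 for singleton groups so the table never
#' contains NA spread values.
#'
#' @param rows result rows from [regional_summary()].
#' @param group_by subset of `c("subject", "session", "task")`.
#' @return A data frame of descriptives, deterministically ordered.
#' @export
group_descriptives <- function(rows, group_by = "subject") {
  assert_that(nrow(rows) > 0, "no result rows")
  keymap <- c(subject = "subject_id", session = "session_id", task = "task_id")
  unknown <- setdiff(group_by, names(keymap))
  assert_that(length(unknown) == 0, "unknown group key(s): %s",
              paste(unknown, collapse = ", "))
  keys <- c(unname(keymap[group_by]), "stage", "region", "metric")
  grp <- interaction(rows[keys], drop = TRUE, lex.order = TRUE)
  first_idx <- tapply(seq_len(nrow(rows)), grp, `[`, 1)
  out <- rows[first_idx, keys, drop = FALSE]
  vals <- rows$value
  out$mean <- as.numeric(tapply(vals, grp, function(v) mean(v, na.rm = TRUE)))
  out$sd <- as.numeric(tapply(vals, grp, function(v) {
    v <- v[!is.na(v)]
    if (length(v) <= 1) 0 else stats::sd(v)
  }))
  out$min <- as.numeric(tapply(vals, grp, function(v) min(v, na.rm = TRUE)))
  out$max <- as.numeric(tapply(vals, grp, function(v) max(v, na.rm = TRUE)))
  out$n <- as.integer(tapply(vals, grp, function(v) sum(!is.na(v))))
  out <- out[do.call(order, out[keys]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write result rows as a vertical-format CSV
#'
#' One value per row (long layout), header exactly
#' `sub,ses,task,run,stage,region,metric,value`, UTF-8, missing entities as
#' empty strings, rows ordered deterministically by all key columns. Failed
#' fits appear as empty value cells rather than dropped rows so group counts
#' stay auditable.
#'
#' @param rows a data frame from [regional_summary()] (columns `subject_id`,
#'   `session_id`, `task_id`, `run_id`, `stage`, `region`, `metric`, `value`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vertical_csv <- function(rows, path) {
  ent <- function(x) ifelse(is.na(x), "", as.character(x))
  df <- data.frame(sub = ent(rows$subject_id), ses = ent(rows$session_id),
                   task = ent(rows$task_id), run = ent(rows$run_id),
                   stage = ent(rows$stage), region = ent(rows$region),
                   metric = ent(rows$metric),
                   value = format_num(rows$value),
                   stringsAsFactors = FALSE)
  df <- df[do.call(order, df[c("sub", "ses", "task", "run", "stage",
                               "region", "metric")]), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("sub,ses,task,run,stage,region,metric,value", con)
  if (nrow(df))
    writeLines(do.call(paste, c(df, sep = ",")), con)
  invisible(path)
}

#' Read a vertical-format results CSV back into result rows
#'
#' @param path CSV written by [write_vertical_csv()].
#' @return A data frame in [regional_summary()] row layout.
#' @export
read_vertical_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(rep("character", 7), "numeric"))
  blank <- function(x) ifelse(x == "", NA_character_, x)
  data.frame(subject_id = blank(df$sub), session_id = blank(df$ses),
             task_id = blank(df$task), run_id = blank(df$run),
             stage = df$stage, region = df$region, metric = df$metric,
             value = df$value, stringsAsFactors = FALSE)
}
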