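#' Coregistration-stage QC similarity metrics
#'
#' The trio of similarity metrics computed between the static PET volume and
#' the T1 resampled into PET space: cross-correlation (CC), mutual
#' information (MI), and feature-space entropy (FSE, the joint histogram
#' entropy), all over the supplied mask with the registration histogram
#' settings.
#'
#' @param pet_static a [volume3d].
#' @param t1_in_pet_space a [volume3d] on the PET grid.
#' @param mask logical array; `NULL` uses all voxels.
#' @param bins joint-histogram size.
#' @return A data frame with columns `metric` (`"CC"`, `"MI"`, `"FSE"`) and
#'   `value`.
#' @export
coreg_qc_metrics <- function(pet_static, t1_in_pet_space, mask = NULL,
                             bins = 64) {
  h <- joint_histogram(pet_static, t1_in_pet_space, mask, bins)
  data.frame(
    metric = c("CC", "MI", "FSE"),
    value = c(cross_correlation(pet_static, t1_in_pet_space, mask),
              mutual_information(h),
              feature_space_entropy(h)),
    stringsAsFactors = FALSE)
}

#' Kernel density model of a QC metric across subjects
#'
#' Gaussian-kernel density estimate with Silverman's bandwidth
#' `h = 0.9 min(sd, IQR / 1.34) n^(-1/5)`, evaluated on a grid covering
#' `[min - 3h, max + 3h]`. A degenerate sample (zero spread) yields a
#' sentinel model under which nothing is flagged.
#'
#' @param values at least 5 finite metric values.
#' @param grid_n evaluation grid size.
#' @return An object of class `kde_model`: `values`, `bandwidth`, `grid`,
#'   `density`, `degenerate`.
#' @export
fit_kde <- function(values, grid_n = 512) {
  values <- values[is.finite(values)]
  assert_that(length(values) >= 5,
              "insufficient subjects for automated QC (need >= 5, got %d)",
              length(values))
  fit_kde_impl(values, grid_n)
}

# KDE fit without the public minimum-sample check (used by the leave-one-out
# scoring inside group_qc, where the cell minimum is enforced separately)
fit_kde_impl <- function(values, grid_n = 512) {
  spread <- min(stats::sd(values), stats::IQR(values) / 1.34)
  if (spread == 0) {
    return(structure(list(values = values, bandwidth = 0,
                          grid = NULL, density = NULL, degenerate = TRUE),
                     class = "kde_model"))
  }
  h <- 0.9 * spread * length(values)^(-1 / 5)
  d <- stats::density(values, bw = h, kernel = "gaussian",
                      from = min(values) - 3 * h, to = max(values) + 3 * h,
                      n = grid_n)
  structure(list(values = values, bandwidth = h, grid = d$x, density = d$y,
                 degenerate = FALSE),
            class = "kde_model")
}

#' @export
print.kde_model <- function(x, ...) {
  if (x$degenerate)
    cat("<kde_model> degenerate (zero spread): nothing will be flagged\n")
  else
    cat(sprintf("<kde_model> n = %d, bandwidth %.4g\n",
                length(x$values), x$bandwidth))
  invisible(x)
}

# density at a point, evaluated on the model grid
kde_density_at <- function(model, x) {
  if (model$degenerate) return(NA_real_)
  stats::approx(model$grid, model$density, xout = x, yleft = 0, yright = 0)$y
}

#' Lowest-density outlier probability of a QC value
#'
#' The probability of observing a metric value at least as unusual as `x`
#' under the group's empirical distribution: the integral of the estimated
#' density over the lowest-density region `{u : f(u) <= f(x)}`, evaluated on
#' the model grid. The density mode scores 1; far-tail values score ~0.
#' Values with probability below `threshold` are flagged.
#'
#' @param model a [fit_kde()] model.
#' @param x metric value to score.
#' @param threshold flagging threshold (default 0.05).
#' @return A list with `density`, `probability`, `flagged`.
#' @export
outlier_probability <- function(model, x, threshold = 0.05) {
  if (model$degenerate)
    return(list(density = NA_real_, probability = NA_real_, flagged = FALSE))
  fx <- kde_density_at(model, x)
  dx <- diff(model$grid[1:2])
  total <- sum(model$density) * dx
  p <- sum(model$density[model$density <= fx]) * dx / total
  list(density = fx, probability = p, flagged = p < threshold)
}

#' Group-level automated QC
#'
#' Fits one KDE per (stage, metric) cell with at least `min_n` subjects and
#' scores each subject's value against its group distribution;
#' under-populated cells are skipped with a warning. Output ordering is
#' deterministic (stage, metric, subject).
#'
#' Scoring is leave-one-out by default: each subject's value is evaluated
#' against the density of the *other* subjects' values. Including the scored
#' value in its own reference distribution puts a floor of roughly `1/n`
#' plus the distribution's low-density tail mass on every probability, which
#' makes a single gross failure among ~20 subjects undetectable at
#' conventional thresholds; leave-one-out removes that floor. Set
#' `scoring = "pooled"` to score against the full-sample density instead
#' (more conservative; fewer spurious flags, but insensitive to single
#' outliers in small cohorts).
#'
#' @param records data frame with columns `subject_id`, `stage`, `metric`,
#'   `value` (additional entity columns are carried through).
#' @param threshold flagging threshold on the outlier probability.
#' @param min_n minimum subjects per (stage, metric) cell.
#' @param scoring `"leave_one_out"` or `"pooled"`.
#' @return The records with `density`, `probability` and `flagged` columns
#'   filled (NA where a cell was skipped), ordered deterministically.
#' @export
group_qc <- function(records, threshold = 0.05, min_n = 5,
                     scoring = c("leave_one_out", "pooled")) {
  scoring <- match.arg(scoring)
  assert_that(all(c("subject_id", "stage", "metric", "value") %in%
                    names(records)), "records must have subject_id/stage/metric/value")
  records$density <- NA_real_
  records$probability <- NA_real_
  records$flagged <- FALSE
  cells <- unique(records[, c("stage", "metric")])
  cells <- cells[order(cells$stage, cells$metric), , drop = FALSE]
  for (r in seq_len(nrow(cells))) {
    sel <- records$stage == cells$stage[r] & records$metric == cells$metric[r]
    vals <- records$value[sel]
    if (sum(is.finite(vals)) < min_n) {
      warn_pq("QC cell (%s, %s) skipped: %d subjects < %d",
              cells$stage[r], cells$metric[r], sum(is.finite(vals)), min_n)
      next
    }
    scored <- if (scoring == "pooled") {
      model <- fit_kde(vals)
      lapply(vals, function(v) outlier_probability(model, v, threshold))
    } else {
      lapply(seq_along(vals), function(i)
        outlier_probability(fit_kde_impl(vals[-i]), vals[i], threshold))
    }
    records$density[sel] <- vapply(scored, `[[`, numeric(1), "density")
    records$probability[sel] <- vapply(scored, `[[`, numeric(1), "probability")
    records$flagged[sel] <- vapply(scored, `[[`, logical(1), "flagged")
  }
  records[order(records$stage, records$metric, records$subject_id), ,
          drop = FALSE]
}
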