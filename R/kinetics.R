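#' Time-activity curves
#'
#' A TAC is the unit of kinetic modelling: activity (kBq/mL) sampled at frame
#' mid-times (minutes), with frame durations retained for duration-weighted
#' statistics.
#'
#' @param frame_mid_times minutes, strictly increasing, length >= 3.
#' @param activity kBq/mL, finite.
#' @param frame_durations minutes; `NA` allowed for instantaneous samples.
#' @param source region name or voxel index the curve was measured from.
#' @return An object of class `tac`.
#' @export
tac <- function(frame_mid_times, activity, frame_durations = NULL,
                source = NA_character_) {
  assert_that(length(frame_mid_times) >= 3, "TAC length >= 3 required")
  assert_that(length(frame_mid_times) == length(activity),
              "times and activity lengths differ")
  assert_that(all(diff(frame_mid_times) > 0),
              "frame mid-times must be strictly increasing")
  assert_that(all(is.finite(activity)), "TAC activity must be finite")
  if (is.null(frame_durations))
    frame_durations <- rep(NA_real_, length(frame_mid_times))
  structure(list(frame_mid_times = as.numeric(frame_mid_times),
                 activity = as.numeric(activity),
                 frame_durations = as.numeric(frame_durations),
                 source = source),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s: %d frames, %.3g-%.3g min, peak %.4g kBq/mL\n",
              x$source, length(x$activity), x$frame_mid_times[1],
              max(x$frame_mid_times), max(x$activity)))
  invisible(x)
}

#' Extract a regional TAC from a dynamic PET series
#'
#' Unweighted mean over the voxels of the region, per frame.
#'
#' @param pet a [dynamic_pet].
#' @param labels a [label_volume] on the PET grid.
#' @param region_id integer label id or region name.
#' @return A [tac].
#' @export
extract_tac <- function(pet, labels, region_id) {
  assert_that(all(dim(pet$frames)[1:3] == dim(labels$labels)),
              "labels must be on the PET grid")
  if (is.character(region_id)) {
    assert_that(region_id %in% names(labels$name_map),
                "unknown region name '%s'", region_id)
    nm <- region_id
    region_id <- as.integer(labels$name_map[[region_id]])
  } else {
    nm <- names(labels$name_map)[match(region_id, labels$name_map)]
    if (is.na(nm)) nm <- paste0("region", region_id)
  }
  sel <- as.integer(labels$labels) == region_id
  assert_that(any(sel), "region id %d is empty on the PET grid", region_id)
  flat <- matrix(pet$frames, ncol = dim(pet$frames)[4])
  tac(pet$frame_starts + pet$frame_durations / 2,
      colMeans(flat[sel, , drop = FALSE]),
      pet$frame_durations, source = nm)
}

# cumulative 0-anchored trapezoid of y(t) at the sample times
cumtrapz0 <- function(times, y) {
  tt <- c(0, times)
  yy <- c(0, y)
  cumsum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' Integrate a TAC from time zero
#'
#' Cumulative trapezoid from t = 0 (activity anchored at 0 there) to `T`,
#' linearly interpolating the cumulative integral at `T`. This is the
#' "TAC integral" used as the recovery measure of the coregistration and PVC
#' stages.
#'
#' @param x a [tac] or [input_curve].
#' @param T upper limit (minutes) in `[first mid-time, last mid-time]`.
#' @return Integral in kBq*min/mL.
#' @export
tac_integral <- function(x, T) {
  times <- x$frame_mid_times %||% x$times
  y <- x$activity
  assert_that(T >= times[1], "T = %.3g precedes the first sample time %.3g",
              T, times[1])
  assert_that(T <= times[length(times)],
              "T = %.3g beyond the last sample time %.3g",
              T, times[length(times)])
  cum <- cumtrapz0(times, y)
  stats::approx(c(0, times), c(0, cum), xout = T)$y
}

# linear resampling of an input function onto frame mid-times (0 before the
# first sample, constant extrapolation after the last)
input_at <- function(input, mids) {
  times <- input$frame_mid_times %||% input$times
  stats::approx(c(0, times), c(0, input$activity), xout = mids,
                yleft = 0, rule = 2)$y
}

is_reference_input <- function(input) {
  inherits(input, "tac") ||
    (inherits(input, "input_curve") && input$kind == "reference_region")
}

new_kinetic_fit <- function(model, parameters, t_star, n_points_used,
                            goodness, plot_data = NULL) {
  structure(list(model = model, parameters = parameters, t_star = t_star,
                 n_points_used = n_points_used, goodness = goodness,
                 plot_data = plot_data),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit: %s (n = %d%s)\n", x$model, x$n_points_used,
              if (is.finite(x$t_star)) sprintf(", t* = %.3g min", x$t_star)
              else ""))
  for (p in names(x$parameters))
    cat(sprintf("  %-10s %.6g\n", p, x$parameters[[p]]))
  if (!is.null(x$goodness)) cat(sprintf("  R^2        %.6g\n", x$goodness))
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) unlist(object$parameters)

#' @export
summary.kinetic_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.kinetic_fit <- function(x, ...) {
  pd <- x$plot_data
  if (is.null(pd)) {
    warning("no plot data stored for this fit")
    return(invisible(x))
  }
  graphics::plot(pd$x, pd$y, xlab = pd$xlab, ylab = pd$ylab,
                 main = sprintf("%s plot", x$model), ...)
  if (!is.null(pd$slope))
    graphics::abline(pd$intercept, pd$slope, col = "red3")
  invisible(x)
}

ols_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  assert_that(sxx > 0, "degenerate regressor in graphical fit")
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(slope = slope, intercept = intercept, r2 = r2)
}

#' Logan graphical analysis
#'
#' Reduced Logan plot: ordinary least squares of
#' `y(T) = int_0^T C_t / C_t(T)` against `x(T) = int_0^T C_in / C_t(T)` over
#' frame mid-times `>= t_star`. With a reference-region input the slope is
#' the distribution volume ratio (DVR) and `BPnd = DVR - 1` is reported; with
#' an arterial input the slope is the total distribution volume `Vt`. No
#' `k2'` correction term is applied (validation is at late times where the
#' term is negligible).
#'
#' @param tac_target a [tac] for the target region/voxel.
#' @param input a reference-region [tac] or an [input_curve].
#' @param t_star start of the linear segment (minutes).
#' @return A `kinetic_fit` with parameters `DVR` (or `Vt`), `intercept`, and
#'   `BPnd` for reference input.
#' @export
logan <- function(tac_target, input, t_star = 20) {
  mids <- tac_target$frame_mid_times
  assert_that(t_star <= mids[length(mids)],
              "t_star = %.3g beyond the last frame (%.3g min)",
              t_star, mids[length(mids)])
  use <- mids >= t_star
  assert_that(sum(use) >= 3, "Logan needs >= 3 points at/after t_star, got %d",
              sum(use))
  ct <- tac_target$activity
  assert_that(all(ct[use] > 0),
              "nonpositive target activity in the Logan window")
  cin <- input_at(input, mids)
  y <- (cumtrapz0(mids, ct) / ct)[use]
  x <- (cumtrapz0(mids, cin) / ct)[use]
  fit <- ols_fit(x, y)
  ref <- is_reference_input(input)
  params <- if (ref)
    list(DVR = fit$slope, BPnd = fit$slope - 1, intercept = fit$intercept)
  else
    list(Vt = fit$slope, intercept = fit$intercept)
  new_kinetic_fit("logan", params, t_star, sum(use), fit$r2,
                  list(x = x, y = y, slope = fit$slope,
                       intercept = fit$intercept,
                       xlab = "int C_in / C_t", ylab = "int C_t / C_t"))
}

#' Patlak-Gjedde graphical analysis
#'
#' For irreversible tracers: ordinary least squares of `C_t(T) / C_in(T)`
#' against the normalized time `x(T) = int_0^T C_in / C_in(T)` over frame
#' mid-times `>= t_star`. The slope is the net influx rate `Ki` (min^-1) and
#' the intercept the effective distribution volume `V`.
#'
#' @inheritParams logan
#' @return A `kinetic_fit` with parameters `Ki`, `V`.
#' @export
patlak <- function(tac_target, input, t_star = 20) {
  mids <- tac_target$frame_mid_times
  assert_that(t_star <= mids[length(mids)],
              "t_star = %.3g beyond the last frame (%.3g min)",
              t_star, mids[length(mids)])
  use <- mids >= t_star
  assert_that(sum(use) >= 3, "Patlak needs >= 3 points at/after t_star, got %d",
              sum(use))
  cin <- input_at(input, mids)
  assert_that(all(cin[use] > 0),
              "nonpositive input activity in the Patlak window")
  y <- (tac_target$activity / cin)[use]
  x <- (cumtrapz0(mids, cin) / cin)[use]
  fit <- ols_fit(x, y)
  new_kinetic_fit("patlak", list(Ki = fit$slope, V = fit$intercept),
                  t_star, sum(use), fit$r2,
                  list(x = x, y = y, slope = fit$slope,
                       intercept = fit$intercept,
                       xlab = "int C_in / C_in (min)", ylab = "C_t / C_in"))
}

# convolution of a piecewise-linear curve (anchored at (0, 0)) with
# exp(-lambda * t), evaluated at the curve's own sample times
exp_conv <- function(times, y, lambda) {
  tt <- c(0, times)
  yy <- c(0, y)
  out <- numeric(length(times))
  acc <- 0
  for (i in seq_along(times)) {
    dt <- tt[i + 1] - tt[i]
    c0 <- yy[i]
    m <- (yy[i + 1] - yy[i]) / dt
    e <- exp(-lambda * dt)
    if (lambda * dt < 1e-8) {
      j0 <- dt
      j1 <- dt^2 / 2
    } else {
      j0 <- (1 - e) / lambda
      j1 <- dt * (1 - e) / lambda - (1 - e * (1 + lambda * dt)) / lambda^2
    }
    acc <- acc * e + c0 * j0 + m * j1
    out[i] <- acc
  }
  out
}

#' Simplified reference tissue model (basis-function fit)
#'
#' Fits `C_t = R1 C_ref + (k2 - R1 k2a) * (C_ref (x) exp(-k2a t))` by scanning
#' a grid of apparent efflux rates `k2a`: for each candidate the model is
#' linear in `(theta1, theta2)` and solved by least squares; the `k2a`
#' minimizing the residual sum of squares wins and is then refined by
#' golden-section search within the bracketing grid interval (disable with
#' `refine = FALSE` to stay on the grid). Reported parameters:
#' `R1 = theta1`, `k2 = theta2 + R1 k2a`, `BPnd = k2 / k2a - 1`.
#'
#' @param tac_target,tac_ref target and reference-region [tac]s on the same
#'   frame grid.
#' @param k2a_grid positive sorted candidate `k2a` values (min^-1); at least
#'   2, and it should bracket the expected optimum.
#' @param refine logical; golden-section refinement of `k2a`.
#' @return A `kinetic_fit` with parameters `R1`, `k2`, `k2a`, `BPnd`.
#' @export
srtm <- function(tac_target, tac_ref,
                 k2a_grid = exp(seq(log(0.01), log(1), length.out = 30)),
                 refine = TRUE) {
  assert_that(length(k2a_grid) >= 2, "degenerate k2a grid (length < 2)")
  assert_that(all(k2a_grid > 0), "k2a grid must be positive")
  assert_that(!is.unsorted(k2a_grid), "k2a grid must be sorted")
  mids <- tac_target$frame_mid_times
  assert_that(all(abs(mids - tac_ref$frame_mid_times) < 1e-9),
              "target and reference TACs must share the frame grid")
  ct <- tac_target$activity
  cref <- tac_ref$activity
  sse_at <- function(k2a) {
    B <- exp_conv(mids, cref, k2a)
    X <- cbind(cref, B)
    th <- tryCatch(qr.solve(X, ct), error = function(e) c(NA_real_, NA_real_))
    if (anyNA(th)) return(list(sse = Inf, theta = th, B = B))
    r <- ct - X %*% th
    list(sse = sum(r^2), theta = th, B = B)
  }
  sses <- vapply(k2a_grid, function(k) sse_at(k)$sse, numeric(1))
  i <- which.min(sses)
  if (i == 1L || i == length(k2a_grid))
    warn_pq("k2a grid does not bracket the optimum (best at grid boundary)")
  k2a <- k2a_grid[i]
  if (refine && i > 1L && i < length(k2a_grid)) {
    opt <- stats::optimize(function(k) sse_at(k)$sse,
                           c(k2a_grid[i - 1], k2a_grid[i + 1]), tol = 1e-7)
    k2a <- opt$minimum
  }
  best <- sse_at(k2a)
  R1 <- as.numeric(best$theta[1])
  k2 <- as.numeric(best$theta[2]) + R1 * k2a
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot > 0) 1 - best$sse / ss_tot else 1
  new_kinetic_fit("srtm",
                  list(R1 = R1, k2 = k2, k2a = k2a, BPnd = k2 / k2a - 1),
                  NA_real_, length(ct), r2,
                  list(x = mids, y = ct, slope = NULL,
                       xlab = "time (min)", ylab = "activity (kBq/mL)"))
}

#' Standardized uptake value ratio
#'
#' Ratio of duration-weighted mean activities, target over reference, within
#' a late time window.
#'
#' @param tac_target,tac_ref [tac]s on the same frame grid.
#' @param window length-2 numeric, minutes; frames whose mid-times fall in
#'   `[window[1], window[2]]` contribute.
#' @return A `kinetic_fit` with parameter `SUVR`.
#' @export
suvr <- function(tac_target, tac_ref, window) {
  assert_that(length(window) == 2 && window[1] < window[2],
              "window must be (start, end) with start < end")
  mids <- tac_target$frame_mid_times
  use <- mids >= window[1] & mids <= window[2]
  assert_that(any(use), "empty SUVR window [%.3g, %.3g]", window[1], window[2])
  w <- tac_target$frame_durations[use]
  if (anyNA(w)) w <- rep(1, sum(use))
  mt <- sum(tac_target$activity[use] * w) / sum(w)
  mr <- sum(tac_ref$activity[use] * w) / sum(w)
  assert_that(mr > 0, "reference mean must be > 0 in the SUVR window")
  new_kinetic_fit("suvr", list(SUVR = mt / mr), NA_real_, sum(use), NULL)
}

#' Voxelwise parametric map
#'
#' Applies a kinetic model to every voxel TAC of a dynamic series. Voxels
#' failing the model's preconditions (nonpositive activity in the fit window,
#' all-zero curves, ...) are set to 0 and flagged in the failure mask, never
#' interpolated. The SRTM branch uses the basis-function grid without
#' golden-section refinement, so its resolution in `k2a` is the grid's.
#'
#' @param pet a [dynamic_pet].
#' @param input reference-region [tac] or [input_curve].
#' @param model `"logan"`, `"patlak"`, `"srtm"` or `"suvr"`.
#' @param t_star minutes, for the graphical models.
#' @param window minutes, for SUVR.
#' @param k2a_grid for SRTM.
#' @return An object of class `parametric_map`: `map` (a [volume3d] of the
#'   model's headline parameter: DVR, Ki, BPnd or SUVR), `failed` (logical
#'   array), `model`, `parameter`.
#' @export
voxelwise_map <- function(pet, input, model = c("logan", "patlak", "srtm", "suvr"),
                          t_star = 20, window = NULL,
                          k2a_grid = exp(seq(log(0.01), log(1), length.out = 30))) {
  model <- match.arg(model)
  dims <- dim(pet$frames)[1:3]
  nf <- dim(pet$frames)[4]
  V <- matrix(pet$frames, ncol = nf)
  mids <- pet$frame_starts + pet$frame_durations / 2
  cin <- input_at(input, mids)
  vals <- numeric(nrow(V))
  failed <- rep(FALSE, nrow(V))

  if (model == "suvr") {
    assert_that(!is.null(window), "suvr requires a window")
    use <- mids >= window[1] & mids <= window[2]
    assert_that(any(use), "empty SUVR window")
    w <- pet$frame_durations[use]
    mr <- sum(cin[use] * w) / sum(w)
    assert_that(mr > 0, "reference mean must be > 0 in the SUVR window")
    vals <- as.numeric(V[, use, drop = FALSE] %*% w) / sum(w) / mr
    failed <- !is.finite(vals)
  } else if (model %in% c("logan", "patlak")) {
    use <- mids >= t_star
    assert_that(sum(use) >= 3, "need >= 3 frames at/after t_star")
    # cumulative 0-anchored trapezoids, vectorized across voxels
    tt <- c(0, mids)
    CUM <- matrix(0, nrow(V), nf)
    prev <- numeric(nrow(V))
    acc <- numeric(nrow(V))
    for (f in seq_len(nf)) {
      acc <- acc + (mids[f] - tt[f]) * (V[, f] + prev) / 2
      CUM[, f] <- acc
      prev <- V[, f]
    }
    cumin <- cumtrapz0(mids, cin)
    if (model == "logan") {
      ok <- rowSums(V[, use, drop = FALSE] <= 0) == 0
      Y <- CUM[, use, drop = FALSE] / V[, use, drop = FALSE]
      X <- matrix(cumin[use], nrow(V), sum(use), byrow = TRUE) /
        V[, use, drop = FALSE]
      mX <- rowMeans(X); mY <- rowMeans(Y)
      sxx <- rowSums((X - mX)^2)
      sxy <- rowSums((X - mX) * (Y - mY))
      vals <- ifelse(ok & sxx > 0, sxy / sxx, 0)
      failed <- !(ok & sxx > 0) | !is.finite(vals)
    } else {
      assert_that(all(cin[use] > 0), "nonpositive input in the Patlak window")
      x <- (cumin / cin)[use]
      Y <- V[, use, drop = FALSE] /
        matrix(cin[use], nrow(V), sum(use), byrow = TRUE)
      mx <- mean(x); sxx <- sum((x - mx)^2)
      vals <- as.numeric((Y - rowMeans(Y)) %*% (x - mx)) / sxx
      failed <- !is.finite(vals) | rowSums(V != 0) == 0
    }
  } else { # srtm
    cref <- cin
    a11 <- sum(cref^2)
    best_sse <- rep(Inf, nrow(V))
    best <- list(th1 = vals, th2 = vals, k2a = vals)
    yy <- rowSums(V^2)
    for (k2a in k2a_grid) {
      B <- exp_conv(mids, cref, k2a)
      a12 <- sum(cref * B); a22 <- sum(B^2)
      det <- a11 * a22 - a12^2
      if (det <= 0) next
      b1 <- as.numeric(V %*% cref)
      b2 <- as.numeric(V %*% B)
      th1 <- (a22 * b1 - a12 * b2) / det
      th2 <- (a11 * b2 - a12 * b1) / det
      sse <- yy - th1 * b1 - th2 * b2
      upd <- sse < best_sse
      best_sse[upd] <- sse[upd]
      best$th1[upd] <- th1[upd]
      best$th2[upd] <- th2[upd]
      best$k2a[upd] <- k2a
    }
    k2 <- best$th2 + best$th1 * best$k2a
    vals <- ifelse(best$k2a > 0, k2 / best$k2a - 1, 0)
    failed <- !is.finite(vals) | rowSums(V != 0) == 0 | best$k2a == 0
  }
  vals[failed] <- 0
  param <- switch(model, logan = "DVR", patlak = "Ki", srtm = "BPnd",
                  suvr = "SUVR")
  structure(list(map = volume3d(array(vals, dims), pet$affine),
                 failed = array(failed, dims),
                 model = model, parameter = param),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map> %s (%s), %d/%d voxels failed\n",
              x$parameter, x$model, sum(x$failed), length(x$failed)))
  invisible(x)
}
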