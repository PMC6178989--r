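#' Input curves for kinetic modelling
#'
#' An input curve is a sampled activity curve used as the input function of a
#' kinetic model: an arterial blood/plasma curve or a reference-region curve.
#' Times are minutes, activity kBq/mL (values are stored unscaled; the declared
#' unit is recorded).
#'
#' @param times sample times (minutes), strictly increasing, length >= 3.
#' @param activity activity values, finite, same length as `times`.
#' @param kind one of `"reference_region"`, `"arterial_blood"`,
#'   `"arterial_plasma"`.
#' @param unit free-text activity unit string (recorded, not converted).
#' @return An object of class `input_curve`.
#' @export
input_curve <- function(times, activity,
                        kind = c("reference_region", "arterial_blood",
                                 "arterial_plasma"),
                        unit = "kBq/mL") {
  kind <- match.arg(kind)
  assert_that(length(times) >= 3, "input curve length >= 3 required, got %d",
              length(times))
  assert_that(length(times) == length(activity),
              "times and activity lengths differ")
  assert_that(all(diff(times) > 0), "times must be strictly increasing")
  assert_that(all(is.finite(activity)), "activity must be finite")
  structure(list(times = as.numeric(times), activity = as.numeric(activity),
                 kind = kind, unit = unit),
            class = "input_curve")
}

#' @export
print.input_curve <- function(x, ...) {
  cat(sprintf("<input_curve> %s, %d samples, %.3g-%.3g min (%s)\n",
              x$kind, length(x$times), x$times[1], max(x$times), x$unit))
  invisible(x)
}

#' Parse a Turku-style .dft input function file
#'
#' Supported dialect: lines starting with `#` are header lines; a header line
#' may declare the activity unit (e.g. `# unit := kBq/cc`) and the curve kind
#' (`# kind := plasma|blood|reference`). Data rows are whitespace-separated,
#' either `start end activity` (frame start/end, minutes; sample times are the
#' frame midpoints) or `time activity`.
#'
#' @param path path to the text file.
#' @return An [input_curve] with `kind` defaulting to `"arterial_plasma"` when
#'   the header does not declare one.
#' @export
parse_dft <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kind <- "arterial_plasma"
  unit <- "kBq/mL"
  times <- numeric(0)
  activity <- numeric(0)
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      body <- tolower(line)
      if (grepl("unit", body)) {
        m <- regmatches(line, regexpr(":=\\s*\\S+", line))
        if (length(m)) unit <- trimws(sub(":=", "", m))
      }
      if (grepl("kind", body)) {
        if (grepl("blood", body)) kind <- "arterial_blood"
        else if (grepl("plasma", body)) kind <- "arterial_plasma"
        else if (grepl("ref", body)) kind <- "reference_region"
      }
      next
    }
    fields <- strsplit(line, "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop_pq(".dft parse error at line %d: non-numeric cell in '%s'", i, line)
    if (length(vals) == 3) {
      times <- c(times, (vals[1] + vals[2]) / 2)
    } else if (length(vals) == 2) {
      times <- c(times, vals[1])
    } else {
      stop_pq(".dft parse error at line %d: expected 2 or 3 columns, got %d",
              i, length(vals))
    }
    activity <- c(activity, vals[length(vals)])
  }
  assert_that(length(times) >= 3, "input curve length >= 3 required, got %d rows",
              length(times))
  if (any(diff(times) <= 0))
    stop_pq(".dft parse error: sample times not strictly increasing")
  input_curve(times, activity, kind, unit)
}
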