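#' Concentration-time profile
#'
#' Container for one subject/analyte plasma concentration-time series after a
#' single extravascular dose. Times must be strictly increasing, all
#' concentrations non-negative and the dose positive. When a lower limit of
#' quantification (`lloq`) is given, post-dose concentrations below it are
#' flagged as below-the-limit-of-quantification (BLQ); compartmental fitting
#' drops flagged points while non-compartmental summaries treat them as
#' missing. A zero concentration at time 0 (pre-dose) is always kept as a
#' genuine observation.
#'
#' @param subject_id character scalar identifying the subject (or "mean" for a
#'   group-mean profile).
#' @param analyte character scalar, name of the measured compound.
#' @param dose administered dose in mg/kg body weight; must be positive.
#' @param times sampling times in hours, strictly increasing.
#' @param conc plasma concentrations in ng/mL, one per time, all `>= 0`
#'   (missing values allowed and propagated as `NA`).
#' @param lloq optional lower limit of quantification in ng/mL.
#'
#' @return An object of class `conc_profile`: a list with the validated fields
#'   plus a logical `blq` flag vector.
#' @examples
#' cp <- conc_profile("r1", "baicalin", 23.04, c(0, 0.5, 1), c(0, 120, 60))
#' cp
#' @export
conc_profile <- function(subject_id, analyte, dose, times, conc, lloq = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  stopifnot(is.character(analyte), length(analyte) == 1L)
  if (!is_number(dose) || dose <= 0) stop_input("dose must be a single positive number (mg/kg)")
  times <- as.numeric(times); conc <- as.numeric(conc)
  if (length(times) != length(conc))
    stop_input("times and conc must have equal length (%d vs %d)", length(times), length(conc))
  if (anyNA(times)) stop_input("times must not contain NA")
  if (any(diff(times) <= 0)) stop_input("times must be strictly increasing")
  if (any(conc < 0, na.rm = TRUE)) stop_input("all concentrations must be >= 0")
  if (!is.null(lloq) && (!is_number(lloq) || lloq <= 0)) stop_input("lloq must be a positive number")
  blq <- if (is.null(lloq)) rep(FALSE, length(conc)) else !is.na(conc) & conc < lloq & times > 0
  structure(
    list(subject_id = subject_id, analyte = analyte, dose = dose,
         times = times, conc = conc, lloq = lloq, blq = blq),
    class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> %s / %s, dose %.4g mg/kg, %d samples over %.3g-%.3g h\n",
              x$subject_id, x$analyte, x$dose, length(x$times), min(x$times), max(x$times)))
  if (any(x$blq)) cat(sprintf("  %d observation(s) below LLOQ (%.3g ng/mL)\n", sum(x$blq), x$lloq))
  print(data.frame(time = x$times, conc = x$conc), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.conc_profile <- function(x, ...) {
  data.frame(subject = x$subject_id, analyte = x$analyte,
             time = x$times, conc = x$conc, stringsAsFactors = FALSE)
}

#' Temperature (or temperature-change) time profile
#'
#' Holds either raw rectal temperatures (`temp`, degrees C, together with the
#' pre-dose `baseline`) or a derived control-corrected temperature change
#' series (`delta_t`, degrees C). Exactly one of `temp`/`delta_t` must be
#' supplied. Group labels follow the four-arm antipyresis design: normal
#' control (NCG), normal treated (NTG), pyrexia-model control (MCG) and
#' pyrexia-model treated (MTG).
#'
#' @param subject_id character scalar.
#' @param group one of `"NCG"`, `"NTG"`, `"MCG"`, `"MTG"`.
#' @param times measurement times in hours, strictly increasing.
#' @param temp rectal temperatures in degrees C (exclusive with `delta_t`).
#' @param delta_t temperature-change values in degrees C.
#' @param baseline pre-dose basal temperature in degrees C (required with
#'   `temp`).
#' @return An object of class `temp_profile`.
#' @examples
#' temp_profile("mean", "MTG", c(0, 1, 2), delta_t = c(0.06, 1.08, 0.25))
#' @export
temp_profile <- function(subject_id, group, times, temp = NULL, delta_t = NULL,
                         baseline = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  group <- match.arg(group, c("NCG", "NTG", "MCG", "MTG"))
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop_input("times must be strictly increasing")
  if (is.null(temp) == is.null(delta_t))
    stop_input("exactly one of temp or delta_t must be supplied")
  if (!is.null(temp)) {
    temp <- as.numeric(temp)
    if (length(temp) != length(times)) stop_input("temp and times must have equal length")
    if (is.null(baseline) || !is_number(baseline))
      stop_input("baseline temperature is required when temp is supplied")
  } else {
    delta_t <- as.numeric(delta_t)
    if (length(delta_t) != length(times)) stop_input("delta_t and times must have equal length")
  }
  structure(
    list(subject_id = subject_id, group = group, times = times,
         temp = temp, delta_t = delta_t, baseline = baseline),
    class = "temp_profile")
}

#' @export
print.temp_profile <- function(x, ...) {
  kind <- if (is.null(x$delta_t)) "rectal temperature" else "temperature change (deltaT)"
  cat(sprintf("<temp_profile> %s / %s, %s, %d points over %.3g-%.3g h\n",
              x$subject_id, x$group, kind, length(x$times), min(x$times), max(x$times)))
  df <- data.frame(time = x$times)
  if (is.null(x$delta_t)) df$temp <- x$temp else df$delta_t <- x$delta_t
  print(df, row.names = FALSE)
  invisible(x)
}

#' Control-corrected temperature change
#'
#' Computes the antipyresis endpoint from paired treated and control
#' temperature series measured on the same time grid:
#' `dT(t) = (T_treated(t) - T_treated(0)) - (T_control(t) - T_control(0))`,
#' where the time-0 values are the pre-dose baselines carried by each profile.
#' The sign convention is that positive values mean the treated group rose
#' more than the control group; the antipyretic suppression magnitude is the
#' negative of this quantity.
#'
#' @param treated,control `temp_profile` objects carrying raw temperatures and
#'   baselines, on identical time grids. No interpolation is performed:
#'   mismatched grids are an error.
#' @return A `temp_profile` in `delta_t` form on the shared grid, with the
#'   treated profile's subject id and group.
#' @examples
#' trt <- temp_profile("m", "MTG", c(1), temp = 38.5, baseline = 38.0)
#' ctl <- temp_profile("m", "MCG", c(1), temp = 39.2, baseline = 38.1)
#' delta_t(trt, ctl)$delta_t  # -0.6
#' @export
delta_t <- function(treated, control) {
  stopifnot(inherits(treated, "temp_profile"), inherits(control, "temp_profile"))
  if (is.null(treated$temp) || is.null(control$temp))
    stop_input("both profiles must carry raw temperatures and baselines")
  if (length(treated$times) != length(control$times) ||
      any(treated$times != control$times))
    stop_input("treated and control profiles must share an identical time grid")
  dt <- (treated$temp - treated$baseline) - (control$temp - control$baseline)
  temp_profile(treated$subject_id, treated$group, treated$times, delta_t = dt)
}

autodetect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read concentration-time tables
#'
#' Reads a delimited text file with header columns `subject`, `analyte`,
#' `time` (h) and `conc` (ng/mL) into a list of [conc_profile] objects, one
#' per `(subject, analyte)` pair, each sorted by time. Duplicated
#' `(subject, analyte, time)` rows and non-numeric `time`/`conc` cells are
#' hard errors naming the offending row.
#'
#' @param path file path; comma- or tab-delimited (auto-detected unless `sep`
#'   is given).
#' @param dose either a single dose (mg/kg) applied to every profile or a
#'   named vector/list keyed by analyte.
#' @param sep field separator; `NULL` to auto-detect.
#' @param lloq optional LLOQ (ng/mL) forwarded to [conc_profile].
#' @return A list of `conc_profile` objects, named `subject:analyte`.
#' @export
read_conc_table <- function(path, dose, sep = NULL, lloq = NULL) {
  sep <- sep %||% autodetect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("subject", "analyte", "time", "conc")
  if (!all(need %in% names(raw)))
    stop_input("input must have header columns: %s", paste(need, collapse = ", "))
  for (col in c("time", "conc")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & !(raw[[col]] %in% c("", "NA")))
    if (length(bad))
      stop_input("non-numeric %s value '%s' in row %d", col, raw[[col]][bad[1]], bad[1])
    raw[[col]] <- num
  }
  key <- paste(raw$subject, raw$analyte, raw$time, sep = "\r")
  if (anyDuplicated(key))
    stop_input("duplicate (subject, analyte, time) in row %d", which(duplicated(key))[1])
  out <- list()
  for (grp in split(raw, paste(raw$subject, raw$analyte, sep = ":"))) {
    grp <- grp[order(grp$time), ]
    an <- grp$analyte[1]
    d <- if (length(dose) > 1L || !is.null(names(dose))) {
      if (is.null(names(dose)) || !an %in% names(dose))
        stop_input("no dose supplied for analyte '%s'", an)
      as.numeric(dose[[an]])
    } else as.numeric(dose)
    out[[paste(grp$subject[1], an, sep = ":")]] <-
      conc_profile(grp$subject[1], an, d, grp$time, grp$conc, lloq = lloq)
  }
  out
}

#' Write concentration profiles to delimited text
#'
#' Inverse of [read_conc_table]; numbers are written with 15 significant
#' digits so a write/read round trip reproduces the profile exactly.
#'
#' @param profiles a `conc_profile` or list of them.
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_conc_table <- function(profiles, path, sep = ",") {
  if (inherits(profiles, "conc_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, as.data.frame))
  df$time <- format(df$time, digits = 15, trim = TRUE, scientific = FALSE)
  df$conc <- format(df$conc, digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read temperature tables
#'
#' Reads a delimited file with header columns `subject`, `group`, `time` and
#' one of `temp`/`delta_t` into a list of [temp_profile] objects.
#'
#' @inheritParams read_conc_table
#' @param baseline optional named vector of basal temperatures keyed by
#'   subject (required when the file carries raw `temp`).
#' @return A list of `temp_profile` objects named by subject.
#' @export
read_temp_table <- function(path, sep = NULL, baseline = NULL) {
  sep <- sep %||% autodetect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           strip.white = TRUE)
  if (!all(c("subject", "group", "time") %in% names(raw)))
    stop_input("input must have header columns subject, group, time and temp or delta_t")
  value_col <- intersect(c("temp", "delta_t"), names(raw))
  if (length(value_col) != 1L) stop_input("exactly one of temp/delta_t columns required")
  out <- list()
  for (grp in split(raw, raw$subject)) {
    grp <- grp[order(grp$time), ]
    sid <- as.character(grp$subject[1])
    if (value_col == "temp") {
      out[[sid]] <- temp_profile(sid, grp$group[1], grp$time, temp = grp$temp,
                                 baseline = as.numeric(baseline[[sid]]))
    } else {
      out[[sid]] <- temp_profile(sid, grp$group[1], grp$time, delta_t = grp$delta_t)
    }
  }
  out
}
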