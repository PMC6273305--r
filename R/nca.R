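## Non-compartmental analysis: terminal-slope estimation and the standard
## exposure/residence summary for a single extravascular profile.

#' Terminal elimination rate constant
#'
#' Estimates `lambda_z` by log-linear regression of the terminal
#' concentrations. Candidate windows are every run of the last `k >= 3`
#' positive, non-BLQ concentrations strictly after Tmax; the window with the
#' best adjusted R-squared wins, ties (within `1e-4`) broken toward more
#' points. A non-negative best slope (rising or flat tail) is an error.
#'
#' @param profile a [conc_profile].
#' @param min_points minimum number of terminal points (default 3).
#' @param n_points optional fixed window size: use exactly the last
#'   `n_points` points after Tmax instead of the automatic search (the usual
#'   manual override of NCA software).
#' @return A list with `lambda_z` (1/h), `n_points`, `r2_adj` and
#'   `intercept` (log ng/mL, at time 0).
#' @examples
#' p <- conc_profile("s", "x", 1, c(1, 2, 4, 6), 1000 * exp(-0.5 * c(1, 2, 4, 6)))
#' estimate_lambda_z(p)$lambda_z  # 0.5
#' @export
estimate_lambda_z <- function(profile, min_points = 3, n_points = NULL) {
  stopifnot(inherits(profile, "conc_profile"))
  ok <- !is.na(profile$conc) & profile$conc > 0 & !profile$blq
  t <- profile$times[ok]; y <- profile$conc[ok]
  if (length(y) < min_points) stop_input("insufficient terminal phase: fewer than %d positive points", min_points)
  i_max <- which.max(y)
  idx <- seq_along(y)[seq_along(y) > i_max]
  if (length(idx) < (n_points %||% min_points))
    stop_input("insufficient terminal phase: fewer than %d points after tmax",
               n_points %||% min_points)
  loglin <- function(sel) {
    # closed-form least squares of log(conc) on time, R2 robust to exact fits
    tt <- t[sel]; ly <- log(y[sel])
    sxx <- sum((tt - mean(tt))^2)
    slope <- sum((tt - mean(tt)) * (ly - mean(ly))) / sxx
    sse <- sum((ly - mean(ly) - slope * (tt - mean(tt)))^2)
    sst <- sum((ly - mean(ly))^2)
    r2 <- if (sst <= .Machine$double.eps * length(sel)) 1 else 1 - sse / sst
    k <- length(sel)
    list(lambda_z = -slope, n_points = k,
         r2_adj = 1 - (1 - r2) * (k - 1) / (k - 2),
         intercept = mean(ly) - slope * mean(tt))
  }
  sizes <- if (is.null(n_points)) seq(min_points, length(idx)) else n_points
  best <- NULL
  for (k in sizes) {
    cand <- loglin(utils::tail(idx, k))
    if (cand$lambda_z <= 0) next
    if (is.null(best) || cand$r2_adj > best$r2_adj + 1e-4 ||
        (abs(cand$r2_adj - best$r2_adj) <= 1e-4 && k > best$n_points)) {
      best <- cand
    }
  }
  if (is.null(best)) stop_input("insufficient terminal phase: no declining terminal window")
  best
}

trapz_segments <- function(t, y, method = c("linlog", "linear")) {
  ## per-interval AUC and AUMC increments; "linlog" = linear-up/log-down
  method <- match.arg(method)
  n <- length(t)
  dt <- diff(t)
  y1 <- y[-n]; y2 <- y[-1]; t1 <- t[-n]; t2 <- t[-1]
  auc <- (y1 + y2) / 2 * dt
  aumc <- (t1 * y1 + t2 * y2) / 2 * dt
  if (method == "linlog") {
    logdown <- y2 < y1 & y2 > 0 & y1 > 0
    if (any(logdown)) {
      lam <- log(y1[logdown] / y2[logdown]) / dt[logdown]
      auc[logdown] <- (y1[logdown] - y2[logdown]) / lam
      aumc[logdown] <- (t1[logdown] * y1[logdown] - t2[logdown] * y2[logdown]) / lam +
        (y1[logdown] - y2[logdown]) / lam^2
    }
  }
  list(auc = auc, aumc = aumc)
}

#' Non-compartmental analysis of a concentration profile
#'
#' Computes the standard single-dose extravascular NCA parameter set: Cmax
#' and Tmax read off the data, `lambda_z` and `t_half` from
#' [estimate_lambda_z], AUC/AUMC by the trapezoidal rule (linear-up/log-down
#' by default, pure linear on request), extrapolation to infinity through
#' `C_last / lambda_z` tail terms, mean residence times as AUMC/AUC, and
#' apparent clearance `CL/F = dose / AUC_0_inf`. BLQ-flagged or missing
#' concentrations are excluded from the trapezoid. If the terminal slope
#' cannot be estimated the 0-t quantities are still returned and all
#' infinity-extrapolated fields are `NA`.
#'
#' @param profile a [conc_profile].
#' @param auc_method `"linlog"` (linear-up/log-down, default) or `"linear"`.
#' @param min_points minimum terminal points for `lambda_z`.
#' @return An object of class `nca_result`: list with fields `cmax` (ng/mL),
#'   `tmax` (h), `lambda_z` (1/h), `t_half` (h), `auc_0_t`, `auc_0_inf`
#'   (h*ng/mL), `aumc_0_t` (h^2*ng/mL), `mrt_0_t`, `mrt_0_inf` (h), `cl_f`
#'   (dose/AUC, (mg/kg)/(h*ng/mL)), `n_lambda_points`, `r2_adj`.
#' @examples
#' fx <- qkl_fixture()
#' run_nca(fx$conc_baicalin)
#' @export
run_nca <- function(profile, auc_method = c("linlog", "linear"), min_points = 3) {
  stopifnot(inherits(profile, "conc_profile"))
  auc_method <- match.arg(auc_method)
  keep <- !is.na(profile$conc) & !profile$blq
  t <- profile$times[keep]; y <- profile$conc[keep]
  if (length(y) < 3) stop_input("need at least 3 usable observations for NCA")
  i <- which.max(y)
  seg <- trapz_segments(t, y, auc_method)
  auc_0_t <- sum(seg$auc); aumc_0_t <- sum(seg$aumc)
  lz <- tryCatch(estimate_lambda_z(profile, min_points), error = function(e) NULL)
  c_last <- y[length(y)]; t_last <- t[length(t)]
  if (!is.null(lz)) {
    auc_0_inf <- auc_0_t + c_last / lz$lambda_z
    aumc_0_inf <- aumc_0_t + c_last * t_last / lz$lambda_z + c_last / lz$lambda_z^2
    res <- list(cmax = y[i], tmax = t[i],
                lambda_z = lz$lambda_z, t_half = log(2) / lz$lambda_z,
                auc_0_t = auc_0_t, auc_0_inf = auc_0_inf,
                aumc_0_t = aumc_0_t,
                mrt_0_t = aumc_0_t / auc_0_t, mrt_0_inf = aumc_0_inf / auc_0_inf,
                cl_f = profile$dose / auc_0_inf,
                n_lambda_points = lz$n_points, r2_adj = lz$r2_adj)
  } else {
    res <- list(cmax = y[i], tmax = t[i], lambda_z = NA_real_, t_half = NA_real_,
                auc_0_t = auc_0_t, auc_0_inf = NA_real_, aumc_0_t = aumc_0_t,
                mrt_0_t = aumc_0_t / auc_0_t, mrt_0_inf = NA_real_, cl_f = NA_real_,
                n_lambda_points = NA_integer_, r2_adj = NA_real_)
  }
  res$subject_id <- profile$subject_id
  res$analyte <- profile$analyte
  res$auc_method <- auc_method
  class(res) <- "nca_result"
  res
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> %s / %s (AUC: %s)\n", x$subject_id, x$analyte, x$auc_method))
  flds <- c("cmax", "tmax", "lambda_z", "t_half", "auc_0_t", "auc_0_inf",
            "aumc_0_t", "mrt_0_t", "mrt_0_inf", "cl_f", "n_lambda_points", "r2_adj")
  v <- vapply(flds, function(f) as.numeric(x[[f]] %||% NA), numeric(1))
  print(signif(v, 6))
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  flds <- c("cmax", "tmax", "lambda_z", "t_half", "auc_0_t", "auc_0_inf",
            "aumc_0_t", "mrt_0_t", "mrt_0_inf", "cl_f", "n_lambda_points", "r2_adj")
  cbind(data.frame(subject = x$subject_id, analyte = x$analyte),
        as.data.frame(setNames(lapply(flds, function(f) x[[f]]), flds)))
}
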