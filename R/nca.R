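#' Non-compartmental analysis of a concentration-time profile
#'
#' Computes Cmax and Tmax from the grid (ties at Cmax resolved to the earliest
#' time), AUC to the last point by the linear-up/log-down trapezoid rule, the
#' terminal rate constant lambda_z by log-linear regression on the last
#' `lambda_z_points` positive concentrations, AUC extrapolated to infinity as
#' `AUC_last + C_last / lambda_z`, and the terminal half-life `ln 2 /
#' lambda_z`.
#'
#' @param profile A data frame with columns `time` (h, strictly increasing)
#'   and `conc` (ug/mL). Rows flagged in an optional logical `blq` column are
#'   dropped first.
#' @param lambda_z_points Number of terminal points used for the log-linear
#'   fit (default 5).
#' @return A one-row tibble: `cmax`, `tmax`, `lambda_z`, `auc_last`,
#'   `auc_inf`, `t_half`, plus `lambda_z_points` and `auc_method` metadata
#'   columns.
#' @export
nca <- function(profile, lambda_z_points = 5) {
  stopifnot(all(c("time", "conc") %in% names(profile)))
  if ("blq" %in% names(profile)) profile <- profile[!profile$blq, ]
  tt <- profile$time
  cc <- profile$conc
  if (is.unsorted(tt, strictly = TRUE)) {
    abort("times must be strictly increasing", class = "lymphpbpk_nca_error")
  }
  if (sum(cc > 0) < 3) {
    abort("need at least 3 positive concentrations",
          class = "lymphpbpk_nca_error")
  }
  if (diff(range(cc)) == 0) {
    abort("flat profile: lambda_z undefined", class = "lymphpbpk_nca_error")
  }

  cmax <- max(cc)
  tmax <- tt[which.max(cc)]  # earliest time at the maximum

  auc_last <- auc_lin_up_log_down(tt, cc)

  pos <- which(cc > 0)
  k <- min(lambda_z_points, length(pos))
  term <- utils::tail(pos, k)
  fit <- stats::lm(log(cc[term]) ~ tt[term])
  lambda_z <- -unname(stats::coef(fit)[2])
  if (!is.finite(lambda_z) || lambda_z <= 0) {
    abort("non-positive terminal slope: lambda_z undefined",
          class = "lymphpbpk_nca_error")
  }
  c_last <- cc[utils::tail(pos, 1)]
  auc_inf <- auc_last + c_last / lambda_z

  tibble(
    cmax = cmax, tmax = tmax, lambda_z = lambda_z,
    auc_last = auc_last, auc_inf = auc_inf, t_half = log(2) / lambda_z,
    lambda_z_points = k, auc_method = "linear-up/log-down"
  )
}

# Linear trapezoid while concentrations rise (or touch zero), logarithmic
# trapezoid while they fall -- the standard PK convention.
auc_lin_up_log_down <- function(tt, cc) {
  dt <- diff(tt)
  c1 <- cc[-length(cc)]
  c2 <- cc[-1]
  lin <- (c1 + c2) / 2 * dt
  logd <- ifelse(c1 > 0 & c2 > 0 & c2 < c1,
                 (c1 - c2) / log(c1 / c2) * dt, lin)
  sum(logd)
}
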