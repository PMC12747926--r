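# Product-limit (Kaplan-Meier) estimation for drug survival.
#
# S(t) = prod over event times t_i <= t of (1 - d_i / n_i), with ties handled
# by processing events before censorings at the same time.  Greenwood's
# formula gives Var(log S) = sum d_i / (n_i (n_i - d_i)); the default 95% CI
# uses the log(-log) transformation, S^exp(+/- z * se(log S) / log S), which
# keeps bounds in [0, 1].

#' Fit a Kaplan-Meier curve
#'
#' @param time Positive times in days (or a data frame with `time` and
#'   `event` columns).
#' @param event Event indicator: 1 = event, 0 = censored.
#' @param conf_type `"log-log"` (default) or `"plain"` (Greenwood on the
#'   identity scale, truncated to `[0, 1]`).
#' @param conf_level Confidence level (default 0.95).
#' @return A `km_curve` object: tibble of distinct observed times with
#'   `n_risk`, `n_event`, `n_censor`, `survival`, `greenwood_var` (variance of
#'   log S), `ci_low`, `ci_high`, plus attributes `n` and `conf_type`.
#' @export
km_fit <- function(time, event = NULL, conf_type = c("log-log", "plain"),
                   conf_level = 0.95) {
  if (is.data.frame(time)) {
    event <- time$event
    time <- time$time
  }
  conf_type <- match.arg(conf_type)
  if (!length(time)) abort("km_fit needs at least one observation")
  if (any(time < 1)) abort("times must be >= 1 day")
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))

  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  n <- length(time)

  tab <- tibble::tibble(time = time, event = event) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(n_event = sum(.data$event),
                     n_censor = sum(1 - .data$event), .groups = "drop")
  tab$n_risk <- n - dplyr::lag(cumsum(tab$n_event + tab$n_censor), default = 0)
  frac <- 1 - tab$n_event / tab$n_risk
  tab$survival <- cumprod(frac)
  gw_term <- ifelse(tab$n_risk > tab$n_event,
                    tab$n_event / (tab$n_risk * (tab$n_risk - tab$n_event)),
                    Inf)
  gw_term[tab$n_event == 0] <- 0
  tab$greenwood_var <- cumsum(gw_term)

  z <- qnorm(1 - (1 - conf_level) / 2)
  s <- tab$survival
  se_log <- sqrt(tab$greenwood_var)
  if (conf_type == "log-log") {
    ok <- s > 0 & s < 1 & is.finite(se_log)
    lo <- hi <- rep(NA_real_, nrow(tab))
    a <- se_log[ok] / log(s[ok])  # negative, since log S < 0
    lo[ok] <- s[ok]^exp(-z * a)
    hi[ok] <- s[ok]^exp(+z * a)
    lo[s == 1] <- 1; hi[s == 1] <- 1
    lo[s == 0] <- 0; hi[s == 0] <- 0
  } else {
    se_s <- s * se_log
    lo <- pmax(0, s - z * se_s)
    hi <- pmin(1, s + z * se_s)
  }
  tab$ci_low <- lo
  tab$ci_high <- hi
  tab <- dplyr::relocate(tab, "time", "n_risk", "n_event", "n_censor")

  structure(list(table = tab, n = n, conf_type = conf_type,
                 conf_level = conf_level),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n = ", x$n, ", ", sum(x$table$n_event), " events, ",
      "median = ", format(km_median(x)), " (", x$conf_type, " CI)\n", sep = "")
  invisible(x)
}

#' Survival probability at a time point
#'
#' Step-function evaluation: the estimate at the last observed time <= `t`
#' (1 before the first).
#'
#' @param curve A `km_curve`.
#' @param t Time(s) in the fitted scale.
#' @param what `"survival"`, `"ci_low"` or `"ci_high"`.
#' @return Numeric vector.
#' @export
km_survival_at <- function(curve, t, what = "survival") {
  tab <- curve$table
  idx <- findInterval(t, tab$time)
  out <- rep(1, length(t))
  if (what != "survival") out[] <- NA_real_
  out[idx > 0] <- tab[[what]][idx[idx > 0]]
  out
}

#' Median survival time
#'
#' Smallest event time at which S(t) drops to 0.5 or below; `NA` when the
#' curve never reaches 0.5.
#'
#' @param curve A `km_curve`.
#' @return Numeric scalar (same unit as the fitted times) or `NA`.
#' @export
km_median <- function(curve) {
  tab <- curve$table[curve$table$n_event > 0, , drop = FALSE]
  hit <- which(tab$survival <= 0.5 + 1e-12)
  if (!length(hit)) return(NA_real_)
  tab$time[hit[1]]
}

#' Cumulative discontinuation at a horizon
#'
#' `1 - S(horizon)` with the transformed CI evaluated at the last event time
#' on or before the horizon.  Horizons are given in years (365.25 days/year).
#'
#' @param curve A `km_curve` fitted on days.
#' @param horizon_years Numeric vector of horizons (e.g. `c(1, 3, 5)`).
#' @return A tibble: `horizon_years`, `rate` (percent), `ci_low`, `ci_high`
#'   (percent bounds).
#' @export
cumulative_discontinuation <- function(curve, horizon_years = c(1, 3, 5)) {
  purrr::map_dfr(horizon_years, function(h) {
    t_h <- round(h * 365.25)
    ev <- curve$table[curve$table$n_event > 0 & curve$table$time <= t_h, ,
                      drop = FALSE]
    if (!nrow(ev)) {
      return(tibble::tibble(horizon_years = h, rate = 0, ci_low = 0, ci_high = 0))
    }
    last <- ev[nrow(ev), ]
    tibble::tibble(
      horizon_years = h,
      rate = 100 * (1 - last$survival),
      ci_low = 100 * (1 - last$ci_high),
      ci_high = 100 * (1 - last$ci_low)
    )
  })
}

#' Time from interruption to biologic restart
#'
#' Among courses with a treatment interruption (restart or discontinuation
#' patterns), measures days from the index episode end to the first later
#' biologic fill; courses that never restart are censored at follow-up end.
#'
#' @param courses Course tibble from [build_courses()].
#' @return A `km_curve`, or `NULL` when no course has an interruption.
#' @export
time_to_restart <- function(courses) {
  interrupted <- courses[courses$pattern %in% c("restart", "discontinuation"), ,
                         drop = FALSE]
  if (!nrow(interrupted)) return(NULL)
  is_restart <- interrupted$pattern == "restart"
  time <- ifelse(is_restart,
                 interrupted$gap_to_restart_days,
                 as.numeric(interrupted$followup_end -
                              interrupted$index_episode_end))
  km_fit(pmax(1, time), as.integer(is_restart))
}

#' @exportS3Method generics::tidy
tidy.km_curve <- function(x, ...) {
  dplyr::rename(x$table, estimate = "survival", std_error_log = "greenwood_var")
}

#' @exportS3Method generics::glance
glance.km_curve <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    events = sum(x$table$n_event),
    median = km_median(x),
    conf_type = x$conf_type
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.km_curve <- function(object, ...) {
  tab <- object$table
  t0 <- c(0, tab$time); s0 <- c(1, tab$survival)
  lo0 <- c(1, tab$ci_low); hi0 <- c(1, tab$ci_high)
  k <- length(t0)
  # expand to explicit step coordinates so the CI ribbon steps with the curve
  steps <- tibble::tibble(
    time = c(t0[1], rep(t0[-1], each = 2)),
    survival = c(rep(s0[-k], each = 2), s0[k]),
    ci_low = c(rep(lo0[-k], each = 2), lo0[k]),
    ci_high = c(rep(hi0[-k], each = 2), hi0[k])
  )
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "S(t)") +
    ggplot2::theme_minimal()
}
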