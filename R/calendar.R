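#' Treatment calendar
#'
#' A dated, timed list of fraction sessions.  Sessions are sorted
#' chronologically; at most two sessions per calendar day are allowed.
#' Scheduling-rule compliance (weekly fraction limit, consecutive
#' twice-daily days, minimum interfraction interval) is checked separately
#' by [validate_schedule()], which reports violations without mutating.
#'
#' @param date Session dates (`Date` or coercible).
#' @param time Session start times in hours since midnight.
#' @param dose Dose per fraction in Gy (recycled).
#' @return An object of class `treatment_calendar`: a data.frame with
#'   columns `date`, `time`, `dose`.
#' @export
treatment_calendar <- function(date, time = 9, dose = 2) {
  date <- as.Date(date)
  n <- length(date)
  time <- rep_len(time, n)
  dose <- rep_len(dose, n)
  ord <- order(date, time)
  cal <- data.frame(date = date[ord], time = time[ord], dose = dose[ord])
  dt <- as.numeric(cal$date) * 24 + cal$time
  if (n > 1 && any(diff(dt) <= 0))
    abort_isodvh("sessions must be strictly ordered in time", "calendar")
  if (any(table(cal$date) > 2))
    abort_isodvh("at most two sessions per calendar day", "calendar")
  class(cal) <- c("treatment_calendar", "data.frame")
  cal
}

#' Overall treatment time of a calendar
#'
#' Counted inclusively in calendar days -- weekends and gap days included:
#' `(last session date - first session date) + 1`.
#'
#' @param calendar A [treatment_calendar()].
#' @return Overall time T in days.
#' @export
overall_time <- function(calendar) {
  stopifnot(inherits(calendar, "treatment_calendar"))
  if (nrow(calendar) == 0L)
    abort_isodvh("calendar has no sessions", "calendar")
  as.integer(max(calendar$date) - min(calendar$date)) + 1L
}

#' Check a calendar against gap-compensation scheduling constraints
#'
#' Flags, without mutating: more than 6 fractions in any ISO (Monday--Sunday)
#' week; twice-daily fractionation on consecutive calendar days; same-day
#' sessions less than 6 hours apart (the minimum recommended interval).
#'
#' @param calendar A [treatment_calendar()].
#' @param max_per_week Weekly fraction limit (default 6).
#' @param min_interval Minimum same-day interfraction interval in hours.
#' @return A data.frame of violations with columns `rule`, `where`,
#'   `detail`; zero rows when the schedule is compliant.
#' @export
validate_schedule <- function(calendar, max_per_week = 6, min_interval = 6) {
  stopifnot(inherits(calendar, "treatment_calendar"))
  v <- list()
  add <- function(rule, where, detail)
    v[[length(v) + 1L]] <<- data.frame(rule = rule, where = where,
                                       detail = detail)
  wk <- format(calendar$date, "%G-W%V")   # ISO week, Monday-based
  per_week <- table(wk)
  for (w in names(per_week)[per_week > max_per_week])
    add("weekly_limit", w,
        sprintf("%d fractions in week %s (limit %d)", per_week[[w]], w,
                max_per_week))
  per_day <- table(calendar$date)
  bid_days <- sort(as.Date(names(per_day)[per_day == 2]))
  if (length(bid_days) > 1) {
    consec <- which(diff(bid_days) == 1)
    for (i in consec)
      add("consecutive_bid", as.character(bid_days[i]),
          sprintf("twice-daily on consecutive days %s and %s",
                  bid_days[i], bid_days[i + 1]))
  }
  for (d in names(per_day)[per_day == 2]) {
    tt <- sort(calendar$time[calendar$date == as.Date(d)])
    if (diff(tt) < min_interval)
      add("min_interval", d,
          sprintf("same-day interval %.2g h < %g h on %s", diff(tt),
                  min_interval, d))
  }
  if (length(v) == 0L)
    data.frame(rule = character(0), where = character(0),
               detail = character(0))
  else do.call(rbind, v)
}

#' Summarize a calendar as a scalar schedule
#'
#' @param calendar A [treatment_calendar()].
#' @return A [schedule_summary()] with `N` = session count, `d` the (single)
#'   dose per fraction, `T` from [overall_time()], `TD` the number of
#'   twice-daily days, and `m` the minimum same-day interval.
#' @export
calendar_summary <- function(calendar) {
  stopifnot(inherits(calendar, "treatment_calendar"))
  per_day <- table(calendar$date)
  td <- sum(per_day == 2)
  m <- 6
  if (td > 0) {
    ivals <- vapply(names(per_day)[per_day == 2], function(d)
      diff(sort(calendar$time[calendar$date == as.Date(d)])), numeric(1))
    m <- min(ivals)
  }
  d <- unique(calendar$dose)
  if (length(d) != 1L)
    abort_isodvh("calendar mixes doses per fraction; summarize segments separately",
                 "calendar")
  schedule_summary(nrow(calendar), d, overall_time(calendar), TD = td, m = m)
}

#' Build a weekday treatment calendar
#'
#' Convenience generator: schedules `n` fractions of `d` Gy starting at
#' `start`, treating on the given weekdays (default Monday--Friday), with an
#' optional set of twice-daily dates (second session `bid_interval` hours
#' after the first) and an optional gap during which no sessions occur.
#'
#' @param start First treatment date.
#' @param n Number of fractions.
#' @param d Dose per fraction (Gy).
#' @param weekdays Treatment weekdays, 1 = Monday ... 7 = Sunday.
#' @param bid_dates Dates receiving two fractions.
#' @param bid_interval Same-day interfraction interval in hours.
#' @param gap Optional `Date` vector (range of days with no sessions).
#' @param first_time Start time of the (first) daily session, hours.
#' @return A [treatment_calendar()].
#' @export
make_calendar <- function(start, n, d, weekdays = 1:5,
                          bid_dates = as.Date(character()), bid_interval = 6,
                          gap = as.Date(character()), first_time = 9) {
  start <- as.Date(start)
  bid_dates <- as.Date(bid_dates)
  dates <- numeric(0); times <- numeric(0)
  day <- start
  while (length(dates) < n) {
    iso_wd <- ((as.integer(day) + 3L) %% 7L) + 1L  # 1970-01-01 = Thursday
    if (iso_wd %in% weekdays && !(day %in% gap)) {
      dates <- c(dates, day); times <- c(times, first_time)
      if (day %in% bid_dates && length(dates) < n) {
        dates <- c(dates, day); times <- c(times, first_time + bid_interval)
      }
    }
    day <- day + 1
  }
  treatment_calendar(as.Date(dates, origin = "1970-01-01"), times, d)
}
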