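#' First-order decay rate from a half-life
#'
#' Growth factors degrade in culture media by first-order (half-life) decay,
#' `C(t) = C0 * exp(k t)` with `k = ln(0.5) / t_half`. The returned rate is
#' negative; `exp(k * t_half) = 0.5` by construction.
#'
#' @param half_life Half-life (s), strictly positive.
#' @return Decay rate k (1/s), negative.
#' @examples
#' decay_rate(3600)            # one-hour half-life
#' exp(decay_rate(3600) * 3600)  # = 0.5
#' @export
decay_rate <- function(half_life) {
  if (!is.numeric(half_life) || length(half_life) != 1L ||
      !is.finite(half_life) || half_life <= 0)
    stop("half_life must be a single positive finite number", call. = FALSE)
  log(0.5) / half_life
}

#' A timed media-exchange event
#'
#' @param time Event time (s), >= 0.
#' @param reservoirs Character vector of reservoir ids the event applies to.
#' @param kind `"full"` (replace reservoir contents with `new_media`) or
#'   `"half"` (replace half the decayed contents: per factor, the boundary
#'   becomes the mean of the decayed level and the fresh media level).
#' @param new_media A [media_composition()].
#' @return An object of class `media_event`.
#' @export
media_event <- function(time, reservoirs, kind = c("full", "half"),
                        new_media) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(time), length(time) == 1L, time >= 0,
            is.character(reservoirs), length(reservoirs) >= 1L,
            inherits(new_media, "media_composition"))
  structure(list(time = time, reservoirs = reservoirs, kind = kind,
                 new_media = new_media),
            class = "media_event")
}

#' A feeding schedule: ordered media events over a culture duration
#'
#' @param events List of [media_event()] objects with non-decreasing times,
#'   all `<= duration`.
#' @param duration Total culture duration (s).
#' @return An object of class `feeding_schedule`.
#' @export
feeding_schedule <- function(events, duration) {
  stopifnot(is.list(events), duration > 0,
            all(vapply(events, inherits, logical(1), "media_event")))
  times <- vapply(events, `[[`, numeric(1), "time")
  if (length(times) && is.unsorted(times))
    stop("event times must be non-decreasing", call. = FALSE)
  if (length(times) && any(times > duration))
    stop("all event times must be <= duration", call. = FALSE)
  structure(list(events = events, duration = duration),
            class = "feeding_schedule")
}

#' @export
print.feeding_schedule <- function(x, ...) {
  cat(sprintf("<feeding_schedule> %d events over %.1f days\n",
              length(x$events), x$duration / 86400))
  for (ev in x$events)
    cat(sprintf("  day %5.1f  %-5s %-22s -> %s\n", ev$time / 86400, ev$kind,
                ev$new_media$name, paste(ev$reservoirs, collapse = ",")))
  invisible(x)
}

#' Initial (empty) reservoir state
#'
#' A reservoir state records, per reservoir, the time of the last media
#' event and the factor concentrations set at that event. Between events
#' every factor decays by its half-life, mirroring degradation in the media
#' channel between exchanges.
#'
#' @param reservoirs Character vector of reservoir ids.
#' @return An object of class `reservoir_state`.
#' @export
reservoir_state <- function(reservoirs = c("left", "right")) {
  per <- stats::setNames(lapply(reservoirs, function(r)
    list(last_event_time = 0, concentration_at_event = numeric(0))),
    reservoirs)
  structure(list(reservoirs = per), class = "reservoir_state")
}

#' Decayed reservoir concentration at a given time
#'
#' Returns `C_event * 2^(-(t - t_event)/t_half)` for the named factor:
#' the concentration set at the reservoir's last media event, decayed by
#' the factor's half-life over the time elapsed since.
#'
#' @param state A [reservoir_state()].
#' @param reservoir Reservoir id.
#' @param factor Factor name.
#' @param t Time (s), `>= last_event_time` for that reservoir.
#' @param factor_set Named list of [growth_factor()] records (for half-life).
#' @return Concentration (ng/mL).
#' @export
reservoir_concentration <- function(state, reservoir, factor, t,
                                    factor_set = default_growth_factors()) {
  stopifnot(inherits(state, "reservoir_state"))
  res <- state$reservoirs[[reservoir]]
  if (is.null(res)) stop("unknown reservoir: ", reservoir, call. = FALSE)
  if (!factor %in% names(factor_set))
    stop("unknown growth factor: ", factor, call. = FALSE)
  if (t < res$last_event_time)
    stop("t must be >= the reservoir's last event time", call. = FALSE)
  c0 <- if (factor %in% names(res$concentration_at_event))
    res$concentration_at_event[[factor]] else 0
  c0 * 2^(-(t - res$last_event_time) / factor_set[[factor]]$half_life)
}

#' Apply a media event to a reservoir state
#'
#' A full exchange sets the affected reservoirs to the fresh media
#' concentrations. A half exchange first decays the current contents to the
#' event time, then mixes 50:50 with fresh media: factors absent from the
#' fresh media are diluted to half their decayed level.
#'
#' @param state A [reservoir_state()].
#' @param event A [media_event()] with `time >=` each affected reservoir's
#'   `last_event_time`.
#' @param factor_set Named list of [growth_factor()] records.
#' @return The updated `reservoir_state`.
#' @export
apply_media_event <- function(state, event,
                              factor_set = default_growth_factors()) {
  stopifnot(inherits(state, "reservoir_state"),
            inherits(event, "media_event"))
  fresh <- event$new_media$factors
  for (r in event$reservoirs) {
    res <- state$reservoirs[[r]]
    if (is.null(res)) stop("unknown reservoir: ", r, call. = FALSE)
    if (event$time < res$last_event_time)
      stop("event time precedes reservoir's last event", call. = FALSE)
    if (event$kind == "full") {
      conc <- fresh
    } else {
      all_factors <- union(names(res$concentration_at_event), names(fresh))
      decayed <- vapply(all_factors, function(f)
        reservoir_concentration(state, r, f, event$time, factor_set),
        numeric(1))
      fresh_full <- vapply(all_factors, function(f)
        if (f %in% names(fresh)) fresh[[f]] else 0, numeric(1))
      conc <- 0.5 * decayed + 0.5 * fresh_full
      names(conc) <- all_factors
    }
    state$reservoirs[[r]] <- list(last_event_time = event$time,
                                  concentration_at_event = conc)
  }
  state
}

#' Build the 31-day counter-current gradient feeding schedule
#'
#' Encodes the co-culture feeding strategy: both sides are loaded on day 0
#' (vascular media on one side, stromal on the other) with full exchanges on
#' day 1; on days 3 and 5 the vascular side receives fresh vascular media
#' (full) while the stromal side is half-exchanged for adipocyte initiation
#' media; from day 7 the adipogenic side is half-exchanged for maturation
#' media every 2-3 days up to day 17. On day 17 the gradient is inverted:
#' the adipogenic side is fully exchanged for vascular media and the former
#' vascular side is half-exchanged for initiation media, and the day 3-17
#' pattern repeats mirrored up to day 31.
#'
#' @param media Named list of media compositions as returned by
#'   [default_media()] (`stromal`, `vascular`, `adipogenic_initiation`,
#'   `adipogenic_maturation`).
#' @param vascular_side Reservoir initially fed vascular media
#'   (`"left"` or `"right"`).
#' @param exchange_days Numeric vector of exchange days; the cadence
#'   "every 2-3 days" is encoded by the default list.
#' @param inversion_day Day the gradient is inverted.
#' @param duration_days Total culture duration in days.
#' @return A [feeding_schedule()] with times in seconds.
#' @export
build_gradient_schedule <- function(media = default_media(),
                                    vascular_side = "left",
                                    exchange_days = c(0, 1, 3, 5, 7, 10, 12,
                                                      14, 17, 19, 21, 24, 26,
                                                      28, 31),
                                    inversion_day = 17,
                                    duration_days = 31) {
  stopifnot(vascular_side %in% c("left", "right"))
  other <- setdiff(c("left", "right"), vascular_side)
  day <- 86400
  if (inversion_day > duration_days)
    stop("inversion day lies outside the culture duration", call. = FALSE)
  exchange_days <- sort(unique(exchange_days))
  exchange_days <- exchange_days[exchange_days <= duration_days]
  events <- list()
  add <- function(d, side, kind, m)
    events[[length(events) + 1L]] <<- media_event(d * day, side, kind, m)
  for (d in exchange_days) {
    # sides swap at inversion; relative day within the current phase
    pre <- d < inversion_day
    vasc <- if (pre) vascular_side else other
    adip <- if (pre) other else vascular_side
    rel <- if (pre) d else d - inversion_day + 3
    if (rel == 0) {                      # day-0 loading
      add(d, vasc, "full", media$vascular)
      add(d, adip, "full", media$stromal)
    } else if (rel == 1) {               # day-1 full refresh
      add(d, vasc, "full", media$vascular)
      add(d, adip, "full", media$stromal)
    } else if (rel <= 5) {               # days 3,5: initiation half-exchanges
      add(d, vasc, "full", media$vascular)
      add(d, adip, "half", media$adipogenic_initiation)
    } else {                             # day 7 onward: maturation
      add(d, vasc, "full", media$vascular)
      add(d, adip, "half", media$adipogenic_maturation)
    }
  }
  feeding_schedule(events, duration_days * day)
}

#' Single-loading schedule for short design simulations
#'
#' Loads each reservoir once at t = 0 and never exchanges: the boundary
#' concentrations then decay freely by half-life. This is the configuration
#' used for the 2-day distribution-distance simulations.
#'
#' @param left,right [media_composition()] for each reservoir; either may be
#'   an empty composition.
#' @param duration_days Simulation duration in days.
#' @return A [feeding_schedule()].
#' @export
single_loading_schedule <- function(left, right, duration_days = 2) {
  feeding_schedule(list(
    media_event(0, "left", "full", left),
    media_event(0, "right", "full", right)
  ), duration_days * 86400)
}

# Reservoir timeline for one factor: play the schedule's events through
# apply_media_event and return, per reservoir, the piecewise-exponential
# boundary concentration as step data (event time, concentration set then).
# The returned closure conc(reservoir, t) is vectorised over t.
reservoir_timeline <- function(schedule, factor, factor_set) {
  reservoirs <- unique(unlist(lapply(schedule$events, `[[`, "reservoirs")))
  if (!length(reservoirs)) reservoirs <- c("left", "right")
  state <- reservoir_state(reservoirs)
  half_life <- factor_set[[factor]]$half_life
  times <- lapply(stats::setNames(reservoirs, reservoirs), function(r) numeric(0))
  concs <- times
  for (ev in schedule$events) {
    state <- apply_media_event(state, ev, factor_set)
    for (r in ev$reservoirs) {
      res <- state$reservoirs[[r]]
      c0 <- if (factor %in% names(res$concentration_at_event))
        res$concentration_at_event[[factor]] else 0
      times[[r]] <- c(times[[r]], ev$time)
      concs[[r]] <- c(concs[[r]], c0)
    }
  }
  function(reservoir, t) {
    tt <- times[[reservoir]]
    if (is.null(tt) || !length(tt)) return(rep(0, length(t)))
    idx <- findInterval(t, tt)
    out <- numeric(length(t))
    pos <- idx > 0
    out[pos] <- concs[[reservoir]][idx[pos]] *
      2^(-(t[pos] - tt[idx[pos]]) / half_life)
    out
  }
}

#' Write / read a feeding schedule as YAML
#'
#' Serialises event times (s), reservoirs, kinds and media compositions so a
#' schedule can be stored with a run configuration and re-read identically.
#'
#' @param schedule A [feeding_schedule()].
#' @param path File path.
#' @return `read_schedule` returns a [feeding_schedule()];
#'   `write_schedule` returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "feeding_schedule"))
  doc <- list(
    duration = schedule$duration,
    events = lapply(schedule$events, function(ev) list(
      time = ev$time, reservoirs = as.list(ev$reservoirs), kind = ev$kind,
      media = list(name = ev$new_media$name,
                   factors = as.list(ev$new_media$factors)))))
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname write_schedule
#' @param factor_set Named list of [growth_factor()] records used to
#'   validate media compositions on read.
#' @export
read_schedule <- function(path, factor_set = default_growth_factors()) {
  doc <- yaml::read_yaml(path)
  events <- lapply(doc$events, function(ev) {
    fac <- unlist(ev$media$factors)
    if (is.null(fac)) fac <- stats::setNames(numeric(0), character(0))
    media_event(ev$time, unlist(ev$reservoirs), ev$kind,
                media_composition(ev$media$name, fac, factor_set))
  })
  feeding_schedule(events, doc$duration)
}
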