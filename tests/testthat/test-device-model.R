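test_that("decay rate follows the half-life definition", {
  # ln(0.5)/t_half, frozen against independent evaluation
  expect_equal(decay_rate(1440), -4.8135221e-04, tolerance = 1e-7)
  expect_equal(decay_rate(3600), -1.9254088e-04, tolerance = 1e-7)
  expect_lt(decay_rate(1000), 0)
  for (h in c(60, 1440, 3600, 90000, 1e7))
    expect_equal(exp(decay_rate(h) * h), 0.5, tolerance = 1e-12)
  expect_error(decay_rate(0), "positive")
  expect_error(decay_rate(-5), "positive")
  expect_error(decay_rate(Inf), "positive|finite")
})

test_that("growth factor records validate their parameters", {
  gf <- growth_factor("VEGF", 5, 38200, 200, 3600, 1.7)
  expect_s3_class(gf, "growth_factor")
  expect_error(growth_factor("x", -1, 1, 1, 1, 1), "positive")
  expect_error(growth_factor("x", 1, 1, 1, Inf, 1), "finite")
})

test_that("packaged parameter table covers the seven modelled factors", {
  fs <- default_growth_factors()
  expect_setequal(names(fs),
                  c("FGF-alpha", "EGF", "FGF-beta", "IGF-1", "VEGF",
                    "DEX", "Insulin"))
  expect_equal(fs[["IGF-1"]]$diffusivity, 159)
  expect_equal(fs[["IGF-1"]]$half_life, 1440)
  expect_equal(fs[["DEX"]]$supplemented_conc, 392)
  expect_equal(fs[["Insulin"]]$ec50, 33.7)
  med <- default_media(fs)
  # EGF and FGF-beta belong to both stromal and vascular media
  expect_true(all(c("EGF", "FGF-beta") %in% names(med$stromal$factors)))
  expect_true(all(c("EGF", "FGF-beta") %in% names(med$vascular$factors)))
  expect_setequal(names(med$adipogenic_initiation$factors),
                  c("DEX", "Insulin"))
})

test_that("reservoir concentrations decay by half-life between events", {
  fs <- default_growth_factors()
  st <- reservoir_state()
  st <- apply_media_event(
    st, media_event(0, "left", "full", default_media(fs)$vascular), fs)
  # identity at the event time
  expect_equal(reservoir_concentration(st, "left", "IGF-1", 0, fs), 15)
  # one and two half-lives
  expect_equal(reservoir_concentration(st, "left", "IGF-1", 1440, fs), 7.5)
  expect_equal(reservoir_concentration(st, "left", "IGF-1", 2880, fs), 3.75)
  # insulin: one half-life of 108000 s
  st2 <- apply_media_event(
    st, media_event(0, "left", "full",
                    default_media(fs)$adipogenic_initiation), fs)
  expect_equal(reservoir_concentration(st2, "left", "Insulin", 108000, fs),
               500)
  # strictly decreasing between events
  tt <- seq(0, 4 * 1440, by = 120)
  cc <- vapply(tt, function(t)
    reservoir_concentration(st, "left", "IGF-1", t, fs), numeric(1))
  expect_true(all(diff(cc) < 0))
  expect_error(reservoir_concentration(st, "left", "nope", 0, fs), "unknown")
  expect_error(reservoir_concentration(st, "left", "IGF-1", -10, fs), ">=")
})

test_that("half media exchanges mix decayed contents with fresh media", {
  fs <- probe_set(half_life = 3600)
  med10 <- media_composition("m", c(probe = 10), fs)
  st <- reservoir_state("left")
  st <- apply_media_event(st, media_event(0, "left", "full",
                                          media_composition("m", c(probe = 8), fs)), fs)
  # after one half-life the level is 4; half exchange with 10 gives 7
  st <- apply_media_event(st, media_event(3600, "left", "half", med10), fs)
  expect_equal(reservoir_concentration(st, "left", "probe", 3600, fs), 7)
  # half exchange with media lacking the factor halves the decayed level
  st2 <- reservoir_state("left")
  st2 <- apply_media_event(st2, media_event(0, "left", "full", med10), fs)
  st2 <- apply_media_event(st2, media_event(3600, "left", "half",
                                            blank_media(fs)), fs)
  expect_equal(reservoir_concentration(st2, "left", "probe", 3600, fs), 2.5)
})

test_that("repeated half exchanges converge geometrically to fresh media", {
  fs <- probe_set(half_life = 7200)
  fresh <- media_composition("f", c(probe = 20), fs)
  st <- reservoir_state("left")
  st <- apply_media_event(st, media_event(0, "left", "full",
                                          media_composition("m", c(probe = 2), fs)), fs)
  t <- 0
  for (i in 1:6) {
    before <- reservoir_concentration(st, "left", "probe", t + 1800, fs)
    st <- apply_media_event(st, media_event(t + 1800, "left", "half", fresh),
                            fs)
    t <- t + 1800
    after <- reservoir_concentration(st, "left", "probe", t, fs)
    expect_equal(abs(after - 20), 0.5 * abs(before - 20), tolerance = 1e-12)
  }
})

test_that("the 31-day gradient schedule inverts sides on day 17", {
  sched <- build_gradient_schedule()
  expect_s3_class(sched, "feeding_schedule")
  expect_equal(sched$duration, 31 * 86400)
  days <- vapply(sched$events, function(e) e$time / 86400, numeric(1))
  expect_true(!is.unsorted(days))
  # before inversion the left side gets vascular media, after it the right
  vasc_side <- function(day) {
    evs <- Filter(function(e) e$time == day * 86400 &&
                    e$new_media$name == "vascular", sched$events)
    unique(unlist(lapply(evs, `[[`, "reservoirs")))
  }
  expect_equal(vasc_side(14), "left")
  expect_equal(vasc_side(17), "right")
  expect_equal(vasc_side(21), "right")
  # adipogenic half exchanges before inversion target the right side
  ev7 <- Filter(function(e) e$time == 7 * 86400 && e$kind == "half",
                sched$events)
  expect_equal(unlist(lapply(ev7, `[[`, "reservoirs")), "right")
  expect_equal(ev7[[1]]$new_media$name, "adipogenic_maturation")
  expect_error(build_gradient_schedule(inversion_day = 40,
                                       duration_days = 31), "inversion")
})

test_that("degenerate schedules are honoured", {
  fs <- probe_set()
  med <- media_composition("m", c(probe = 10), fs)
  # single loading, no further exchanges
  s <- single_loading_schedule(med, blank_media(fs), 2)
  expect_equal(length(s$events), 2L)
  expect_equal(s$duration, 2 * 86400)
  # only day-0 events when the exchange-day list stops at 0
  s0 <- build_gradient_schedule(exchange_days = 0, inversion_day = 17,
                                duration_days = 31)
  expect_true(all(vapply(s0$events, `[[`, numeric(1), "time") == 0))
  expect_error(feeding_schedule(list(
    media_event(10, "left", "full", med),
    media_event(5, "left", "full", med)), 100), "non-decreasing")
})

test_that("schedules round-trip through YAML identically", {
  sched <- build_gradient_schedule()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_schedule(sched, path)
  back <- read_schedule(path)
  expect_equal(back$duration, sched$duration)
  expect_equal(length(back$events), length(sched$events))
  for (i in seq_along(sched$events)) {
    expect_identical(back$events[[i]]$time, sched$events[[i]]$time)
    expect_identical(back$events[[i]]$kind, sched$events[[i]]$kind)
    expect_identical(back$events[[i]]$reservoirs,
                     sched$events[[i]]$reservoirs)
    expect_equal(back$events[[i]]$new_media$factors,
                 sched$events[[i]]$new_media$factors)
  }
})
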