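# shared fixtures: a minimal probe factor set and small geometries so unit
# tests stay fast; full-chip runs live in test-acceptance.R

probe_factor <- function(name = "probe", c0 = 10, D = 100, half_life = 3600,
                         ec50 = 2.5) {
  growth_factor(name, c0, 1000, D, half_life, ec50)
}

probe_set <- function(...) {
  gf <- probe_factor(...)
  stats::setNames(list(gf), gf$name)
}

blank_media <- function(factor_set) {
  media_composition("blank", stats::setNames(numeric(0), character(0)),
                    factor_set)
}

small_geometry <- function(style = "edge")
  chip_geometry(length = 2, width = 1, channel_segment_length = 0.8,
                channel_style = style)

# single-factor single-loading field on a small chip
probe_field <- function(gf = probe_factor(), duration_days = 0.1,
                        snapshot_interval = 1800, style = "overlap", ...) {
  fs <- stats::setNames(list(gf), gf$name)
  geom <- small_geometry(style)
  med <- media_composition("m", stats::setNames(gf$supplemented_conc,
                                                gf$name), fs)
  sched <- single_loading_schedule(med, blank_media(fs), duration_days)
  simulate_factor(gf, geom, sched, sim_grid(geom, 0.1),
                  snapshot_interval = snapshot_interval, factor_set = fs, ...)
}
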