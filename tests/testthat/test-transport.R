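test_that("pure decay reproduces the closed form everywhere", {
  tc <- generate_pde_testcase("pure_decay")
  fld <- do.call(simulate_factor,
                 c(list(tc$factor, tc$geometry, tc$schedule, tc$grid,
                        snapshot_interval = 1800), tc$sim_args))
  expected <- tc$expected(fld$times)
  for (s in seq_along(fld$times))
    expect_equal(as.vector(fld$values[, , s]),
                 rep(expected[s], tc$grid$nx * tc$grid$ny),
                 tolerance = 1e-3)
})

test_that("a fully clamped compartment relaxes to the uniform boundary value", {
  tc <- generate_pde_testcase("steady_uniform")
  fld <- do.call(simulate_factor,
                 c(list(tc$factor, tc$geometry, tc$schedule, tc$grid,
                        snapshot_interval = 6 * 3600), tc$sim_args))
  final <- fld$values[, , length(fld$times)]
  expect_equal(as.vector(final), rep(10, length(final)), tolerance = 1e-2)
})

test_that("mass is conserved with no-flux walls and no decay", {
  gf <- probe_factor(half_life = 1e15, D = 100)
  fs <- stats::setNames(list(gf), gf$name)
  geom <- small_geometry()
  grid <- sim_grid(geom, 0.1)
  set.seed(42)
  init <- matrix(stats::runif(grid$ny * grid$nx, 0, 10), grid$ny, grid$nx)
  sched <- single_loading_schedule(blank_media(fs), blank_media(fs), 3)
  # dt = 0.9 h^2/(4D) = 5.625 s; 10^4 steps ~ 0.65 days
  dur <- 1e4 * 0.9 * (grid$spacing * 1000)^2 / (4 * gf$diffusivity)
  fld <- simulate_factor(gf, geom, sched, grid, duration = dur,
                         snapshot_interval = dur / 2, factor_set = fs,
                         disable_segments = TRUE, initial = init)
  masses <- apply(fld$values, 3, sum)
  expect_lt(max(abs(masses - masses[1])) / masses[1], 1e-6)
})

test_that("fields scale linearly with the supplemented concentration", {
  f1 <- probe_field(probe_factor(c0 = 10))
  f7 <- probe_field(probe_factor(c0 = 70))
  expect_lt(max(abs(f7$values - 7 * f1$values)) / max(f7$values), 1e-9)
})

test_that("FTCS agrees with a dense matrix-exponential solution on a 5x5 grid", {
  geom <- chip_geometry(0.5, 0.5, 0.25, channel_style = "edge")
  grid <- sim_grid(geom, 0.1)
  expect_equal(c(grid$ny, grid$nx), c(5L, 5L))
  gf <- probe_factor(D = 120, half_life = 5400)
  fs <- stats::setNames(list(gf), gf$name)
  h <- grid$spacing * 1000
  set.seed(1)
  init <- matrix(stats::runif(25, 0, 10), grid$ny, grid$nx)
  sched <- single_loading_schedule(blank_media(fs), blank_media(fs), 1)
  fld <- simulate_factor(gf, geom, sched, grid, duration = 3600,
                         snapshot_interval = 1800, factor_set = fs,
                         disable_segments = TRUE, initial = init)
  # independent reference: exact evolution exp(At) c0 with the no-flux
  # (mirrored ghost) Laplacian assembled by brute force
  ny <- grid$ny; nx <- grid$nx; n <- ny * nx
  A <- matrix(0, n, n)
  idx <- function(r, c) (c - 1) * ny + r
  for (r in seq_len(ny)) for (c in seq_len(nx)) {
    i <- idx(r, c)
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- min(max(r + d[1], 1), ny)
      cc <- min(max(c + d[2], 1), nx)
      A[i, idx(rr, cc)] <- A[i, idx(rr, cc)] + 1
      A[i, i] <- A[i, i] - 1
    }
  }
  A <- (gf$diffusivity / h^2) * A + diag(decay_rate(gf$half_life), n)
  for (s in 2:3) {
    ref <- as.numeric(Matrix::expm(Matrix::Matrix(A * fld$times[s])) %*%
                        as.vector(init))
    rms <- sqrt(mean((as.vector(fld$values[, , s]) - ref)^2)) /
      sqrt(mean(ref^2))
    expect_lt(rms, 0.005)
  }
})

test_that("the maximum principle and non-negativity hold on every snapshot", {
  fld <- probe_field(probe_factor(c0 = 10, half_life = 1800),
                     duration_days = 0.2)
  expect_true(all(fld$values >= 0))
  expect_true(all(fld$values <= 10 + 1e-12))
})

test_that("cells decay monotonically once boundaries are exhausted", {
  # short half-life: the boundary quickly falls below interior levels
  gf <- probe_factor(c0 = 10, half_life = 600, D = 200)
  fld <- probe_field(gf, duration_days = 0.2, snapshot_interval = 900)
  # after 10 half-lives the boundary is ~1e-3 of C0; from the following
  # snapshot on, every cell above that must be non-increasing
  start <- which(fld$times > 10 * gf$half_life)[1]
  later <- fld$values[, , start:length(fld$times)]
  high <- fld$values[, , start] > 0.1
  for (s in seq_len(dim(later)[3] - 1)) {
    diffs <- later[, , s + 1][high] - later[, , s][high]
    expect_true(all(diffs <= 1e-12))
  }
})

test_that("mirrored feeding produces mirrored fields", {
  tc <- generate_pde_testcase("reflection_symmetry")
  fl <- simulate_factor(tc$factor, tc$geometry, tc$schedule_left, tc$grid,
                        snapshot_interval = 3600)
  fr <- simulate_factor(tc$factor, tc$geometry, tc$schedule_right, tc$grid,
                        snapshot_interval = 3600)
  expect_lt(max(abs(fl$values - tc$expected(fr))), 1e-10)
})

test_that("halving the grid spacing barely changes the field", {
  gf <- probe_factor(D = 150, half_life = 7200)
  fs <- stats::setNames(list(gf), gf$name)
  geom <- small_geometry("overlap")
  med <- media_composition("m", c(probe = 10), fs)
  sched <- single_loading_schedule(med, blank_media(fs), 0.1)
  coarse <- simulate_factor(gf, geom, sched, sim_grid(geom, 0.1),
                            snapshot_interval = 4320, factor_set = fs)
  fine <- simulate_factor(gf, geom, sched, sim_grid(geom, 0.05),
                          snapshot_interval = 4320, factor_set = fs)
  s <- length(coarse$times)
  # average fine 2x2 blocks onto the coarse grid
  fine_avg <- 0.25 * (fine$values[seq(1, 19, 2), seq(1, 39, 2), s] +
                      fine$values[seq(2, 20, 2), seq(1, 39, 2), s] +
                      fine$values[seq(1, 19, 2), seq(2, 40, 2), s] +
                      fine$values[seq(2, 20, 2), seq(2, 40, 2), s])
  rms <- sqrt(mean((coarse$values[, , s] - fine_avg)^2)) /
    sqrt(mean(fine_avg^2))
  expect_lt(rms, 0.02)
})

test_that("simulate_media produces one shared-grid field per supplied factor", {
  fs <- default_growth_factors()
  med <- default_media(fs)
  geom <- chip_geometry()
  res <- simulate_media(list(left = med$vascular,
                             right = med$adipogenic_initiation),
                        geom, grid = sim_grid(geom, 0.2),
                        duration = 4 * 3600, snapshot_interval = 3600,
                        factor_set = fs)
  expect_setequal(names(res$fields),
                  c("IGF-1", "VEGF", "EGF", "FGF-beta", "DEX", "Insulin"))
  times <- lapply(res$fields, `[[`, "times")
  expect_true(all(vapply(times, identical, logical(1), times[[1]])))
  expect_error(simulate_media(list(left = blank_media(fs),
                                   right = blank_media(fs)),
                              geom, factor_set = fs), "no growth factors")
})

test_that("simulation inputs are validated", {
  gf <- probe_factor()
  fs <- stats::setNames(list(gf), gf$name)
  geom <- small_geometry()
  sched <- single_loading_schedule(blank_media(fs), blank_media(fs), 1)
  expect_error(simulate_factor(gf, geom, sched, sim_grid(geom, 0.1),
                               duration = -5), "duration")
  expect_error(sim_grid(geom, 2), "coarse")
})
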