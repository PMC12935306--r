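test_that("a spatially uniform state grows by exactly the logistic increment", {
  grid <- sim_grid(16, 16, h = 0.5, radius = NULL)
  st <- uniform_state(16, b1 = 0.2)
  out <- biofilm_step(st, two_strains(r1 = 1, r2 = 1), grid, dt = 0.01)
  expect_equal(out$B1, matrix(0.2 + 1 * 0.2 * 0.8 * 0.01, 16, 16),
               tolerance = 1e-14)
  expect_true(all(out$B2 == 0))
})

test_that("zero growth conserves each strain's mass through diffusion", {
  grid <- sim_grid(24, 24, h = 0.5, radius = 5)
  set.seed(42)
  B1 <- matrix(stats::runif(576, 0, 0.5), 24, 24) * grid$mask
  B2 <- matrix(stats::runif(576, 0, 0.4), 24, 24) * grid$mask
  st <- structure(list(B1 = B1, B2 = B2, t = 0), class = "biofilm_state")
  zs <- two_strains(r1 = 0, r2 = 0)
  m1 <- sum(B1); m2 <- sum(B2)
  for (i in 1:50) {
    st <- biofilm_step(st, zs, grid, dt = 0.02)
    expect_lt(abs(sum(st$B1) - m1) / m1, 1e-10)
    expect_lt(abs(sum(st$B2) - m2) / m2, 1e-10)
  }
})

test_that("with no diffusion the solution matches the closed-form logistic curve", {
  grid <- sim_grid(3, 3, h = 1, radius = NULL)
  st <- uniform_state(3, b1 = 0.01)
  strains <- two_strains(r1 = 1, r2 = 1, d1 = 0)
  dt <- 1e-3
  for (i in seq_len(5000)) st <- biofilm_step(st, strains, grid, dt)
  exact <- 0.01 * exp(5) / (1 + 0.01 * (exp(5) - 1))
  expect_lt(abs(st$B1[1, 1] - exact) / exact, 1e-3)
})

test_that("the step enforces the explicit stability bound by name", {
  grid <- sim_grid(16, 16, h = 0.5, radius = NULL)
  expect_error(biofilm_step(uniform_state(16, 0.1), two_strains(), grid,
                            dt = 0.1),
               "h\\^2/\\(4 max d\\)")
  expect_equal(stability_dt(grid, two_strains()), 0.5^2 / 4)
  expect_equal(stability_dt(grid, two_strains(d1 = 2)), 0.5^2 / 8)
})

test_that("densities stay nonnegative and below capacity on randomized states", {
  grid <- sim_grid(32, 32, h = 0.5, radius = 7)
  dt <- 0.5 * stability_dt(grid, two_strains())
  for (case in 1:8) {
    set.seed(case)
    u <- matrix(stats::runif(1024), 32, 32)
    v <- matrix(stats::runif(1024), 32, 32)
    tot <- pmin(u + v, 1)
    share <- matrix(stats::runif(1024), 32, 32)
    st <- structure(list(B1 = tot * share * grid$mask,
                         B2 = tot * (1 - share) * grid$mask, t = 0),
                    class = "biofilm_state")
    strains <- two_strains(r1 = stats::runif(1, 0.2, 1),
                           r2 = stats::runif(1, 0.2, 1))
    for (i in 1:20) {
      st <- biofilm_step(st, strains, grid, dt)
      expect_gte(min(st$B1), 0)
      expect_gte(min(st$B2), 0)
      expect_lte(max(st$B1 + st$B2), 1 + 1e-9)
    }
  }
})

test_that("relabelling the strains swaps the outputs exactly", {
  grid <- sim_grid(48, 48, h = 0.5, radius = 10)
  sp <- data.frame(x = c(-1.5, 2, 0.5), y = c(0, 1, -2),
                   radius = c(1, 0.8, 1.2), strain = c(1L, 2L, 2L),
                   b0 = 0.5)
  sp_swap <- transform(sp, strain = 3L - strain)
  mk <- function(spots, r1, r2) {
    sim_config(grid, two_strains(r1, r2), founder_layout(spots), t_end = 8)
  }
  a <- simulate_biofilm(mk(sp, 1, 1.25))
  b <- simulate_biofilm(mk(sp_swap, 1.25, 1))
  expect_identical(a$state$B1, b$state$B2)
  expect_identical(a$state$B2, b$state$B1)
  expect_identical(a$outcome$f1, b$outcome$f2)
})

test_that("a strain absent at t = 0 stays identically zero", {
  grid <- sim_grid(48, 48, h = 0.5, radius = 10)
  sp <- data.frame(x = 0, y = 0, radius = 2, strain = 1L, b0 = 0.5)
  res <- simulate_biofilm(sim_config(grid, two_strains(1, 1.3),
                                     founder_layout(sp), t_end = 10))
  expect_true(all(res$state$B2 == 0))
  expect_equal(res$outcome$f1, 1)
})

test_that("an empty founder layout leaves the domain empty", {
  grid <- sim_grid(24, 24, h = 0.5, radius = 5)
  lay <- make_founder_layout(0, inoculum_radius = 2, seed = 1, grid = grid)
  res <- simulate_biofilm(sim_config(grid, two_strains(), lay, t_end = 1))
  expect_true(all(res$state$B1 == 0) && all(res$state$B2 == 0))
  expect_null(res$outcome)
})

test_that("founder layouts are deterministic, contained, and validated", {
  grid <- sim_grid(64, 64, h = 0.5, radius = 14)
  l1 <- make_founder_layout(50, inoculum_radius = 6, seed = 3, grid = grid)
  l2 <- make_founder_layout(50, inoculum_radius = 6, seed = 3, grid = grid)
  expect_identical(l1$spots, l2$spots)
  expect_true(all(sqrt(l1$spots$x^2 + l1$spots$y^2) <= 6))
  expect_identical(nrow(l1$spots), 100L)
  expect_error(make_founder_layout(5, inoculum_radius = 20, grid = grid),
               "exceeds the domain")
})

test_that("a mirror-symmetric layout with equal rates splits the colony 50:50", {
  grid <- sim_grid(64, 64, h = 0.5, radius = 14)
  sp <- data.frame(x = c(2.5, -2.5, 4, -4), y = c(1.5, 1.5, -3, -3),
                   radius = 1, strain = c(1L, 2L, 1L, 2L), b0 = 0.5)
  res <- simulate_biofilm(sim_config(grid, two_strains(1, 1),
                                     founder_layout(sp), t_end = 15))
  expect_equal(res$outcome$f1, 0.5, tolerance = 1e-12)
  expect_equal(res$outcome$f2, 0.5, tolerance = 1e-12)
})

test_that("refining the grid changes the competitive outcome by less than 0.01", {
  mk <- function(n, h) {
    grid <- sim_grid(n, n, h = h, radius = 10)
    sim_config(grid, two_strains(1, 1.2),
               make_founder_layout(10, inoculum_radius = 4,
                                   spot_radius = 1.2, b0 = 0.5, seed = 5,
                                   grid = grid),
               t_end = 12)
  }
  f_coarse <- simulate_biofilm(mk(48, 0.5))$outcome$f2
  f_fine <- simulate_biofilm(mk(96, 0.25))$outcome$f2
  expect_lt(abs(f_fine - f_coarse), 0.01)
})

test_that("outcome summaries are normalised fractions", {
  st <- uniform_state(8, 0.3, 0.1)
  oc <- outcome_summary(st)
  expect_equal(oc$f1 + oc$f2, 1)
  expect_equal(oc$percent_challenger_remaining, 75)
  expect_error(outcome_summary(uniform_state(8, 0, 0)), "empty biofilm")
})
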