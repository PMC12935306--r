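#' Two-strain colony-biofilm competition model
#'
#' The simulator integrates the nondimensional reaction-diffusion system
#'
#' \deqn{\partial B_i/\partial t = d_i \,\nabla\cdot(\phi(B)\nabla B_i) +
#'       r_i B_i (1 - B), \qquad B = B_1 + B_2,}
#'
#' on a masked grid (default: a disc), with negative density-dependent
#' diffusivity \eqn{\phi(B) = \max(0, 1 - B)} (spread slows as total
#' biomass approaches the carrying capacity, nondimensionalised to 1) and
#' zero-flux boundaries. Discretisation is explicit forward Euler in time
#' with a second-order central flux form in space; face diffusivity is the
#' arithmetic mean of \eqn{\phi} at the adjacent cells, and fluxes across
#' the domain boundary are zeroed.
#'
#' @name biofilm-sim
NULL

#' Define the computational grid
#'
#' @param nx,ny grid size (cells).
#' @param h grid spacing (nondimensional length per cell).
#' @param radius radius of the disc domain \eqn{\Omega}; `NULL` uses the
#'   full rectangle.
#' @param mask optional logical `nx` x `ny` matrix overriding the disc.
#' @return list of class `sim_grid`: `nx`, `ny`, `h`, `mask`, `x`, `y`
#'   (cell-centre coordinates, origin at the domain centre).
#' @export
sim_grid <- function(nx = 256L, ny = 256L, h = 0.5, radius = 60,
                     mask = NULL) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(h > 0, nx >= 3L, ny >= 3L)
  x <- (seq_len(nx) - (nx + 1) / 2) * h
  y <- (seq_len(ny) - (ny + 1) / 2) * h
  if (is.null(mask)) {
    mask <- if (is.null(radius)) {
      matrix(TRUE, nx, ny)
    } else {
      outer(x, y, function(a, b) a^2 + b^2 <= radius^2)
    }
  }
  stopifnot(identical(dim(mask), c(nx, ny)), any(mask))
  structure(list(nx = nx, ny = ny, h = h, radius = radius, mask = mask,
                 x = x, y = y), class = "sim_grid")
}

#' Strain growth/motility parameters
#'
#' @param name strain label.
#' @param r nondimensional logistic growth rate (>= 0; zero disables
#'   growth, which is useful for conservation checks).
#' @param d nondimensional motility (diffusion scale) coefficient (>= 0).
#' @return list of class `strain_params`.
#' @export
strain_params <- function(name, r = 1, d = 1) {
  stopifnot(r >= 0, d >= 0)
  structure(list(name = name, r = r, d = d), class = "strain_params")
}

#' Random 1:1 founder layout in the central inoculum disc
#'
#' Emulates spotting a 1:1 mixed inoculum: `n_per_strain` founder spots per
#' strain placed uniformly in the central disc of radius `inoculum_radius`.
#'
#' @param n_per_strain founder spots per strain.
#' @param inoculum_radius radius of the inoculated disc.
#' @param spot_radius radius of each founder spot.
#' @param b0 initial density per spot (0 < b0 <= 1).
#' @param seed integer seed.
#' @param grid a [sim_grid()] (for the domain-containment check).
#' @return list of class `founder_layout`: `spots` data.frame with columns
#'   `x`, `y`, `radius`, `strain`, `b0`; `seed`.
#' @export
make_founder_layout <- function(n_per_strain, inoculum_radius = 5,
                                spot_radius = 1, b0 = 0.5, seed = 1L,
                                grid = NULL) {
  stopifnot(b0 > 0, b0 <= 1, inoculum_radius > 0)
  if (!is.null(grid) && !is.null(grid$radius) &&
      inoculum_radius > grid$radius) {
    stop("inoculum_radius exceeds the domain radius", call. = FALSE)
  }
  spots <- with_seed(seed, {
    n <- 2L * n_per_strain
    if (n == 0L) {
      data.frame(x = numeric(), y = numeric(), radius = numeric(),
                 strain = integer(), b0 = numeric())
    } else {
      rad <- inoculum_radius * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      data.frame(x = rad * cos(th), y = rad * sin(th),
                 radius = spot_radius,
                 strain = rep(c(1L, 2L), each = n_per_strain), b0 = b0)
    }
  })
  structure(list(spots = spots, seed = seed), class = "founder_layout")
}

#' Founder layout from explicit spots
#'
#' @param spots data.frame with columns `x`, `y`, `radius`, `strain`, `b0`.
#' @return a `founder_layout`.
#' @export
founder_layout <- function(spots) {
  stopifnot(all(c("x", "y", "radius", "strain", "b0") %in% names(spots)),
            all(spots$strain %in% c(1L, 2L)),
            all(spots$b0 > 0 & spots$b0 <= 1))
  structure(list(spots = spots, seed = NA_integer_),
            class = "founder_layout")
}

#' Rasterise a founder layout into an initial biofilm state
#'
#' Overlapping spots are resolved by proportionally rescaling both strains
#' wherever B1 + B2 would exceed the carrying capacity.
#'
#' @param grid a [sim_grid()].
#' @param layout a `founder_layout`.
#' @return list of class `biofilm_state`: `B1`, `B2` (matrices), `t = 0`.
#' @export
init_biofilm_state <- function(grid, layout) {
  B1 <- matrix(0, grid$nx, grid$ny)
  B2 <- matrix(0, grid$nx, grid$ny)
  sp <- layout$spots
  for (k in seq_len(nrow(sp))) {
    hit <- outer(grid$x - sp$x[k], grid$y - sp$y[k],
                 function(a, b) a^2 + b^2 <= sp$radius[k]^2)
    if (sp$strain[k] == 1L) B1[hit] <- B1[hit] + sp$b0[k]
    else B2[hit] <- B2[hit] + sp$b0[k]
  }
  tot <- B1 + B2
  over <- tot > 1
  if (any(over)) {
    sc <- 1 / tot[over]
    B1[over] <- B1[over] * sc
    B2[over] <- B2[over] * sc
  }
  B1[!grid$mask] <- 0
  B2[!grid$mask] <- 0
  structure(list(B1 = B1, B2 = B2, t = 0), class = "biofilm_state")
}

#' Maximum stable time step
#'
#' Explicit-scheme stability bound \eqn{h^2 / (4\,\max_i d_i)} for the
#' diffusion term (the diffusivity \eqn{\phi} never exceeds 1). The default
#' integration step also respects the logistic bound \eqn{1/\max_i r_i},
#' which (for equal motilities) makes the scheme positivity- and
#' capacity-preserving.
#'
#' @param grid a [sim_grid()].
#' @param strains list of two [strain_params()].
#' @return the diffusion stability bound (numeric).
#' @export
stability_dt <- function(grid, strains) {
  dmax <- max(vapply(strains, `[[`, numeric(1), "d"))
  if (dmax == 0) return(Inf)
  grid$h^2 / (4 * dmax)
}

# Flux divergence of one density field: div(phi_face * grad B), zero-flux
# across the mask boundary. phi is evaluated on the pre-step total density.
flux_divergence <- function(B, P, mask, h) {
  nr <- nrow(B); nc <- ncol(B)
  div <- matrix(0, nr, nc)
  # faces in the first dimension
  Pf <- 0.5 * (P[-1, , drop = FALSE] + P[-nr, , drop = FALSE])
  open <- mask[-1, , drop = FALSE] & mask[-nr, , drop = FALSE]
  Ff <- Pf * (B[-1, , drop = FALSE] - B[-nr, , drop = FALSE]) / h
  Ff[!open] <- 0
  div[-nr, ] <- div[-nr, , drop = FALSE] + Ff / h
  div[-1, ] <- div[-1, , drop = FALSE] - Ff / h
  # faces in the second dimension
  Pf <- 0.5 * (P[, -1, drop = FALSE] + P[, -nc, drop = FALSE])
  open <- mask[, -1, drop = FALSE] & mask[, -nc, drop = FALSE]
  Ff <- Pf * (B[, -1, drop = FALSE] - B[, -nc, drop = FALSE]) / h
  Ff[!open] <- 0
  div[, -nc] <- div[, -nc, drop = FALSE] + Ff / h
  div[, -1] <- div[, -1, drop = FALSE] - Ff / h
  div
}

#' Advance the biofilm state by one explicit time step
#'
#' @param state a `biofilm_state`.
#' @param strains list of two [strain_params()].
#' @param grid a [sim_grid()].
#' @param dt time step; must satisfy [stability_dt()].
#' @param phi diffusivity function of total density (default
#'   `max(0, 1 - B)`).
#' @return the updated `biofilm_state`.
#' @export
biofilm_step <- function(state, strains, grid, dt,
                         phi = function(B) pmax(1 - B, 0)) {
  bound <- stability_dt(grid, strains)
  if (dt > bound + 1e-12) {
    stop(sprintf("dt = %g violates the stability bound h^2/(4 max d) = %g",
                 dt, bound), call. = FALSE)
  }
  B1 <- state$B1; B2 <- state$B2
  Btot <- B1 + B2
  P <- phi(Btot)
  P[!grid$mask] <- 0
  growth1 <- strains[[1]]$r * B1 * (1 - Btot)
  growth2 <- strains[[2]]$r * B2 * (1 - Btot)
  B1 <- B1 + dt * (strains[[1]]$d * flux_divergence(B1, P, grid$mask, grid$h) +
                     growth1)
  B2 <- B2 + dt * (strains[[2]]$d * flux_divergence(B2, P, grid$mask, grid$h) +
                     growth2)
  # Roundoff guard only: the flux-limited scheme is positivity-preserving.
  if (min(B1) < -1e-12 || min(B2) < -1e-12) {
    stop("negative density beyond roundoff: unstable configuration",
         call. = FALSE)
  }
  B1[B1 < 0] <- 0
  B2[B2 < 0] <- 0
  state$B1 <- B1
  state$B2 <- B2
  state$t <- state$t + dt
  state
}

#' Assemble a simulation configuration
#'
#' @param grid a [sim_grid()].
#' @param strains list of two [strain_params()].
#' @param layout a `founder_layout`.
#' @param dt time step; default 0.5 x the stability bound (also capped at
#'   half the logistic bound `1/max r`).
#' @param t_end stop time (nondimensional).
#' @param stop_area_frac stop when the occupied area (total density above
#'   `occupied_threshold`) reaches this fraction of the domain.
#' @param occupied_threshold density defining "occupied" (default 0.05).
#' @param snapshot_every snapshot cadence in time units (`NULL` = none).
#' @param phi diffusivity function.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(grid, strains, layout, dt = NULL, t_end = 50,
                       stop_area_frac = 0.9, occupied_threshold = 0.05,
                       snapshot_every = NULL,
                       phi = function(B) pmax(1 - B, 0)) {
  stopifnot(inherits(grid, "sim_grid"), length(strains) == 2L,
            inherits(layout, "founder_layout"), t_end > 0)
  rmax <- max(vapply(strains, `[[`, numeric(1), "r"))
  if (is.null(dt)) dt <- 0.5 * min(stability_dt(grid, strains), 1 / rmax)
  if (dt > stability_dt(grid, strains)) {
    stop(sprintf("dt = %g violates the stability bound h^2/(4 max d) = %g",
                 dt, stability_dt(grid, strains)), call. = FALSE)
  }
  structure(list(grid = grid, strains = strains, layout = layout, dt = dt,
                 t_end = t_end, stop_area_frac = stop_area_frac,
                 occupied_threshold = occupied_threshold,
                 snapshot_every = snapshot_every, phi = phi),
            class = "sim_config")
}

#' Run a two-strain biofilm competition simulation
#'
#' Integrates the model until the stop rule triggers (occupied area reaches
#' `stop_area_frac` of the domain, or `t_end`), then summarises the final
#' state.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_result`: `state` (final), `outcome`
#'   ([outcome_summary()]), `snapshots` (list of states), `steps`, `config`.
#' @export
simulate_biofilm <- function(config) {
  grid <- config$grid
  state <- init_biofilm_state(grid, config$layout)
  n_domain <- sum(grid$mask)
  snapshots <- list()
  next_snap <- if (is.null(config$snapshot_every)) Inf else 0
  steps <- 0L
  repeat {
    if (state$t >= next_snap) {
      snapshots[[length(snapshots) + 1L]] <- state
      next_snap <- next_snap + config$snapshot_every
    }
    occ <- sum((state$B1 + state$B2) > config$occupied_threshold) / n_domain
    if (occ >= config$stop_area_frac || state$t >= config$t_end - 1e-12) break
    dt <- min(config$dt, config$t_end - state$t)
    state <- biofilm_step(state, config$strains, grid, dt, phi = config$phi)
    steps <- steps + 1L
    if (!all(is.finite(state$B1)) || !all(is.finite(state$B2))) {
      stop(sprintf("instability detected at t = %.3f (non-finite density)",
                   state$t), call. = FALSE)
    }
  }
  outcome <- if (sum(state$B1) + sum(state$B2) > 0) {
    outcome_summary(state, grid,
                    occupied_threshold = config$occupied_threshold)
  } else {
    NULL
  }
  structure(list(state = state, outcome = outcome, snapshots = snapshots,
                 steps = steps, config = config), class = "sim_result")
}

#' Final relative strain densities and occupancy
#'
#' @param state a `biofilm_state` (or list with `B1`, `B2`).
#' @param grid a [sim_grid()] (for occupied-area fractions); optional.
#' @param challenger index (1 or 2) of the challenger strain.
#' @param occupied_threshold density defining "occupied".
#' @return list of class `outcome_summary`: `f1`, `f2` (relative strain
#'   densities, `f1 + f2 = 1`), `percent_challenger_remaining`,
#'   `area_frac1`, `area_frac2`.
#' @export
outcome_summary <- function(state, grid = NULL, challenger = 1L,
                            occupied_threshold = 0.05) {
  s1 <- sum(state$B1); s2 <- sum(state$B2)
  if (s1 + s2 <= 0) stop("empty biofilm", call. = FALSE)
  f1 <- s1 / (s1 + s2); f2 <- s2 / (s1 + s2)
  n <- if (is.null(grid)) length(state$B1) else sum(grid$mask)
  structure(list(
    f1 = f1, f2 = f2,
    percent_challenger_remaining = 100 * if (challenger == 1L) f1 else f2,
    area_frac1 = sum(state$B1 > occupied_threshold) / n,
    area_frac2 = sum(state$B2 > occupied_threshold) / n),
    class = "outcome_summary")
}

#' Sweep the relative growth rate and tabulate competitive outcomes
#'
#' Runs one simulation per growth-rate ratio `rho = r2/r1`, holding the
#' grid, layout and seed fixed, and tabulates the final relative density of
#' strain 2.
#'
#' @param base_config a [sim_config()]; strain 1's growth rate sets the
#'   time scale and strain 2's rate is `rho * r1`.
#' @param ratios numeric vector of growth-rate ratios (> 0).
#' @return data.frame with columns `rho`, `f2_final`,
#'   `percent_challenger_remaining` (challenger = strain 1), sorted by
#'   `rho`.
#' @export
sweep_relative_growth <- function(base_config, ratios) {
  stopifnot(all(ratios > 0))
  ratios <- sort(ratios)
  rows <- lapply(ratios, function(rho) {
    cfg <- base_config
    cfg$strains[[2]]$r <- rho * cfg$strains[[1]]$r
    rmax <- max(vapply(cfg$strains, `[[`, numeric(1), "r"))
    cfg$dt <- min(cfg$dt, 0.5 / rmax)
    res <- simulate_biofilm(cfg)
    data.frame(rho = rho, f2_final = res$outcome$f2,
               percent_challenger_remaining =
                 res$outcome$percent_challenger_remaining)
  })
  do.call(rbind, rows)
}

#' Merge two density fields into a pseudo-colour RGB array
#'
#' Strain 1 is rendered green and strain 2 magenta; overlap appears grey.
#'
#' @param B1,B2 density matrices.
#' @return numeric array `nrow x ncol x 3` in `[0, 1]`.
#' @export
merge_channels <- function(B1, B2) {
  top <- max(B1, B2, 1e-12)
  g <- pmin(B1 / top, 1)
  m <- pmin(B2 / top, 1)
  array(c(m, g, m), dim = c(nrow(B1), ncol(B1), 3L))
}
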