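#' Configuration for the radial diffusion-titration simulator
#'
#' The simulator marches acid/base propagation from a pore source on a 1-D
#' radial grid, in either the quasi-2D lateral geometry (thin gap, annular
#' volume increments proportional to r) or the 3D hemispherical geometry
#' (shell increments proportional to r^2). Species diffuse with their own
#' coefficients and the local acid-base equilibrium (water ion product plus a
#' single effective monoprotic buffer) is re-imposed at every node after each
#' diffusion step, so diffusion and titration occur simultaneously everywhere.
#'
#' @param geometry `"lateral"` (2D) or `"hemispherical"` (3D).
#' @param pore_radius_um Pore radius R (µm); sources in this work are pores of
#'   150-210 µm diameter.
#' @param domain_radius_um Outer domain radius (µm), > R.
#' @param dr_um Radial grid spacing (µm).
#' @param dt_s Time step (s); `NULL` chooses `0.2 * dr^2 / max(D)`. Must
#'   satisfy the explicit stability bound `dt <= 0.4 * dr^2 / max(D)`.
#' @param duration_s Simulated duration (s).
#' @param output_interval_s Interval between stored states (s).
#' @param D_H,D_OH Diffusion coefficients of H+ and OH- (cm^2/s); defaults
#'   9.31e-5 and 5.27e-5 at 25 C.
#' @param D_buffer Diffusion coefficient of both buffer species (cm^2/s).
#' @param buffer_total Total buffer concentration of the bulk (mol/L).
#' @param source_buffer_total Total buffer concentration of the source held at
#'   the pore rim (mol/L). The pore plug is cast from four-fold diluted 0.01 M
#'   phosphate buffer, i.e. 2.5e-3 mol/L, considerably stronger than the
#'   1e-4 mol/L bulk; this asymmetry is what lets the front propagate well
#'   beyond the pore before titration stalls it.
#' @param buffer_pKa Effective buffer pKa (default 7.2, the dominant phosphate
#'   pK near the working range).
#' @param source_ph,bulk_ph pH held at the pore rim and initially filling (and
#'   bounding) the bulk.
#' @param Kw Water ion product (default 1e-14).
#' @param mode `"buffered"` (full chemistry) or `"tracer"` (single
#'   non-reactive species, no titration; used for closed-form limit checks).
#' @param bc_inner,bc_outer Boundary conditions: `"dirichlet"` (held at
#'   source/bulk composition), `"closed"` (zero flux), and for the outer
#'   boundary of the hemispherical geometry also `"open"` (ghost value
#'   following the far-field 1/r decay, emulating an unbounded bath).
#' @param init_ph Optional initial pH profile: a function of radius (µm) or a
#'   vector over grid nodes; default is uniform bulk pH. Useful for
#'   conservation checks with closed boundaries.
#' @param gap_height_um Lateral gap height (µm); a constant multiplier in the
#'   finite-volume weights that cancels from the dynamics, kept for
#'   documentation.
#' @return A validated list of class `obci_transport_config`.
#' @export
transport_config <- function(geometry = c("lateral", "hemispherical"),
                             pore_radius_um = 100,
                             domain_radius_um = 2000,
                             dr_um = 10,
                             dt_s = NULL,
                             duration_s = 600,
                             output_interval_s = 30,
                             D_H = 9.31e-5,
                             D_OH = 5.27e-5,
                             D_buffer = 8.0e-6,
                             buffer_total = 1e-4,
                             source_buffer_total = 2.5e-3,
                             buffer_pKa = 7.2,
                             source_ph = 8.5,
                             bulk_ph = 4.5,
                             Kw = 1e-14,
                             mode = c("buffered", "tracer"),
                             bc_inner = c("dirichlet", "closed"),
                             bc_outer = c("dirichlet", "closed", "open"),
                             init_ph = NULL,
                             gap_height_um = 7) {
  geometry <- match.arg(geometry)
  mode <- match.arg(mode)
  bc_inner <- match.arg(bc_inner)
  bc_outer <- match.arg(bc_outer)
  if (pore_radius_um <= 0 || domain_radius_um <= pore_radius_um)
    stop("need 0 < pore_radius_um < domain_radius_um")
  if (dr_um <= 0 || duration_s <= 0 || output_interval_s <= 0)
    stop("dr_um, duration_s and output_interval_s must be positive")
  if (any(c(source_ph, bulk_ph) <= 0) || any(c(source_ph, bulk_ph) >= 14))
    stop("pH values must lie in (0, 14)")
  if (buffer_total < 0 || source_buffer_total < 0)
    stop("buffer concentrations must be >= 0")
  Dmax_um2 <- max(D_H, D_OH, D_buffer) * 1e8  # cm^2/s -> um^2/s
  dt_bound <- 0.4 * dr_um^2 / Dmax_um2
  if (is.null(dt_s)) dt_s <- 0.5 * dt_bound
  if (dt_s > dt_bound * (1 + 1e-12))
    stop(sprintf("dt_s = %.4g s violates the stability bound 0.4*dr^2/max(D) = %.4g s",
                 dt_s, dt_bound))
  if (bc_outer == "open" && geometry == "lateral")
    stop("the 'open' (1/r far-field) outer boundary is defined for the hemispherical geometry")
  structure(list(geometry = geometry, pore_radius_um = pore_radius_um,
                 domain_radius_um = domain_radius_um, dr_um = dr_um,
                 dt_s = dt_s, duration_s = duration_s,
                 output_interval_s = output_interval_s,
                 D_H = D_H, D_OH = D_OH, D_buffer = D_buffer,
                 buffer_total = buffer_total,
                 source_buffer_total = source_buffer_total,
                 buffer_pKa = buffer_pKa,
                 source_ph = source_ph, bulk_ph = bulk_ph, Kw = Kw,
                 mode = mode, bc_inner = bc_inner, bc_outer = bc_outer,
                 init_ph = init_ph, gap_height_um = gap_height_um),
            class = "obci_transport_config")
}

#' Steady-state hemispherical concentration profile from a pore
#'
#' At distances a few pore radii from the source the diffusion pattern is
#' hemispherical and the steady-state profile is hyperbolic,
#' `c(r) = c0 * R / r` for `r >= R`.
#'
#' @param c0 Concentration in the pore (mol/L).
#' @param R Pore radius (µm).
#' @param r Distance(s) from the pore center (µm), `>= R`.
#' @return Concentration(s) at `r`.
#' @export
steady_state_profile <- function(c0, R, r) {
  if (R <= 0) stop("R must be > 0")
  if (any(r < R)) stop("the steady-state profile is defined for r >= R")
  c0 * R / r
}

#' Radius of the hundred-fold concentration drop
#'
#' The hydroxide concentration falls 100-fold between pH 8.5 and pH 6.5, so
#' on the hyperbolic steady-state profile the pH 6.5 line would sit at
#' `r_st = 100 * R`: about 10 mm for a 100 µm pore. The observed fronts stall
#' far short of this, which is the signature of titration consuming the
#' propagating base.
#'
#' @param R Pore radius (µm).
#' @return `100 * R` (µm).
#' @export
hundredfold_radius <- function(R) {
  if (any(R <= 0)) stop("R must be > 0")
  100 * R
}

#' Species composition of a buffer at a given pH
#'
#' Computes `[H+]`, `[OH-]`, `[HA]`, `[A-]` and the conserved proton excess
#' `P = [H+] - [OH-] + [HA]` for a monoprotic buffer of total concentration
#' `B_tot` equilibrated at pH `ph`.
#'
#' @param ph pH value(s).
#' @param B_tot Total buffer (mol/L).
#' @param pKa Buffer pKa.
#' @param Kw Water ion product.
#' @return A list with components `H, OH, HA, A, P, ph`.
#' @export
ph_to_composition <- function(ph, B_tot, pKa = 7.2, Kw = 1e-14) {
  H <- 10^(-ph)
  OH <- Kw / H
  Ka <- 10^(-pKa)
  HA <- B_tot * H / (H + Ka)
  A <- B_tot - HA
  list(H = H, OH = OH, HA = HA, A = A, P = H - OH + HA, ph = ph)
}

#' Equilibrate water and buffer species at every node
#'
#' Given the conserved quantities total buffer `B_tot` and proton excess
#' `P = [H+] - [OH-] + [HA]`, solves for the unique species set satisfying the
#' water ion product `[H+][OH-] = Kw`, the buffer mass balance
#' `[HA] + [A-] = B_tot`, and the acid dissociation equilibrium
#' `[HA]/[A-] = [H+]/Ka`. The residual of the proton-excess equation is driven
#' below 1e-12 mol/L by a safeguarded, vectorized Newton iteration (the
#' residual is strictly increasing in `[H+]`, so the root is unique); nodes
#' that fail to converge fall back to bisection on pH in (0, 14).
#'
#' @param B_tot Total buffer (mol/L), vectorized.
#' @param P Proton excess (mol/L), vectorized.
#' @param pKa Buffer pKa.
#' @param Kw Water ion product.
#' @param H_init Optional warm-start `[H+]` values.
#' @return A list `H, OH, HA, A, ph`.
#' @export
equilibrate <- function(B_tot, P, pKa = 7.2, Kw = 1e-14, H_init = NULL) {
  n <- max(length(B_tot), length(P))
  B_tot <- rep_len(B_tot, n); P <- rep_len(P, n)
  if (any(B_tot < 0)) stop("B_tot must be >= 0")
  Ka <- 10^(-pKa)
  f <- function(H) H - Kw / H + B_tot * H / (H + Ka) - P
  fp <- function(H) 1 + Kw / H^2 + B_tot * Ka / (H + Ka)^2
  H <- if (is.null(H_init)) {
    # strong-acid/base closed form ignoring buffer, as a start
    pmax((P + sqrt(P^2 + 4 * Kw)) / 2, 1e-14)
  } else pmax(rep_len(H_init, n), 1e-15)
  tol <- 1e-13
  for (it in 1:60) {
    res <- f(H)
    if (all(abs(res) < tol)) break
    H_new <- H - res / fp(H)
    bad <- !is.finite(H_new) | H_new <= 0
    H_new[bad] <- H[bad] / 2
    H <- pmin(pmax(H_new, 1e-15), 10)
  }
  res <- f(H)
  if (any(abs(res) >= 1e-12)) {
    for (i in which(abs(res) >= 1e-12)) {
      lo <- 1e-14; hi <- 1
      if (f(lo)[i] > 0 || f(hi)[i] < 0)
        stop(sprintf(
          "equilibration failed to bracket: node %d, B_tot=%.3g, P=%.3g, f(1e-14)=%.3g, f(1)=%.3g",
          i, B_tot[i], P[i], f(lo)[i], f(hi)[i]))
      for (j in 1:120) {
        mid <- sqrt(lo * hi)
        fi <- mid - Kw / mid + B_tot[i] * mid / (mid + Ka) - P[i]
        if (fi > 0) hi <- mid else lo <- mid
      }
      H[i] <- sqrt(lo * hi)
    }
  }
  OH <- Kw / H
  HA <- B_tot * H / (H + Ka)
  list(H = H, OH = OH, HA = HA, A = B_tot - HA, ph = -log10(H))
}

# Finite-volume diffusion stencil for one geometry/grid. Face "areas" are
# r (lateral, per unit gap height and radian) or r^2 (hemispherical); cell
# volumes are the exact integrals of the same weights.
make_grid <- function(cfg) {
  R <- cfg$pore_radius_um; L <- cfg$domain_radius_um; dr <- cfg$dr_um
  N <- floor((L - R) / dr)
  faces <- R + (0:N) * dr
  centers <- R + ((1:N) - 0.5) * dr
  if (cfg$geometry == "lateral") {
    area <- faces
    vol <- (faces[-1]^2 - faces[-(N + 1)]^2) / 2
  } else {
    area <- faces^2
    vol <- (faces[-1]^3 - faces[-(N + 1)]^3) / 3
  }
  list(N = N, faces = faces, centers = centers, area = area, vol = vol)
}

# One explicit diffusion step of a single species on the grid.
# cf_int: D*area/dr at interior faces; boundary handled per bc.
diffuse_step <- function(c, dt, D_um2, grid, bc_inner, bc_outer, c_src, c_bulk) {
  N <- grid$N
  flux <- numeric(N + 1)  # outward-positive flux at each face
  flux[2:N] <- D_um2 * grid$area[2:N] * (c[1:(N - 1)] - c[2:N]) / (grid$centers[2:N] - grid$centers[1:(N - 1)])
  if (bc_inner == "dirichlet") {
    flux[1] <- D_um2 * grid$area[1] * (c_src - c[1]) / (grid$centers[1] - grid$faces[1])
  } else {
    flux[1] <- 0
  }
  if (bc_outer == "dirichlet") {
    flux[N + 1] <- D_um2 * grid$area[N + 1] * (c[N] - c_bulk) / (grid$faces[N + 1] - grid$centers[N])
  } else if (bc_outer == "open") {
    r_ghost <- grid$centers[N] + (grid$centers[N] - grid$centers[N - 1])
    c_ghost <- c[N] * grid$centers[N] / r_ghost
    flux[N + 1] <- D_um2 * grid$area[N + 1] * (c[N] - c_ghost) / (r_ghost - grid$centers[N])
  } else {
    flux[N + 1] <- 0
  }
  c + dt * (flux[1:N] - flux[2:(N + 1)]) / grid$vol
}

#' Simulate acid/base propagation from a pore
#'
#' Operator-split explicit march: each step diffuses the species
#' (`[H+]`, `[OH-]`, `[HA]`, `[A-]` in buffered mode, each with its own
#' diffusion coefficient; one non-reactive species in tracer mode) on the
#' radial finite-volume grid, then re-equilibrates every node (buffered mode)
#' so the water ion product holds at every point at all times. The pore rim is
#' held at the source-pH equilibrium composition and the outer boundary at the
#' bulk composition (or closed / open per the configuration).
#'
#' @param cfg An [transport_config()] object.
#' @return An object of class `obci_sim`: list with `times`, `r_um` (cell
#'   centers), `ph` (time x radius matrix), `conc` (list of species matrices),
#'   and `cfg`.
#' @export
simulate_propagation <- function(cfg) {
  grid <- make_grid(cfg)
  # shrink dt so that output times fall exactly on the requested interval
  out_every <- max(1L, ceiling(cfg$output_interval_s / cfg$dt_s))
  dt <- cfg$output_interval_s / out_every
  n_steps <- out_every * ceiling(cfg$duration_s / cfg$output_interval_s)
  D_H <- cfg$D_H * 1e8; D_OH <- cfg$D_OH * 1e8; D_B <- cfg$D_buffer * 1e8

  src <- ph_to_composition(cfg$source_ph, cfg$source_buffer_total, cfg$buffer_pKa, cfg$Kw)
  blk <- ph_to_composition(cfg$bulk_ph, cfg$buffer_total, cfg$buffer_pKa, cfg$Kw)
  ph0 <- if (is.null(cfg$init_ph)) rep(cfg$bulk_ph, grid$N)
         else if (is.function(cfg$init_ph)) cfg$init_ph(grid$centers)
         else rep_len(cfg$init_ph, grid$N)

  times <- list(); states <- list(); keep <- 1L
  if (cfg$mode == "tracer") {
    # single species: the dominant carrier (OH- for a basic source, H+ acid)
    basic <- cfg$source_ph >= cfg$bulk_ph
    D <- if (basic) D_OH else D_H
    c_src <- if (basic) src$OH else src$H
    c_blk <- if (basic) blk$OH else blk$H
    ini <- ph_to_composition(ph0, cfg$buffer_total, cfg$buffer_pKa, cfg$Kw)
    c <- if (basic) ini$OH else ini$H
    to_ph <- function(c) if (basic) 14 + log10(pmax(c, 1e-16)) else -log10(pmax(c, 1e-16))
    times[[1]] <- 0; states[[1]] <- c
    for (s in seq_len(n_steps)) {
      c <- clip_nonneg(
        diffuse_step(c, dt, D, grid, cfg$bc_inner, cfg$bc_outer, c_src, c_blk),
        "tracer")
      if (s %% out_every == 0) {
        keep <- keep + 1L
        times[[keep]] <- s * dt; states[[keep]] <- c
      }
    }
    conc_mat <- do.call(rbind, states)
    ph <- t(apply(conc_mat, 1, to_ph))
    result <- list(times = unlist(times), r_um = grid$centers, ph = ph,
                   conc = list(c = conc_mat), cfg = cfg)
  } else {
    ini <- ph_to_composition(ph0, cfg$buffer_total, cfg$buffer_pKa, cfg$Kw)
    H <- ini$H; OH <- ini$OH; HA <- ini$HA; A <- ini$A
    times[[1]] <- 0
    states[[1]] <- list(H = H, OH = OH, HA = HA, A = A)
    for (s in seq_len(n_steps)) {
      H <- clip_nonneg(diffuse_step(H, dt, D_H, grid, cfg$bc_inner, cfg$bc_outer,
                                    src$H, blk$H), "H")
      OH <- clip_nonneg(diffuse_step(OH, dt, D_OH, grid, cfg$bc_inner, cfg$bc_outer,
                                     src$OH, blk$OH), "OH")
      HA <- clip_nonneg(diffuse_step(HA, dt, D_B, grid, cfg$bc_inner, cfg$bc_outer,
                                     src$HA, blk$HA), "HA")
      A <- clip_nonneg(diffuse_step(A, dt, D_B, grid, cfg$bc_inner, cfg$bc_outer,
                                    src$A, blk$A), "A")
      B_tot <- HA + A
      P <- H - OH + HA
      eq <- equilibrate(B_tot, P, cfg$buffer_pKa, cfg$Kw, H_init = H)
      H <- eq$H; OH <- eq$OH; HA <- eq$HA; A <- eq$A
      if (s %% out_every == 0) {
        keep <- keep + 1L
        times[[keep]] <- s * dt
        states[[keep]] <- list(H = H, OH = OH, HA = HA, A = A)
      }
    }
    conc <- lapply(c(H = "H", OH = "OH", HA = "HA", A = "A"), function(sp)
      do.call(rbind, lapply(states, `[[`, sp)))
    ph <- -log10(conc$H)
    result <- list(times = unlist(times), r_um = grid$centers, ph = ph,
                   conc = conc, cfg = cfg)
  }
  class(result) <- "obci_sim"
  result
}

clip_nonneg <- function(c, label) {
  worst <- min(c)
  if (worst < 0) {
    if (worst < -1e-18) {
      stop("negative concentration in species ", label,
           " (min = ", signif(worst, 4), "): invariant failure (check dt stability)")
    }
    c[c < 0] <- 0  # harmless round-off
  }
  c
}

#' @export
print.obci_sim <- function(x, ...) {
  cat(sprintf("obci simulation (%s, %s): %d frames x %d nodes, t = 0..%g s\n",
              x$cfg$geometry, x$cfg$mode, length(x$times), length(x$r_um),
              max(x$times)))
  invisible(x)
}

#' Front trace of a simulation (truth trace)
#'
#' @param sim An `obci_sim`.
#' @param target_ph Target pH (default 6.5).
#' @return An `obci_front_trace` data.frame.
#' @export
sim_front_trace <- function(sim, target_ph = 6.5) {
  trace_front_profiles(sim$times, sim$r_um, sim$ph, target_ph,
                       pore_radius_um = sim$cfg$pore_radius_um)
}

#' Plateau flatness of a pH profile
#'
#' Buffered pH propagation produces profiles that are essentially flat over
#' most of the distance from the pore, in contrast to the sharp hyperbolic
#' decay of simple diffusion. The statistic is the pH range over the middle
#' 60% of the span between the pore rim and the target-pH front, divided by
#' the total pore-to-bulk pH difference: 0 for an ideal step, small values for
#' a plateau.
#'
#' @param r_um Radii (µm).
#' @param ph pH profile.
#' @param source_ph,bulk_ph Pore and bulk pH.
#' @param pore_radius_um Pore radius (µm).
#' @param target_ph Front definition (default 6.5).
#' @return A list `flatness` (dimensionless; `NA` if the front is absent),
#'   `front_radius_um`, `status`.
#' @export
profile_flatness <- function(r_um, ph, source_ph, bulk_ph, pore_radius_um,
                             target_ph = 6.5) {
  loc <- locate_front(r_um, ph, target_ph)
  if (loc$status != "ok")
    return(list(flatness = NA_real_, front_radius_um = NA_real_,
                status = "front_absent"))
  rf <- loc$radius
  span <- rf - pore_radius_um
  lo <- pore_radius_um + 0.2 * span
  hi <- pore_radius_um + 0.8 * span
  rr <- seq(lo, hi, length.out = 200)
  pp <- stats::approx(r_um, ph, xout = rr, rule = 2)$y
  list(flatness = (max(pp) - min(pp)) / abs(source_ph - bulk_ph),
       front_radius_um = rf, status = "ok")
}

#' Rasterize a simulated radial pH profile onto a pixel grid
#'
#' Produces the radially symmetric 2-D pH field used as ground truth by the
#' renderer: each pixel takes the profile value at its distance from the
#' source center (source pH inside the pore, bulk pH beyond the simulated
#' domain).
#'
#' @param sim An `obci_sim`.
#' @param t Time (s); the nearest stored frame is used.
#' @param dim Grid shape `c(rows, cols)`.
#' @param center Source center, 0-based `(row, col)`.
#' @param um_per_px Pixel size (µm).
#' @return A numeric `rows x cols` pH matrix.
#' @export
rasterize_ph <- function(sim, t, dim, center, um_per_px) {
  i <- which.min(abs(sim$times - t))
  prof <- sim$ph[i, ]
  ai <- annulus_index(dim, center, ring_width = 1)
  r_um <- ai$r_px * um_per_px
  ph <- stats::approx(c(sim$cfg$pore_radius_um, sim$r_um),
                      c(sim$cfg$source_ph, prof),
                      xout = pmax(r_um, sim$cfg$pore_radius_um), rule = 2)$y
  matrix(ph, dim[1], dim[2])
}

#' Write simulated radial profiles as CSV
#'
#' Columns: `t_s, r_um, ph` plus species concentrations when available.
#'
#' @param sim An `obci_sim`.
#' @param path Output path.
#' @export
write_sim_csv <- function(sim, path) {
  nt <- length(sim$times); nr <- length(sim$r_um)
  df <- data.frame(t_s = rep(sim$times, each = nr),
                   r_um = rep(sim$r_um, nt),
                   ph = as.vector(t(sim$ph)))
  if (!is.null(sim$conc$H)) {
    df$H <- as.vector(t(sim$conc$H)); df$OH <- as.vector(t(sim$conc$OH))
    df$HA <- as.vector(t(sim$conc$HA)); df$A <- as.vector(t(sim$conc$A))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
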