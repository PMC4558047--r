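test_that("the hyperbolic steady-state profile follows c0*R/r", {
  expect_equal(steady_state_profile(1, 100, 100), 1.0)
  expect_equal(steady_state_profile(1, 100, 10000), 0.01)
  expect_equal(steady_state_profile(2e-6, 50, 1000), 1e-7)
  expect_error(steady_state_profile(1, 100, 50), "r >= R")
  expect_equal(hundredfold_radius(100), 10000)
  expect_equal(hundredfold_radius(1), 100)
  expect_equal(steady_state_profile(3, 80, hundredfold_radius(80)), 3 / 100)
})

test_that("equilibration reproduces textbook limits to high precision", {
  expect_equal(equilibrate(0, 0)$ph, 7, tolerance = 1e-9)
  expect_equal(equilibrate(0, 1e-3)$ph, 3, tolerance = 1e-6)     # strong acid
  expect_equal(equilibrate(0, -1e-3)$ph, 11, tolerance = 1e-6)   # strong base
  half <- ph_to_composition(7.2, 1e-4, pKa = 7.2)
  eq <- equilibrate(1e-4, half$P, pKa = 7.2)
  expect_equal(eq$ph, 7.2, tolerance = 1e-9)                     # half-titration
  expect_equal(eq$HA, eq$A, tolerance = 1e-6)
})

test_that("equilibrated states satisfy all chemical constraints", {
  set.seed(14)
  B <- stats::runif(200, 0, 5e-3)
  P <- stats::runif(200, -1, 1) * (B + 1e-3)
  eq <- equilibrate(B, P, pKa = 7.2)
  expect_lt(max(abs(eq$H * eq$OH - 1e-14) / 1e-14), 1e-6)       # ion product
  expect_equal(eq$HA + eq$A, B, tolerance = 1e-12)              # mass balance
  expect_lt(max(abs(eq$H - eq$OH + eq$HA - P)), 1e-10)          # proton excess
  # projection property: an equilibrated state is a fixed point
  eq2 <- equilibrate(eq$HA + eq$A, eq$H - eq$OH + eq$HA, pKa = 7.2,
                     H_init = eq$H)
  expect_equal(eq2$H, eq$H, tolerance = 1e-9)
})

test_that("composition and equilibration are mutually inverse", {
  for (ph in c(4.5, 6.5, 7.2, 8.5)) {
    comp <- ph_to_composition(ph, 2.5e-3, pKa = 7.2)
    expect_equal(equilibrate(2.5e-3, comp$P, pKa = 7.2)$ph, ph, tolerance = 1e-9)
  }
})

test_that("the configuration guards its invariants", {
  expect_error(transport_config(pore_radius_um = 300, domain_radius_um = 200),
               "pore_radius")
  expect_error(transport_config(dt_s = 1), "stability bound")
  expect_error(transport_config(source_ph = 15), "pH values")
  expect_error(transport_config(geometry = "lateral", bc_outer = "open"),
               "hemispherical")
  cfg <- transport_config(dr_um = 20)
  expect_lte(cfg$dt_s, 0.4 * 20^2 / (9.31e-5 * 1e8))
})

test_that("a gradient-free run stays constant in space and time", {
  cfg <- transport_config(geometry = "lateral", source_ph = 6.8, bulk_ph = 6.8,
                          source_buffer_total = 1e-4,
                          dr_um = 40, domain_radius_um = 1000,
                          duration_s = 30, output_interval_s = 30)
  sim <- simulate_propagation(cfg)
  expect_lt(max(abs(sim$ph - 6.8)), 1e-9)
})

test_that("closed boundaries conserve buffer and proton excess", {
  blob <- function(r) ifelse(r < 400, 8.0, 5.0)
  for (geom in c("lateral", "hemispherical")) {
    cfg <- transport_config(geometry = geom, bc_inner = "closed",
                            bc_outer = "closed", init_ph = blob,
                            dr_um = 25, domain_radius_um = 800,
                            duration_s = 20, output_interval_s = 20)
    sim <- simulate_propagation(cfg)
    # exact finite-volume cell weights (annulus / shell integrals)
    h <- cfg$dr_um / 2
    g <- if (geom == "lateral") ((sim$r_um + h)^2 - (sim$r_um - h)^2) / 2
         else ((sim$r_um + h)^3 - (sim$r_um - h)^3) / 3
    total <- function(mat, i) sum(mat[i, ] * g)
    B0 <- total(sim$conc$HA + sim$conc$A, 1)
    B1 <- total(sim$conc$HA + sim$conc$A, nrow(sim$ph))
    P0 <- total(sim$conc$H - sim$conc$OH + sim$conc$HA, 1)
    P1 <- total(sim$conc$H - sim$conc$OH + sim$conc$HA, nrow(sim$ph))
    expect_lt(abs(B1 - B0) / abs(B0), 1e-8)
    expect_lt(abs(P1 - P0) / abs(P0), 1e-8)
    # something actually moved
    expect_gt(max(abs(sim$ph[nrow(sim$ph), ] - sim$ph[1, ])), 0.01)
  }
})

test_that("a non-reactive tracer relaxes to the hyperbolic profile", {
  cfg <- transport_config(geometry = "hemispherical", mode = "tracer",
                          buffer_total = 0, bc_outer = "open",
                          pore_radius_um = 100, domain_radius_um = 1500,
                          dr_um = 50, duration_s = 1500,
                          output_interval_s = 1500)
  sim <- simulate_propagation(cfg)
  last <- sim$conc$c[nrow(sim$conc$c), ]
  c0 <- ph_to_composition(cfg$source_ph, 0)$OH
  pred <- steady_state_profile(c0, 100, sim$r_um)
  sel <- sim$r_um >= 200 & sim$r_um <= 750
  expect_lt(max(abs(last[sel] / pred[sel] - 1)), 0.05)
})

test_that("halving the grid spacing moves the front by less than 5 percent", {
  front_at <- function(dr) {
    cfg <- transport_config(geometry = "lateral", dr_um = dr,
                            domain_radius_um = 1500, duration_s = 120,
                            output_interval_s = 120)
    sim <- simulate_propagation(cfg)
    locate_front(sim$r_um, sim$ph[nrow(sim$ph), ])$radius
  }
  r40 <- front_at(40); r20 <- front_at(20)
  expect_lt(abs(r40 - r20) / r20, 0.05)
})

test_that("profile flatness is 0 for a step and 0.6 for a linear ramp", {
  r <- seq(100, 2000, by = 10)
  step <- ifelse(r < 1500, 8.5, 4.5)
  fs <- profile_flatness(r, step, 8.5, 4.5, pore_radius_um = 100,
                         target_ph = 6.5)
  expect_equal(fs$flatness, 0, tolerance = 1e-9)
  # ramp from source to bulk with the front essentially at the bulk end
  ramp <- 8.5 - (8.5 - 4.5) * (r - 100) / (2000 - 100)
  fr <- profile_flatness(r, ramp, 8.5, 4.5, pore_radius_um = 100,
                         target_ph = 4.51)
  expect_equal(fr$flatness, 0.6, tolerance = 0.01)
  none <- profile_flatness(r, rep(8, length(r)), 8.5, 4.5, 100)
  expect_equal(none$status, "front_absent")
})

test_that("rasterized profiles are radially symmetric with source inside the pore", {
  cfg <- transport_config(geometry = "lateral", dr_um = 25,
                          domain_radius_um = 1200, duration_s = 60,
                          output_interval_s = 60)
  sim <- simulate_propagation(cfg)
  field <- rasterize_ph(sim, 60, c(61, 61), c(30, 30), um_per_px = 11)
  expect_equal(field[31, 31], cfg$source_ph)
  expect_equal(field[31, 61], field[61, 31], tolerance = 1e-9)  # symmetry
  expect_lt(field[1, 1], field[31, 35])  # pH decreases away from the pore
})
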