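langmuirClosedForm <- function(t, k_on, k_off, R_max, C) {
  KD <- k_off / k_on
  Req <- R_max * C / (C + KD)
  Req * (1 - exp(-(k_on * C + k_off) * t))
}

test_that("simulateSensorgram matches the closed form and its limits", {
  k_on <- 1e5; k_off <- 1e-3; R_max <- 100
  # C = KD: equilibrium plateau at R_max / 2
  KD <- k_off / k_on
  sg <- simulateSensorgram(k_on, k_off, R_max, KD, t_assoc = 1e6, dt = 1e4)
  expect_equal(max(sg$RU), R_max / 2, tolerance = 1e-6)
  # C >> KD: plateau approaches R_max
  sg2 <- simulateSensorgram(k_on, k_off, R_max, 1e4 * KD,
                            t_assoc = 100, dt = 1)
  expect_equal(max(sg2$RU), R_max, tolerance = 1e-3)
  # closed form at t = 180 s
  sg3 <- simulateSensorgram(k_on, k_off, R_max, 1e-7, t_assoc = 180)
  expect_equal(sg3$RU[sg3$time == 180],
               langmuirClosedForm(180, k_on, k_off, R_max, 1e-7),
               tolerance = 1e-11)
  # continuous at the phase boundary
  i <- max(which(sg3$phase == "association"))
  expect_lt(abs(sg3$RU[i + 1] - sg3$RU[i]), abs(sg3$RU[i] - sg3$RU[i - 1]) * 2)
})

test_that("the closed form agrees with the integrated Langmuir ODE", {
  skip_if_not_installed("deSolve")
  k_on <- 2e5; k_off <- 5e-3; R_max <- 80; C <- 3e-8
  ode <- deSolve::lsoda(
    y = c(R = 0), times = seq(0, 180, 1),
    func = function(t, y, p) list(k_on * C * (R_max - y) - k_off * y),
    parms = NULL, rtol = 1e-10, atol = 1e-12)
  closed <- langmuirClosedForm(seq(0, 180, 1), k_on, k_off, R_max, C)
  expect_equal(unname(ode[, "R"]), closed, tolerance = 1e-6)
})

test_that("normalizeSensorgram applies the subtraction chain", {
  t <- 0:100
  base <- data.frame(time = t, RU = 0, phase = "association")
  mk <- function(ru) transform(base, RU = ru)
  s <- sin(t / 20) * 10
  # null chain: fc2 = fc1, zero blank and control
  out0 <- normalizeSensorgram(mk(5), mk(5), mk(0), mk(0))
  expect_equal(out0$RU, rep(0, length(t)))
  # additivity: planted signal in fc2 only passes through unchanged
  drift <- cos(t / 10)
  out1 <- normalizeSensorgram(mk(s + drift), mk(drift), mk(0), mk(0))
  expect_equal(out1$RU, s)
  # noisy chain: residual against the planted signal is centred at zero
  set.seed(81)
  noisy <- function(x) mk(x + rnorm(length(t), 0, 0.5))
  out2 <- normalizeSensorgram(noisy(s + drift), noisy(drift), noisy(0),
                              noisy(0))
  expect_lt(abs(mean(out2$RU - s)), 3 * 0.5 * 2 / sqrt(length(t)))
})

test_that("fitKinetics recovers rates from noiseless multicycle data", {
  k_on <- 1e5; k_off <- 1e-3; R_max <- 100
  concs <- c(1e-8, 3e-8, 1e-7)
  sg <- generateSensorgrams(k_on, k_off, R_max, concs)
  fit <- fitKinetics(sg)
  expect_equal(fit$k_on, k_on, tolerance = 1e-3)
  expect_equal(fit$k_off, k_off, tolerance = 1e-3)
  expect_equal(fit$R_max, R_max, tolerance = 1e-3)
  expect_equal(fit$KD_kinetic, 1e-8, tolerance = 1e-3)
  # KD identity is exact by construction
  expect_identical(fit$KD_kinetic, fit$k_off / fit$k_on)
})

test_that("single-cycle chained associations fit the same model", {
  k_on <- 5e4; k_off <- 2e-3; R_max <- 60
  concs <- c(1e-8, 3e-8, 1e-7, 3e-7, 1e-6)
  # chain associations in one cycle, carrying the boundary response
  segs <- list(); R0 <- 0; t_end <- 0
  for (C in concs) {
    seg <- simulateSensorgram(k_on, k_off, R_max, C, t_assoc = 120,
                              t_dissoc = 0, R0 = R0)
    seg <- seg[seg$phase == "association", ]
    if (length(segs)) {
      seg$time <- seg$time + t_end
      seg <- seg[-1, ]  # the t = 0 sample duplicates the previous endpoint
    }
    R0 <- seg$RU[nrow(seg)]
    t_end <- seg$time[nrow(seg)]
    segs[[length(segs) + 1]] <- seg
  }
  dis <- data.frame(time = t_end + 1:600, concentration = 0, cycle = 1,
                    flow_cell = 2, phase = "dissociation",
                    RU = R0 * exp(-k_off * (1:600)))
  sc <- rbind(do.call(rbind, segs), dis)
  sc$cycle <- 1
  # the chained segments need the analyte concentration recorded; the
  # dissociation keeps concentration 0
  fit <- fitKinetics(sc, mode = "single-cycle")
  expect_equal(fit$k_on, k_on, tolerance = 0.01)
  expect_equal(fit$k_off, k_off, tolerance = 0.01)
})

test_that("KD is recovered within 10% at 2% noise in >= 90% of runs", {
  k_on <- 1e5; k_off <- 1e-3; R_max <- 100
  KD <- k_off / k_on
  concs <- KD * c(0.3, 1, 3)
  # phase durations matched to the slow off rate, as a real protocol would be
  ok <- 0L
  for (s in 1:10) {
    sg <- generateSensorgrams(k_on, k_off, R_max, concs,
                              t_assoc = 300, t_dissoc = 600,
                              noise_sd = 0.02 * R_max, seed = 900 + s)
    fit <- suppressWarnings(fitKinetics(sg))
    if (is.finite(fit$KD_kinetic) &&
        abs(fit$KD_kinetic - KD) / KD <= 0.1) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("fitEquilibrium finds the isotherm inflection from plateaus", {
  R_max <- 100; KD <- 1e-8
  # exact Langmuir plateaus
  C <- KD * c(0.1, 0.3, 1, 3, 10)
  plats <- data.frame(concentration = C, RU = R_max * C / (C + KD))
  fit <- fitEquilibrium(plats)
  expect_equal(fit$KD, KD, tolerance = 0.05)
  # plateau at C = KD equals half saturation
  expect_equal(plats$RU[C == KD], fit$R_max / 2, tolerance = 0.05)
  # flat plateaus cannot bound KD
  flat <- fitEquilibrium(data.frame(concentration = C, RU = rep(50, 5)))
  expect_equal(flat$flag, "unbounded")
  # plateau extraction from full sensorgrams (fast-equilibrating system)
  sg <- generateSensorgrams(5e6, 0.05, R_max, C)
  fit2 <- fitEquilibrium(sg)
  expect_equal(fit2$KD, KD, tolerance = 0.05)
})

test_that("transitions faster than the instrument are flagged non-measurable", {
  expect_false(flagMeasurable(1e5, 10, 1e-7))     # 95% time = 0.3 s
  expect_true(flagMeasurable(1e5, 1e-3, 1e-7))    # 95% time ~ 3000 s
  # boundary exactly at 2 s counts as non-measurable
  k_off_edge <- log(20) / 2
  expect_false(flagMeasurable(1e-9, k_off_edge, 1e-9))
})
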