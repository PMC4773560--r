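# minimal hand-built trajectory covering given times (for objective
# oracles that need exact simulated values)
fake_trajectory <- function(times, values, column = "PREG_med") {
  states <- matrix(0, length(times), 35,
                   dimnames = list(NULL, state_names()))
  states[, column] <- values
  structure(list(times = times, states = states),
            class = "steroid_trajectory")
}

two_point_dataset <- function(values = c(4, 2), censored = c(FALSE, FALSE)) {
  calibration_dataset(data.frame(
    compartment = "medium", species = "PREG", time_h = c(8, 24),
    replicate = 1, value = values, below_lloq = censored))
}

test_that("NLSD reproduces the hand oracle and censoring rule", {
  # exp = (4, 2), sim = (2, 2), X^max = 4: (4-2)^2/16 + 0 = 0.25
  ds <- two_point_dataset()
  tr <- fake_trajectory(c(8, 24), c(2, 2))
  expect_equal(nlsd(ds, tr), 0.25)

  # sim == exp -> 0
  expect_equal(nlsd(ds, fake_trajectory(c(8, 24), c(4, 2))), 0)

  # censoring the second point leaves the objective unchanged (its
  # residual was 0) and censoring the first removes the 0.25 term
  ds2 <- two_point_dataset(censored = c(FALSE, TRUE))
  expect_equal(nlsd(ds2, tr), 0.25)
  ds3 <- two_point_dataset(censored = c(TRUE, FALSE))
  expect_equal(nlsd(ds3, tr), 0)

  # missing simulated time point errors rather than interpolating
  expect_error(nlsd(ds, fake_trajectory(c(8, 20), c(2, 2))),
               "interpolation")
})

test_that("NLSD is invariant under rescaling a species' units", {
  set.seed(7)
  m <- steroidogenesis_model()
  ds <- noiseless_dataset(m, species = c("PREG", "CORT"))
  tr <- simulate(m, record_times = unique(c(0, ds$times)))
  base <- nlsd(ds, tr)
  raw <- attr(ds, "raw")
  raw$value[raw$species == "CORT"] <- raw$value[raw$species == "CORT"] * 1e3
  ds_scaled <- calibration_dataset(raw)
  tr_scaled <- tr
  tr_scaled$states[, c("CORT_med", "CORT_cell")] <-
    tr_scaled$states[, c("CORT_med", "CORT_cell")] * 1e3
  expect_equal(nlsd(ds_scaled, tr_scaled), base, tolerance = 1e-10)
})

test_that("replicates average per point and all-censored points drop out", {
  df <- data.frame(
    compartment = "medium", species = "ALDO", time_h = rep(c(0, 8), each = 4),
    replicate = rep(1:4, 2), value = c(1, 2, 3, 4, rep(0.01, 4)),
    below_lloq = c(rep(FALSE, 4), rep(TRUE, 4)))
  ds <- calibration_dataset(df)
  expect_equal(ds$obs$value[ds$obs$time_h == 0], 2.5)
  expect_true(ds$obs$censored[ds$obs$time_h == 8])
  expect_equal(unname(ds$xmax["medium.ALDO"]), 2.5)
})

test_that("fitting from the truth is a fixed point", {
  m <- steroidogenesis_model()
  ds <- noiseless_dataset(m)
  fit <- fit_parameters(m, ds, free = c("VmaxA_HSD3B2", "Vmax_CYP11A1"),
                        control = list(maxiter = 10))
  expect_lt(fit$nlsd, 1e-6)
  expect_equal(unname(coef(fit)),
               unname(m$params$kin[c("VmaxA_HSD3B2", "Vmax_CYP11A1")]),
               tolerance = 1e-4)
})

test_that("a single perturbed Vmax is recovered within 1%", {
  truth <- steroidogenesis_model()
  ds <- noiseless_dataset(truth,
                          species = c("PREG", "PROG", "CORTICO", "CORT"))
  start <- truth$params$kin
  start["VmaxA_HSD3B2"] <- start["VmaxA_HSD3B2"] * 3
  p <- truth$params
  m0 <- steroidogenesis_model(
    kinetic_parameters(start, diff_f = p$diff_f, diff_b = p$diff_b,
                       kdist_f = p$kdist_f, kdist_b = p$kdist_b,
                       geometry = p$geometry),
    initial_state = truth$initial_state)
  fit <- fit_parameters(m0, ds, free = "VmaxA_HSD3B2")
  expect_lt(fit$nlsd, fit$nlsd_initial)
  expect_equal(unname(coef(fit)["VmaxA_HSD3B2"]),
               unname(truth$params$kin["VmaxA_HSD3B2"]),
               tolerance = 0.01)
})

test_that("accepted LM iterations never increase the objective", {
  truth <- steroidogenesis_model()
  ds <- noiseless_dataset(truth)
  start <- truth$params$kin
  start["Vmax_CYP11A1"] <- start["Vmax_CYP11A1"] * 2
  p <- truth$params
  m0 <- steroidogenesis_model(
    kinetic_parameters(start, diff_f = p$diff_f, geometry = p$geometry),
    initial_state = truth$initial_state)
  fit <- fit_parameters(m0, ds, free = "Vmax_CYP11A1")
  expect_true(all(diff(fit$trace) <= 1e-12))
  expect_lte(fit$nlsd, fit$nlsd_initial)
})

test_that("fitting sensitivity separates influential from inert parameters", {
  # with aromatase switched off, its second Km (the E1 site) can never
  # carry flux: its fitting sensitivity is exactly 0
  m <- steroidogenesis_model(activities = c(CYP19A1 = 0))
  ds <- noiseless_dataset(m, species = c("PREG", "PROG", "CORTICO"))
  raw <- attr(ds, "raw")
  raw$value <- raw$value * 1.2   # misfit so the baseline NLSD > 0
  ds <- calibration_dataset(raw)
  fs <- fitting_sensitivity(m, ds,
                            parameters = c("VmaxA_HSD3B2", "Vmax_CYP11A1",
                                           "KmB_CYP19A1"))
  score <- stats::setNames(fs$score, fs$parameter)
  expect_equal(unname(score["KmB_CYP19A1"]), 0)
  expect_gt(score["VmaxA_HSD3B2"], score["KmB_CYP19A1"])
  expect_gt(score["Vmax_CYP11A1"], 0)
  expect_false(attr(fs, "absolute_scale"))
})

test_that("exact fit flags absolute-scale sensitivity scores", {
  m <- steroidogenesis_model()
  ds <- noiseless_dataset(m, species = "PREG", times = c(0, 8))
  fs <- fitting_sensitivity(m, ds, parameters = "Vmax_CYP11A1")
  expect_true(attr(fs, "absolute_scale"))
  expect_gte(fs$score[1], 0)
})

test_that("initial-state equilibration honors the diffusion balance", {
  p <- default_parameters()
  # asymmetric diffusion kf = 2, kb = 1: cell = 2 * medium
  pa <- kinetic_parameters(p$kin, diff_f = 2, diff_b = 1,
                           geometry = p$geometry)
  ds <- calibration_dataset(data.frame(
    compartment = "medium",
    species = rep(steroid_species(), each = 1), time_h = 0,
    replicate = 1, value = 1))
  st <- equilibrate_initial_state(ds, pa)
  expect_equal(unname(st[paste0(steroid_species(), "_med")]), rep(1, 14))
  expect_equal(unname(st[paste0(steroid_species(), "_cell")]), rep(2, 14))

  # symmetric constants: intracellular equals medium
  ps <- kinetic_parameters(p$kin, diff_f = 1, geometry = p$geometry)
  st2 <- equilibrate_initial_state(ds, ps)
  expect_equal(st2[paste0(steroid_species(), "_cell")],
               stats::setNames(rep(1, 14),
                               paste0(steroid_species(), "_cell")))

  # zero medium everywhere gives a zero steroid state; missing species warn
  ds0 <- calibration_dataset(data.frame(
    compartment = "medium", species = "PREG", time_h = 0,
    replicate = 1, value = 0))
  expect_warning(st3 <- equilibrate_initial_state(ds0, ps), "initialized to 0")
  expect_true(all(st3[8:35] == 0))
})

test_that("noisy three-parameter recovery succeeds in most replicates", {
  # 5% multiplicative noise, 3 free parameters, 20 seeded replicates;
  # recovery within 25% relative for at least 90%
  truth <- steroidogenesis_model()
  free <- c("Vmax_CYP11A1", "VmaxA_HSD3B2", "VmaxA_CYP21A2")
  ok <- vapply(1:20, function(s) {
    spec <- synth_spec(cv = 0.05, lloq = 0, seed = 100 + s)
    ds <- generate_timecourse(spec, truth)
    raw <- attr(ds, "raw")
    keep <- raw$species %in% c("PREG", "PROG", "DCORTICO", "CORTICO",
                               "CORT", "HPREG")
    ds <- calibration_dataset(raw[keep, ])
    start <- truth$params$kin
    start[free] <- start[free] * c(1.5, 0.6, 1.4)
    p <- truth$params
    m0 <- steroidogenesis_model(
      kinetic_parameters(start, diff_f = p$diff_f, geometry = p$geometry),
      initial_state = truth$initial_state)
    fit <- fit_parameters(m0, ds, free = free, control = list(maxiter = 25))
    all(abs(coef(fit) / truth$params$kin[free] - 1) < 0.25)
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})
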