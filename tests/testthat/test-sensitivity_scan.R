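test_that("dynamic sensitivity matches the exponential-decay closed form", {
  # y = x0 e^{-kt}, x = k: S(t) = (e^{-0.1 k t} - 1)/0.1
  m <- decay_model(k = 1, x0 = 100)
  ts <- c(1, 2, 5)
  s <- dynamic_sensitivity(m, "k_CholesterolTransport", species = "CHOL",
                           times = ts, compartment = "medium")
  expected <- (exp(-0.1 * 1 * ts) - 1) / 0.1
  expect_equal(unname(s[, "CHOL"]), expected, tolerance = 1e-6)
  # at k t = 1 the value is about -0.9516
  expect_equal(s["1", "CHOL"], (exp(-0.1) - 1) / 0.1, tolerance = 1e-6)
})

test_that("proportional response gives unit sensitivity", {
  # saturated CYP11A1 with no downstream losses: PREG_cell ~ Vmax * t,
  # so S(t) = 1 for all t > 0
  p <- zero_parameters()
  kin <- p$kin
  kin["Vmax_CYP11A1"] <- 5
  kin["Km_CYP11A1"] <- 1e-3
  st <- default_initial_state()
  st[] <- 0
  st["CHON"] <- 1000   # S/Km = 1e6: zeroth-order regime
  m <- steroidogenesis_model(
    kinetic_parameters(kin, diff_f = 0, kdist_f = 0, kdist_b = 0,
                       geometry = p$geometry),
    initial_state = st, dilution = FALSE)
  s <- dynamic_sensitivity(m, "Vmax_CYP11A1", species = "PREG",
                           times = c(6, 24, 48), compartment = "cell")
  expect_equal(unname(s[, "PREG"]), rep(1, 3), tolerance = 1e-4)
})

test_that("a parameter without pathway influence has zero sensitivity", {
  m <- steroidogenesis_model(activities = c(CYP19A1 = 0))
  s <- dynamic_sensitivity(m, "KmB_CYP19A1", species = steroid_species(),
                           times = seq(6, 72, 12))
  expect_true(all(s == 0))
})

test_that("undefined sensitivities (zero baseline) are flagged NA", {
  m <- decay_model()   # no steroids anywhere
  s <- dynamic_sensitivity(m, "Vmax_CYP11A1", species = "ALDO",
                           times = c(6, 12))
  expect_true(all(is.na(s)))
})

test_that("sensitivity sign symmetry holds for locally linear responses", {
  m <- steroidogenesis_model()
  sp <- c("PREG", "CORTICO", "CORT")
  s_plus <- dynamic_sensitivity(m, "VmaxA_HSD3B2", species = sp,
                                times = c(24, 48, 72), delta = 0.1)
  s_minus <- dynamic_sensitivity(m, "VmaxA_HSD3B2", species = sp,
                                 times = c(24, 48, 72), delta = -0.1)
  # raw relative responses Delta y / y flip sign with the perturbation,
  # so the normalized S (response / (Delta x / x)) keeps its sign
  expect_true(all(sign(s_plus * 0.1) == -sign(s_minus * -0.1)))
  expect_lt(max(abs(abs(s_plus) - abs(s_minus)) / abs(s_plus)), 0.15)
})

test_that("the sensitivity matrix has full dimensions and sign structure", {
  m <- steroidogenesis_model()
  sm <- sensitivity_heatmap(m, times = seq(6, 72, 6))
  expect_equal(dim(sm), c(42, 15, 12))
  # direct product positive / direct substrate negative at early times
  expect_gt(sm["VmaxA_HSD3B2", "PROG", "6"], 0)
  expect_lt(sm["VmaxA_HSD3B2", "PREG", "6"], 0)
  expect_gt(sm["VmaxA_CYP17H", "HPREG", "6"], 0)
  expect_lt(sm["VmaxA_CYP17H", "PREG", "6"], 0)
  expect_gt(sm["VmaxA_CYP21A2", "DCORTICO", "6"], 0)
  expect_lt(sm["VmaxA_CYP21A2", "PROG", "6"], 0)

  # Vmax outweighs the paired Km where the substrate is far above Km
  rank <- auc_ranking(sm)
  auc <- stats::setNames(rank$auc, rank$parameter)
  expect_gt(auc["VmaxA_HSD3B2"], auc["KmA_HSD3B2"])
  expect_gt(auc["Vmax_CYP11A1"], 0)

  # export is tidy
  f <- tempfile(fileext = ".csv")
  write_sensitivity(sm, f)
  expect_equal(nrow(read.csv(f)), 42 * 15 * 12)
  unlink(f)
})

test_that("AUC ranking integrates |S| by the trapezoid rule", {
  # hand oracle: S = (0, 1) over 6 h has AUC 3.0
  arr <- array(c(0, 1), dim = c(1, 1, 2),
               dimnames = list("p", "s", c(0, 6)))
  x <- structure(arr, times = c(0, 6), delta = 0.1,
                 compartment = "medium", class = "sensitivity_matrix")
  expect_equal(auc_ranking(x)$auc, 3.0)
  # zero matrix: all ties at 0
  arr0 <- array(0, dim = c(3, 2, 2),
                dimnames = list(paste0("p", 1:3), c("a", "b"), c(0, 6)))
  x0 <- structure(arr0, times = c(0, 6), delta = 0.1,
                  compartment = "medium", class = "sensitivity_matrix")
  expect_true(all(auc_ranking(x0)$auc == 0))
  # sign cancellation is avoided: S = (-1, 1) has the same AUC as (1, 1)
  arr1 <- array(c(-1, 1, 1, 1), dim = c(2, 1, 2),
                dimnames = list(c("p1", "p2"), "s", c(0, 6)))
  x1 <- structure(arr1, times = c(0, 6), delta = 0.1,
                  compartment = "medium", class = "sensitivity_matrix")
  expect_equal(auc_ranking(x1)$auc, c(6, 6))
})

test_that("phenotype classification implements the threshold rule", {
  sp <- steroid_species()
  base <- stats::setNames(rep(10, 14), sp)
  expect_equal(classify_phenotype(base, base), "all_steroid")
  # losing the glucocorticoids but keeping ALDO: mineralocorticoid
  x <- base
  x[c("DCORT", "CORT", "HPREG", "DHEA", "HPROG", "DIONE", "TESTO",
      "E1", "E2")] <- 0.0001
  expect_equal(classify_phenotype(x, base), "mineralocorticoid")
  # the converse: glucocorticoid
  y <- base
  y["ALDO"] <- 0.0001
  expect_equal(classify_phenotype(y, base), "glucocorticoid")
  # both corticoids but a missing androgen: both_corticoid
  z <- base
  z["DHEA"] <- 0.0001
  expect_equal(classify_phenotype(z, base), "both_corticoid")
  # neither corticoid branch: terminated upstream
  w <- base
  w[c("ALDO", "DCORT", "CORT")] <- 0.0001
  expect_equal(classify_phenotype(w, base), "terminated_upstream")
  # zero-baseline steroids are excluded with a warning
  b2 <- base
  b2["E2"] <- 0
  expect_warning(cat_out <- classify_phenotype(base, b2), "E2")
  expect_equal(cat_out, "all_steroid")
})

test_that("the 2-D activity scan reproduces the pathway topology", {
  m <- steroidogenesis_model()
  sc <- scan_activity_grid(m, multipliers = c(0, 0.5, 1, 2),
                           config = integrator_config(c_step = 100))
  expect_equal(nrow(sc), 16)
  expect_false(any(is.na(sc$category)))
  cell <- function(a17, a3)
    sc$category[sc$cyp17h_pct == a17 & sc$hsd3b2_pct == a3]
  # baseline cell is all-steroid-producing
  expect_equal(cell(100, 100), "all_steroid")
  # CYP17H at 0: no 17alpha branch, mineralocorticoid branch only
  expect_true(all(cell(0, 50) == "mineralocorticoid",
                  cell(0, 100) == "mineralocorticoid",
                  cell(0, 200) == "mineralocorticoid"))
  # 17alpha-derived steroids are absent in that row
  r <- sc[sc$cyp17h_pct == 0 & sc$hsd3b2_pct == 100, ]
  base <- attr(sc, "baseline")
  for (s in c("HPREG", "DHEA", "HPROG", "DIONE", "DCORT", "CORT",
              "TESTO", "E1", "E2"))
    expect_lt(r[[s]], 0.01 * base[s])
  # HSD3B2 at 0: steroidogenesis terminates upstream
  expect_true(all(cell(50, 0) == "terminated_upstream",
                  cell(100, 0) == "terminated_upstream"))
  # deterministic
  sc2 <- scan_activity_grid(m, multipliers = c(0, 0.5, 1, 2),
                            config = integrator_config(c_step = 100))
  expect_identical(as.data.frame(sc), as.data.frame(sc2))
})

test_that("categories are stable for theta in [0.005, 0.02] off boundaries", {
  m <- steroidogenesis_model()
  for (th in c(0.005, 0.02)) {
    sc <- scan_activity_grid(m, multipliers = c(0, 1, 2), theta = th,
                             config = integrator_config(c_step = 100))
    expect_equal(sc$category[sc$cyp17h_pct == 100 & sc$hsd3b2_pct == 100],
                 "all_steroid")
    expect_equal(sc$category[sc$cyp17h_pct == 0 & sc$hsd3b2_pct == 100],
                 "mineralocorticoid")
    expect_equal(sc$category[sc$cyp17h_pct == 100 & sc$hsd3b2_pct == 0],
                 "terminated_upstream")
  }
})
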