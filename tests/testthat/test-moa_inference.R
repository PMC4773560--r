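make_profile <- function(values = 1, censored = NULL) {
  sp <- lcms_steroids()
  fc <- stats::setNames(rep(1, 12), sp)
  fc[names(values)] <- values
  if (length(values) == 12 && is.null(names(values))) fc[] <- values
  foldchange_profile(fc, censored = censored)
}

test_that("the fold-change objective matches the hand oracle", {
  sp <- lcms_steroids()
  cens <- stats::setNames(rep(TRUE, 12), sp)
  cens[c("PREG", "PROG")] <- FALSE
  obs <- make_profile(c(PREG = 2, PROG = 0.5), censored = cens)
  sim <- make_profile()  # all ones
  # ((2-1)/2)^2 + ((0.5-1)/0.5)^2 = 0.25 + 1 = 1.25
  expect_equal(moa_objective(obs, sim), 1.25)
  # exact match -> 0
  expect_equal(moa_objective(obs, obs), 0)
  # censoring one steroid removes exactly its term
  cens2 <- cens; cens2["PROG"] <- TRUE
  obs2 <- make_profile(c(PREG = 2, PROG = 0.5), censored = cens2)
  expect_equal(moa_objective(obs2, sim), 0.25)
  # raw switch
  expect_equal(moa_objective(obs, sim, normalized = FALSE), 1 + 0.25)
  # all censored errors
  expect_error(moa_objective(make_profile(censored = !logical(12)), sim),
               "censored")
})

test_that("REX crossover has the stated moments and structure", {
  set.seed(1)
  # identical parents: every child equals that point
  parents <- matrix(rep(c(1, -0.5, 0.2), each = 6), 6, 3)
  ch <- rex_crossover(parents, 10)
  expect_equal(dim(ch), c(10, 3))
  for (i in 1:10) expect_equal(unname(ch[i, ]), c(1, -0.5, 0.2))

  # empirical child mean over 1e4 draws is the parent centroid (3 SE)
  set.seed(42)
  parents <- matrix(stats::runif(6 * 8, -2, 2), 6, 8)
  ctr <- colMeans(parents)
  ch <- rex_crossover(parents, 1e4)
  expect_equal(ncol(ch), 8)  # children dimension preserved
  # per-coordinate child SD: sqrt(sum_k dev_k^2 / (k-1))
  dev <- sweep(parents, 2, ctr)
  sd_theory <- sqrt(colSums(dev^2) / 5)
  se <- sd_theory / sqrt(1e4)
  expect_true(all(abs(colMeans(ch) - ctr) < 3 * se))
  expect_equal(apply(ch, 2, sd), sd_theory, tolerance = 0.05)

  # bounds clip
  ch2 <- rex_crossover(parents, 100, lower = rep(-0.1, 8),
                       upper = rep(0.1, 8))
  expect_true(all(ch2 >= -0.1 & ch2 <= 0.1))
  expect_error(rex_crossover(parents[1, , drop = FALSE], 5), "2 parents")
})

test_that("JGG replaces only the sampled parents and keeps size", {
  set.seed(3)
  sphere <- function(x) sum(x^2)
  pop <- matrix(stats::runif(100 * 8, -2, 2), 100, 8)
  obj <- apply(pop, 1, sphere)
  st <- jgg_step(pop, obj, sphere)
  expect_equal(dim(st$population), c(100, 8))
  # exactly the n_parents sampled rows may differ; all others identical
  changed <- which(rowSums(st$population != pop) > 0)
  expect_lte(length(changed), 6)
  untouched <- setdiff(1:100, changed)
  expect_identical(st$population[untouched, ], pop[untouched, ])
  expect_identical(st$obj_values[untouched], obj[untouched])
})

test_that("REX/JGG minimizes the 8-D sphere in every seeded run", {
  sphere <- function(x) sum(x^2)
  for (seed in 1:5) {
    set.seed(seed)
    pop <- matrix(stats::runif(100 * 8, -2, 2), 100, 8)
    obj <- apply(pop, 1, sphere)
    best <- min(obj)
    trace <- numeric(200)
    for (g in 1:200) {
      st <- jgg_step(pop, obj, sphere)
      pop <- st$population
      obj <- st$obj_values
      trace[g] <- min(c(best, obj))
      best <- trace[g]
    }
    expect_true(all(diff(trace) <= 0))   # best-so-far nonincreasing
    expect_lt(trace[200], 1e-2)          # and it actually converges
  }
})

test_that("predicted fold changes are exactly 1 for the null perturbation", {
  m <- steroidogenesis_model()
  p <- predict_foldchange(m, stats::setNames(rep(1, 8), moa_enzymes()))
  expect_equal(unname(p$fc), rep(1, 12))
  expect_false(any(p$censored))
})

test_that("ALDO responds monotonically to CYP11B2 activity", {
  m <- steroidogenesis_model()
  sp <- lcms_steroids()
  rec <- c(0, 72)
  base <- trajectory_concentration(simulate(m, record_times = rec),
                                   sp, "medium", 72)[1, ]
  aldo <- vapply(c(0.1, 0.5, 1), function(a) {
    predict_foldchange(m, c(CYP11B2 = a), baseline = base)$fc[["ALDO"]]
  }, 0)
  expect_true(all(diff(aldo) > 0))
  expect_lt(aldo[1], 1)
  expect_equal(aldo[3], 1, tolerance = 1e-10)
})

test_that("strong HSD3B2 inhibition accumulates upstream and depletes downstream", {
  m <- steroidogenesis_model()
  p <- predict_foldchange(m, c(HSD3B2 = 0.05))
  expect_gt(p$fc[["PREG"]], 1)
  expect_gt(p$fc[["HPREG"]], 1)
  expect_gt(p$fc[["DHEA"]], 1)
  expect_lt(p$fc[["PROG"]], 1)
  expect_lt(p$fc[["CORTICO"]], 1)
  expect_lt(p$fc[["ALDO"]], 1)
})

test_that("Welch/Bonferroni behaves on degenerate and shifted data", {
  sp <- lcms_steroids()
  base <- matrix(rep(c(10, 10.1, 9.9, 10), 12), 12, 4, byrow = TRUE,
                 dimnames = list(sp, NULL))
  # identical groups: adjusted p = 1
  r <- welch_bonferroni(base, base)
  expect_true(all(r$p_adj[!r$degenerate] == 1))
  # constant rows in both groups are flagged, not errored
  const <- matrix(5, 12, 4, dimnames = list(sp, NULL))
  r2 <- welch_bonferroni(const, const)
  expect_true(all(r2$degenerate))
  # m = 1: adjusted equals raw
  r3 <- welch_bonferroni(base[1, , drop = FALSE], base[1, , drop = FALSE] * 0 +
                           c(11, 10.9, 11.1, 11))
  expect_equal(r3$p_adj, r3$p)
  # power: 10-fold shift, n = 4, 5% SD is significant after correction
  set.seed(9)
  ctrl <- matrix(10 * (1 + 0.05 * rnorm(48)), 12, 4,
                 dimnames = list(sp, NULL))
  trt <- matrix(100 * (1 + 0.05 * rnorm(48)), 12, 4,
                dimnames = list(sp, NULL))
  r4 <- welch_bonferroni(trt, ctrl)
  expect_true(all(r4$significant))
  expect_error(welch_bonferroni(base[, 1, drop = FALSE], base), "replicates")
})

test_that("Ward clustering on standardized distances matches a hand oracle", {
  # three 2-column profiles; verify linkage heights against an explicit
  # Lance-Williams ward.D2 computation
  x <- rbind(a = c(0, 0), b = c(1, 0), c = c(4, 2))
  s <- apply(x, 2, sd)
  xs <- sweep(x, 2, s, "/")
  d <- as.matrix(dist(xs))
  cl <- cluster_profiles(x)
  h <- cl$tree$height
  # first merge: closest pair (a, b) at their distance
  expect_equal(h[1], d["a", "b"])
  # second height: ward.D2 update
  # d(c,{ab})^2 = (2 d_ac^2 + 2 d_bc^2 - d_ab^2) / 3
  h2 <- sqrt((2 * d["a", "c"]^2 + 2 * d["b", "c"]^2 - d["a", "b"]^2) / 3)
  expect_equal(h[2], unname(h2))

  # duplicated profile: distance 0, merged first
  y <- rbind(p = c(1, 2, 3), q = c(1, 2, 3), r = c(9, 1, 0))
  cl2 <- cluster_profiles(y)
  expect_equal(cl2$tree$height[1], 0)
  expect_equal(sort(cl2$tree$merge[1, ]), c(-2, -1))

  # constant column gets the SD floor instead of dividing by zero
  z <- rbind(c(1, 5), c(2, 5), c(3, 5))
  expect_silent(cluster_profiles(z))

  # planted two-group structure separates perfectly at k = 2
  set.seed(11)
  inh <- matrix(rnorm(3 * 12, mean = -2, sd = 0.1), 3, 12)
  null <- matrix(rnorm(3 * 12, mean = 0, sd = 0.1), 3, 12)
  cl3 <- cluster_profiles(rbind(inh, null), k = 2)
  expect_equal(length(unique(cl3$clusters[1:3])), 1)
  expect_equal(length(unique(cl3$clusters[4:6])), 1)
  expect_false(cl3$clusters[1] == cl3$clusters[4])
})

test_that("profile construction validates and reorders", {
  sp <- lcms_steroids()
  fc <- stats::setNames(seq(0.5, 1.6, 0.1), sp)
  shuffled <- fc[sample(sp)]
  p1 <- foldchange_profile(fc)
  p2 <- foldchange_profile(shuffled)
  expect_identical(p1$fc, p2$fc)  # estimate is invariant to ordering
  expect_error(foldchange_profile(fc[-1]), "12")
  bad <- fc; bad["PREG"] <- -1
  expect_error(foldchange_profile(bad), "> 0")
})
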