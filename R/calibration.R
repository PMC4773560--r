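#' Assemble a calibration dataset of measured steroid time courses
#'
#' Observations are indexed by compartment (`"medium"` or `"cell"`),
#' species (the 14 steroids and/or `"CHOL"` for total cholesterol) and
#' time point, with replicates and lower-limit-of-quantification (LLOQ)
#' censoring. Replicates are averaged per (compartment, species, time)
#' over quantified values only; a point is censored when no replicate is
#' quantified. The per-trace normalizer `X^max` (maximum mean over time)
#' is precomputed for the NLSD objective.
#'
#' @param data data.frame with columns `compartment`, `species`,
#'   `time_h`, `replicate`, `value`, and optionally `below_lloq`
#'   (logical, default all FALSE). `"intracellular"` is accepted as a
#'   synonym for `"cell"`.
#' @return object of class `calibration_dataset` with elements `obs`
#'   (mean table with `censored` flag), `xmax`, `times`, `species`,
#'   `n_replicates` and `sd` (per-point SD over quantified replicates,
#'   kept for reporting only; the objective is unweighted).
#' @export
calibration_dataset <- function(data) {
  need <- c("compartment", "species", "time_h", "replicate", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  if (is.null(data$below_lloq)) data$below_lloq <- FALSE
  data$compartment <- ifelse(data$compartment == "intracellular", "cell",
                             data$compartment)
  if (!all(data$compartment %in% c("medium", "cell")))
    stop("compartment must be 'medium' or 'cell'")
  ok <- c(steroid_species(), "CHOL")
  bad <- setdiff(unique(data$species), ok)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))

  key <- interaction(data$compartment, data$species, data$time_h,
                     drop = TRUE)
  agg <- function(f, what) {
    v <- tapply(what, key, f)
    v[match(levels(key), names(v))]
  }
  quant_val <- ifelse(data$below_lloq, NA_real_, data$value)
  obs <- data.frame(do.call(rbind, strsplit(levels(key), ".", fixed = TRUE)),
                    stringsAsFactors = FALSE)
  names(obs) <- c("compartment", "species", "time_h")
  obs$time_h <- as.numeric(obs$time_h)
  obs$value <- as.numeric(agg(function(v) mean(v, na.rm = TRUE), quant_val))
  obs$sd <- as.numeric(agg(function(v) stats::sd(v[!is.na(v)]), quant_val))
  obs$n <- as.integer(agg(function(v) sum(!is.na(v)), quant_val))
  obs$censored <- obs$n == 0L
  obs$value[obs$censored] <- NA_real_
  obs <- obs[order(obs$compartment, obs$species, obs$time_h), ]
  rownames(obs) <- NULL

  trace_key <- paste(obs$compartment, obs$species, sep = ".")
  xmax <- tapply(obs$value, trace_key, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  if (any(!is.na(xmax) & xmax < 0))
    stop("X^max must be >= 0 for every trace with a quantified point")
  # degenerate all-zero trace: fall back to a unit normalizer so its
  # (zero) observations still enter the objective on an absolute scale
  xmax[!is.na(xmax) & xmax == 0] <- 1
  structure(list(obs = obs, xmax = xmax,
                 times = sort(unique(obs$time_h)),
                 species = unique(obs$species),
                 n_replicates = max(table(key))),
            class = "calibration_dataset")
}

#' @export
print.calibration_dataset <- function(x, ...) {
  cat(sprintf(
    "Calibration dataset: %d species, %d time points, %d censored of %d points\n",
    length(x$species), length(x$times), sum(x$obs$censored), nrow(x$obs)))
  invisible(x)
}

#' Read a tidy time-course CSV
#'
#' Columns `compartment`, `species`, `time_h`, `replicate`, `value`,
#' `below_lloq`.
#' @param path CSV file.
#' @return a [calibration_dataset()].
#' @export
read_timecourse <- function(path) {
  calibration_dataset(utils::read.csv(path, stringsAsFactors = FALSE))
}

# simulated value matching one observation row; cell cholesterol is the
# sum of the intracellular pools (the assay measures total cholesterol)
.sim_value <- function(traj, compartment, species, time) {
  i <- match(time, traj$times)
  if (is.na(i)) stop("simulated trajectory does not cover t = ", time,
                     " h; record times must include every dataset time ",
                     "point (no interpolation)")
  if (species == "CHOL") {
    if (compartment == "medium") traj$states[i, "CHOL"]
    else sum(traj$states[i, c("CHOS", "CHOC", "CHOM", "CHOR", "CHON")])
  } else {
    traj$states[i, paste0(species, if (compartment == "medium") "_med"
                          else "_cell")]
  }
}

#' Normalized least squares distance (NLSD)
#'
#' The calibration objective: squared differences between measured and
#' simulated concentrations, normalized per trace by the squared maximum
#' measured concentration, summed over compartments, species, and time
#' points. Censored (below-LLOQ) points are excluded, not imputed. The
#' normalization makes the objective invariant under rescaling the units
#' of any single species.
#'
#' \deqn{\mathrm{NLSD}=\sum_h\sum_i\sum_j
#'   \left(X^{exp}_{h,i,j}-X^{sim}_{h,i,j}\right)^2 / (X^{max}_{h,i})^2}
#'
#' @param dataset a [calibration_dataset()].
#' @param trajectory a `steroid_trajectory` whose record grid covers all
#'   dataset time points (an off-grid time point is an error; values are
#'   never interpolated).
#' @return nonnegative scalar.
#' @export
nlsd <- function(dataset, trajectory) {
  stopifnot(inherits(dataset, "calibration_dataset"))
  obs <- dataset$obs[!dataset$obs$censored, ]
  if (!nrow(obs)) return(0)
  sim <- mapply(.sim_value, obs$compartment, obs$species, obs$time_h,
                MoreArgs = list(traj = trajectory))
  xmax <- dataset$xmax[paste(obs$compartment, obs$species, sep = ".")]
  sum(((obs$value - sim) / xmax)^2)
}

# residual vector whose sum of squares is the NLSD
.nlsd_residuals <- function(dataset, trajectory) {
  obs <- dataset$obs[!dataset$obs$censored, ]
  sim <- mapply(.sim_value, obs$compartment, obs$species, obs$time_h,
                MoreArgs = list(traj = trajectory))
  xmax <- dataset$xmax[paste(obs$compartment, obs$species, sep = ".")]
  as.numeric((obs$value - sim) / xmax)
}

#' Fit kinetic parameters to time-course data
#'
#' Levenberg-Marquardt minimization of the [nlsd()] objective over a
#' selected subset of the 42-item kinetic inventory. Parameters are
#' optimized in log space: all are positive and span decades, and the
#' log transform makes the search scale-free. Deterministic given the
#' starting point.
#'
#' @param model a [steroidogenesis_model()] providing the starting
#'   parameter values, initial state and geometry.
#' @param dataset a [calibration_dataset()].
#' @param free character vector of kinetic parameter names to optimize
#'   (at least one; see [kinetic_parameter_names()]).
#' @param lower,upper bounds on the free parameters (natural scale);
#'   defaults span 1e-4x to 1e4x the start.
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @return object of class `calibration_fit`: the optimized parameter
#'   set, initial and final NLSD, and the per-iteration deviance trace.
#'   `coef()` returns the fitted values.
#' @export
fit_parameters <- function(model, dataset, free,
                           lower = NULL, upper = NULL,
                           control = list(maxiter = 50)) {
  stopifnot(inherits(model, "steroidogenesis_model"),
            inherits(dataset, "calibration_dataset"))
  kin <- model$params$kin
  bad <- setdiff(free, names(kin))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  if (!length(free)) stop("'free' must select at least one parameter")
  start <- kin[free]
  if (any(start <= 0))
    stop("free parameters must start positive for log-space optimization")
  if (is.null(lower)) lower <- start * 1e-4
  if (is.null(upper)) upper <- start * 1e4
  if (any(lower <= 0)) stop("bounds must be positive")

  rec <- dataset$times
  if (rec[1] != 0) rec <- c(0, rec)
  make_model <- function(theta) {
    kin2 <- kin
    kin2[free] <- exp(theta)
    p <- model$params
    steroidogenesis_model(
      kinetic_parameters(kin2, diff_f = p$diff_f, diff_b = p$diff_b,
                         kdist_f = p$kdist_f, kdist_b = p$kdist_b,
                         geometry = p$geometry),
      activities = model$activities, initial_state = model$initial_state,
      dilution = model$dilution)
  }
  resid_fn <- function(theta) {
    tr <- simulate(make_model(theta), record_times = rec)
    r <- .nlsd_residuals(dataset, tr)
    if (any(!is.finite(r))) r[!is.finite(r)] <- 1e6  # backtrack signal
    r
  }
  nlsd0 <- sum(resid_fn(log(start))^2)
  fit <- minpack.lm::nls.lm(par = log(start), fn = resid_fn,
                            lower = log(lower), upper = log(upper),
                            control = do.call(minpack.lm::nls.lm.control,
                                              control))
  est <- exp(fit$par)
  names(est) <- free
  final <- fit$deviance
  if (final > nlsd0) {  # LM never accepts an uphill step, but be safe
    est <- start
    final <- nlsd0
  }
  kin_out <- kin
  kin_out[free] <- est
  p <- model$params
  structure(list(
    params = kinetic_parameters(kin_out, diff_f = p$diff_f,
                                diff_b = p$diff_b, kdist_f = p$kdist_f,
                                kdist_b = p$kdist_b, geometry = p$geometry),
    estimate = est, nlsd = final, nlsd_initial = nlsd0,
    trace = fit$rsstrace, niter = fit$niter,
    message = fit$message, free = free, model = model),
    class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Kinetic parameter fit (Levenberg-Marquardt on log parameters)\n")
  cat(sprintf("  NLSD: %.6g -> %.6g in %d iterations\n",
              x$nlsd_initial, x$nlsd, x$niter))
  print(signif(x$estimate, 4))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) object$estimate

#' Fitting sensitivity of the calibration objective
#'
#' Relative finite-difference effect of each static kinetic parameter on
#' the NLSD: `|NLSD(x(1+delta)) - NLSD(x)| / (NLSD(x) delta)`. Parameters
#' with no influence on the observed traces score 0. When the baseline
#' NLSD is 0 (exact fit) scores are reported on the absolute scale and
#' flagged via the `"absolute_scale"` attribute.
#'
#' @param model a `steroidogenesis_model` (the calibrated model).
#' @param dataset a [calibration_dataset()].
#' @param delta relative perturbation (default 0.1, i.e. +10%).
#' @param parameters which kinetic parameters to score (default all 42).
#' @return data.frame (`parameter`, `score`) sorted by decreasing score.
#' @export
fitting_sensitivity <- function(model, dataset, delta = 0.1,
                                parameters = kinetic_parameter_names()) {
  rec <- unique(c(0, dataset$times))
  base <- nlsd(dataset, simulate(model, record_times = rec))
  absolute <- base == 0
  kin <- model$params$kin
  p <- model$params
  score <- vapply(parameters, function(nm) {
    kin2 <- kin
    kin2[nm] <- kin2[nm] * (1 + delta)
    m2 <- steroidogenesis_model(
      kinetic_parameters(kin2, diff_f = p$diff_f, diff_b = p$diff_b,
                         kdist_f = p$kdist_f, kdist_b = p$kdist_b,
                         geometry = p$geometry),
      activities = model$activities, initial_state = model$initial_state,
      dilution = model$dilution)
    v <- nlsd(dataset, simulate(m2, record_times = rec))
    if (absolute) abs(v - base) / delta else abs(v - base) / (base * delta)
  }, 0)
  out <- data.frame(parameter = parameters, score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  structure(out, absolute_scale = absolute)
}

#' Initial state from t = 0 measurements
#'
#' Sets medium steroid concentrations from the t = 0 data, intracellular
#' steroid concentrations to the passive-diffusion equilibrium implied
#' by the transport law (`kf * medium = kb * cell`, i.e. cell =
#' kf/kb * medium: steroids are assumed to equilibrate rapidly across
#' the membrane), and the cholesterol pools from configured initial
#' values.
#'
#' @param dataset a [calibration_dataset()] with t = 0 medium values.
#' @param params a [kinetic_parameters()].
#' @param cholesterol named vector of initial pool concentrations
#'   (CHOL, CHOS, CHOC, CHOM, CHOR, CHON, OXY); defaults from
#'   [default_initial_state()], with medium CHOL overridden by the
#'   t = 0 measurement when present.
#' @return named state vector of length 35.
#' @export
equilibrate_initial_state <- function(dataset, params,
                                      cholesterol = NULL) {
  stopifnot(inherits(dataset, "calibration_dataset"))
  x <- default_initial_state(params)
  if (!is.null(cholesterol)) x[names(cholesterol)] <- cholesterol
  obs0 <- dataset$obs[dataset$obs$time_h == 0 &
                        dataset$obs$compartment == "medium" &
                        !dataset$obs$censored, ]
  sp <- steroid_species()
  med <- stats::setNames(rep(NA_real_, 14), sp)
  med[intersect(obs0$species, sp)] <-
    obs0$value[match(intersect(obs0$species, sp), obs0$species)]
  if (any(is.na(med))) {
    warning("no t = 0 medium measurement for ",
            paste(sp[is.na(med)], collapse = ", "),
            "; initialized to 0")
    med[is.na(med)] <- 0
  }
  if ("CHOL" %in% obs0$species)
    x["CHOL"] <- obs0$value[obs0$species == "CHOL"]
  ratio <- ifelse(params$diff_b > 0, params$diff_f / params$diff_b, 1)
  x[paste0(sp, "_med")] <- med
  x[paste0(sp, "_cell")] <- med * ratio
  x
}
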