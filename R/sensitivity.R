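#' Dynamic sensitivity of steroid concentrations to a kinetic parameter
#'
#' Time-resolved relative response to a one-sided parameter
#' perturbation:
#' \deqn{S_{x,y}(t) = \frac{\Delta y(t)/y(t)}{\Delta x/x}}
#' computed from a single forward simulation with the parameter scaled
#' by `1 + delta` (default +10%), against the unperturbed baseline.
#'
#' @param model a [steroidogenesis_model()].
#' @param param one of the 42 kinetic parameter names.
#' @param species species to evaluate (steroids and/or `"CHOL"`).
#' @param times evaluation times (h); must include only times >= 0.
#' @param delta relative perturbation (default 0.1).
#' @param compartment `"medium"` (the displayed convention) or
#'   `"cell"` (the cytosolic variant).
#' @param baseline optional precomputed baseline trajectory on a grid
#'   covering `times`.
#' @return matrix times x species; entries where the baseline
#'   concentration is 0 are `NA` (undefined sensitivity).
#' @export
dynamic_sensitivity <- function(model, param,
                                species = c("CHOL", steroid_species()),
                                times = seq(0, 72, 6), delta = 0.1,
                                compartment = c("medium", "cell"),
                                baseline = NULL) {
  compartment <- match.arg(compartment)
  if (!param %in% kinetic_parameter_names())
    stop("'param' must be one of the 42 kinetic parameters")
  rec <- sort(unique(c(0, times)))
  if (is.null(baseline)) baseline <- simulate(model, record_times = rec)
  y0 <- trajectory_concentration(baseline, species, compartment, times)
  p <- model$params
  kin2 <- p$kin
  kin2[param] <- kin2[param] * (1 + delta)
  m2 <- steroidogenesis_model(
    kinetic_parameters(kin2, diff_f = p$diff_f, diff_b = p$diff_b,
                       kdist_f = p$kdist_f, kdist_b = p$kdist_b,
                       geometry = p$geometry),
    activities = model$activities, initial_state = model$initial_state,
    dilution = model$dilution)
  y1 <- trajectory_concentration(simulate(m2, record_times = rec),
                                 species, compartment, times)
  s <- ((y1 - y0) / y0) / delta
  s[y0 == 0] <- NA_real_
  s
}

#' Full dynamic sensitivity matrix
#'
#' Sensitivities of every species to every parameter of the 42-item
#' kinetic inventory on a 6-h grid to 72 h (one forward simulation per
#' parameter plus one baseline).
#'
#' @inheritParams dynamic_sensitivity
#' @param parameters kinetic parameters to scan (default all 42).
#' @return object of class `sensitivity_matrix`: a 3-d array
#'   `[parameter, species, time]` with attributes `times`, `delta`,
#'   `compartment`.
#' @export
sensitivity_heatmap <- function(model,
                                species = c("CHOL", steroid_species()),
                                times = seq(6, 72, 6), delta = 0.1,
                                compartment = "medium",
                                parameters = kinetic_parameter_names()) {
  rec <- sort(unique(c(0, times)))
  baseline <- simulate(model, record_times = rec)
  arr <- array(NA_real_,
               dim = c(length(parameters), length(species), length(times)),
               dimnames = list(parameters, species, times))
  for (p in parameters) {
    s <- dynamic_sensitivity(model, p, species, times, delta,
                             compartment, baseline = baseline)
    arr[p, , ] <- t(s)
  }
  structure(arr, times = times, delta = delta, compartment = compartment,
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "Dynamic sensitivity matrix: %d parameters x %d species x %d times (%s)\n",
    d[1], d[2], d[3], attr(x, "compartment")))
  cat(sprintf("  |S| range: %.3g .. %.3g (NA: %d undefined cells)\n",
              min(abs(x), na.rm = TRUE), max(abs(x), na.rm = TRUE),
              sum(is.na(x))))
  invisible(x)
}

#' @export
plot.sensitivity_matrix <- function(x, ...) {
  auc <- apply(x, c(1, 2), function(s) {
    t <- attr(x, "times")
    ok <- !is.na(s)
    if (sum(ok) < 2) return(NA_real_)
    sum(diff(t[ok]) * (abs(s[ok])[-sum(ok)] + abs(s[ok])[-1]) / 2)
  })
  graphics::image(seq_len(nrow(auc)), seq_len(ncol(auc)), log10(auc + 1e-12),
                  xlab = "parameter (inventory order)", ylab = "",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, ...)
  graphics::axis(1, seq_len(nrow(auc)), cex.axis = 0.5)
  graphics::axis(2, seq_len(ncol(auc)), colnames(auc), las = 2,
                 cex.axis = 0.6)
  invisible(auc)
}

#' Export a sensitivity matrix as tidy CSV
#'
#' Columns `parameter`, `species`, `time`, `S`.
#' @param x a `sensitivity_matrix`.
#' @param path output file.
#' @export
write_sensitivity <- function(x, path) {
  d <- dimnames(x)
  df <- expand.grid(parameter = d[[1]], species = d[[2]],
                    time = as.numeric(d[[3]]), stringsAsFactors = FALSE)
  df$S <- as.vector(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Rank parameters by total unsigned sensitivity AUC
#'
#' For each parameter, the trapezoidal integral of `|S(t)|` over time is
#' summed over species. The unsigned form is used so that sensitivities
#' that change sign over the time course (as the intermediate steroids'
#' do) are not cancelled; the score is an importance measure. Undefined
#' cells are dropped from the integral.
#'
#' @param x a [sensitivity_heatmap()] result.
#' @return data.frame (`parameter`, `auc`) in descending order.
#' @export
auc_ranking <- function(x) {
  stopifnot(inherits(x, "sensitivity_matrix"))
  t <- attr(x, "times")
  auc_curve <- function(s) {
    ok <- !is.na(s)
    if (sum(ok) < 2) return(0)
    tt <- t[ok]
    ss <- abs(s[ok])
    sum(diff(tt) * (ss[-length(ss)] + ss[-1]) / 2)
  }
  per_param <- apply(x, 1, function(m) sum(apply(m, 1, auc_curve)))
  out <- data.frame(parameter = dimnames(x)[[1]], auc = unname(per_param),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$auc), ]
  rownames(out) <- NULL
  out
}
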