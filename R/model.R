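#' Competing-substrate rapid-equilibrium reaction rates
#'
#' Rate law for a single-active-site enzyme shared by several substrates:
#' \deqn{v_i = a \, V_{max,i} \frac{S_i/K_{m,i}}{1 + \sum_j S_j/K_{m,j}}}
#' Each substrate's rate is reduced by the occupancy of every other
#' substrate, which realizes the substrate inhibition characteristic of
#' the steroidogenic enzymes (most recognize several steroids).
#'
#' @param Vmax,Km,S numeric vectors of equal length (one entry per
#'   substrate); Km > 0, S >= 0.
#' @param activity nonnegative scalar multiplier of enzyme activity.
#' @return numeric vector of per-substrate rates; each is bounded by
#'   `activity * Vmax`.
#' @examples
#' competing_substrate_rates(c(10, 10), c(1, 1), c(1, 1))  # 10/3 each
#' @export
competing_substrate_rates <- function(Vmax, Km, S, activity = 1) {
  n <- length(Vmax)
  if (length(Km) != n || length(S) != n)
    stop("Vmax, Km and S must have the same length")
  if (n < 1L) stop("at least one substrate is required")
  if (any(!is.finite(Vmax)) || any(!is.finite(Km)) || any(!is.finite(S)))
    stop("non-finite input")
  if (any(Km <= 0)) stop("Km must be > 0")
  if (any(S < 0) || any(Vmax < 0) || activity < 0)
    stop("negative input rejected: S, Vmax and activity must be >= 0")
  occ <- S / Km
  activity * Vmax * occ / (1 + sum(occ))
}

#' First-order flux
#'
#' @param k rate constant (1/h), `k >= 0`.
#' @param S concentration, `S >= 0`.
#' @return `k * S`.
#' @export
first_order_flux <- function(k, S) {
  if (any(k < 0) || any(S < 0)) stop("negative input rejected")
  k * S
}

#' Default initial state
#'
#' A synthetic control initial condition at the start of stimulation:
#' fresh stimulation medium (no steroids in the medium yet), medium
#' cholesterol around 5 umol/L, a loaded intracellular cholesterol
#' store, and small basal intracellular steroid concentrations carried
#' over from pre-stimulation steroidogenesis. When calibrating to
#' measured data use [equilibrate_initial_state()] instead. Values are
#' placeholders with realistic orders of magnitude, not measured data.
#'
#' @param params a [kinetic_parameters] object (unused by the default
#'   values but kept so alternative initializers share the signature).
#' @return named numeric state vector of length 35 (see [state_names()]).
#' @export
default_initial_state <- function(params = default_parameters()) {
  sp <- steroid_species()
  cell <- c(PREG = 50, HPREG = 20, DHEA = 10, PROG = 10, HPROG = 10,
            DIONE = 5, TESTO = 2, DCORTICO = 20, DCORT = 15,
            CORTICO = 30, CORT = 25, ALDO = 0.2, E1 = 0.5, E2 = 0.2)[sp]
  x <- c(CHOL = 5000, CHOS = 30000, CHOC = 10000, CHOM = 3000,
         CHOR = 1500, CHON = 800, OXY = 0,
         stats::setNames(cell, paste0(sp, "_cell")),
         stats::setNames(rep(0, 14), paste0(sp, "_med")))
  x[state_names()]
}

#' Construct a steroidogenesis model
#'
#' Bundles a kinetic parameter set, enzyme activity multipliers, an
#' initial state and the dilution switch into a model object that
#' [simulate()] integrates. Activity multipliers scale each enzyme's
#' Vmax (or rate constant for CYP11B2); 1 means unperturbed.
#'
#' @param params a [kinetic_parameters] object.
#' @param activities named numeric vector of activity multipliers for
#'   (a subset of) [enzyme_names()]; missing enzymes default to 1.
#' @param initial_state named state vector (see [state_names()]).
#' @param dilution logical; dilute intracellular concentrations by cell
#'   volume growth, `d log V/dt = g_n + g_v` (default TRUE).
#' @return object of class `steroidogenesis_model`.
#' @examples
#' m <- steroidogenesis_model()
#' m2 <- steroidogenesis_model(activities = c(CYP11B1 = 0.1))
#' @export
steroidogenesis_model <- function(params = default_parameters(),
                                  activities = NULL,
                                  initial_state = default_initial_state(params),
                                  dilution = TRUE) {
  stopifnot(inherits(params, "kinetic_parameters"))
  act <- stats::setNames(rep(1, 9), enzyme_names())
  if (!is.null(activities)) {
    if (is.null(names(activities)))
      stop("'activities' must be named by enzyme")
    bad <- setdiff(names(activities), enzyme_names())
    if (length(bad)) stop("unknown enzyme(s): ", paste(bad, collapse = ", "))
    if (any(activities < 0)) stop("activities must be >= 0")
    act[names(activities)] <- activities
  }
  x0 <- initial_state
  if (length(x0) != 35L) stop("initial_state must have length 35")
  if (!is.null(names(x0))) {
    if (!setequal(names(x0), state_names()))
      stop("initial_state names must match state_names()")
    x0 <- x0[state_names()]
  } else names(x0) <- state_names()
  if (any(!is.finite(x0)) || any(x0 < 0))
    stop("initial_state must be finite and >= 0")
  structure(list(params = params, activities = act,
                 initial_state = x0, dilution = isTRUE(dilution)),
            class = "steroidogenesis_model")
}

#' @export
print.steroidogenesis_model <- function(x, ...) {
  cat("Two-compartment kinetic model of adrenal steroidogenesis\n")
  cat("  35 states: 7 cholesterol pools + 14 steroids x {cell, medium}\n")
  cat("  17 enzymatic reactions / 9 enzymes\n")
  pert <- x$activities[x$activities != 1]
  if (length(pert))
    cat("  perturbed activities:",
        paste(sprintf("%s = %.3g", names(pert), pert), collapse = ", "), "\n")
  else cat("  all enzyme activities at baseline (1)\n")
  cat("  dilution by cell growth:", x$dilution, "\n")
  invisible(x)
}

#' Update a model's enzyme activities
#'
#' @param model a `steroidogenesis_model`.
#' @param activities named activity multipliers (as in
#'   [steroidogenesis_model()]); replaces only the named entries.
#' @param reset start from all-ones rather than the model's current
#'   activities.
#' @return the modified model.
#' @export
set_activities <- function(model, activities, reset = TRUE) {
  stopifnot(inherits(model, "steroidogenesis_model"))
  base <- if (reset) NULL else model$activities
  steroidogenesis_model(model$params,
                        activities = if (reset) activities
                                     else replace(model$activities,
                                                  names(activities),
                                                  activities),
                        initial_state = model$initial_state,
                        dilution = model$dilution)
}

# pack model into the flat list the C++ integrator takes
.pack_pars <- function(model) {
  p <- model$params
  list(kin = unname(p$kin), act = unname(model$activities),
       diff_f = unname(p$diff_f), diff_b = unname(p$diff_b),
       kdist_f = p$kdist_f, kdist_b = p$kdist_b,
       n0 = p$geometry$n0, g_n = p$geometry$g_n,
       v0 = p$geometry$v0, g_v = p$geometry$g_v,
       v_med = p$geometry$v_med, dilution = model$dilution)
}

#' Evaluate the model right-hand side
#'
#' Assembles the time derivative of all 35 state variables: cholesterol
#' uptake, ester storage/release, mitochondrial transfer, StAR-mediated
#' localization, the oxysterol bypass, the 17 enzymatic reactions,
#' passive steroid diffusion with volume-correct amount bookkeeping,
#' and dilution by cell growth.
#'
#' @param model a `steroidogenesis_model`.
#' @param t time (h).
#' @param state state vector; defaults to the model's initial state.
#' @return list with `deriv` (named derivative vector, nmol/L/h) and
#'   `max_rate` (largest absolute flux velocity, used by the adaptive
#'   step-size rule).
#' @export
ode_rhs <- function(model, t = 0, state = model$initial_state) {
  stopifnot(inherits(model, "steroidogenesis_model"))
  if (!is.null(names(state))) state <- state[state_names()]
  res <- cpp_rhs(t, as.numeric(state), .pack_pars(model))
  d <- stats::setNames(res$deriv, state_names())
  if (any(!is.finite(d)))
    stop("non-finite derivative for species: ",
         paste(state_names()[!is.finite(d)], collapse = ", "))
  list(deriv = d, max_rate = res$max_rate)
}

#' Total cell volume at time t
#'
#' `N(t) v(t) = n0 v0 exp((g_n + g_v) t)`, in mL.
#'
#' @param geometry geometry list (see [default_geometry()]).
#' @param t time (h).
#' @export
cell_volume <- function(geometry, t = 0) {
  geometry$n0 * geometry$v0 * exp((geometry$g_n + geometry$g_v) * t)
}

#' Total molar amount of cholesterol-derived species
#'
#' Sums concentration times compartment volume over every pool and both
#' compartments (including the oxysterol sink): medium species in the
#' medium volume, intracellular species in the total cell volume at
#' time `t`. With dilution enabled this quantity is conserved along any
#' trajectory (all reactions are 1:1 and transport is amount-correct).
#'
#' @param state named state vector (nmol/L).
#' @param geometry geometry list.
#' @param t time (h) at which the cell volume is evaluated.
#' @return total amount in nmol.
#' @export
total_mass <- function(state, geometry, t = 0) {
  if (!is.null(names(state))) state <- state[state_names()]
  v_cell <- cell_volume(geometry, t)  # mL
  med_idx <- c(1L, 22:35)             # CHOL + 14 medium steroids
  cell_idx <- setdiff(seq_len(35L), med_idx)
  # nmol/L * mL = 1e-3 nmol
  (sum(state[med_idx]) * geometry$v_med +
      sum(state[cell_idx]) * v_cell) * 1e-3
}
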