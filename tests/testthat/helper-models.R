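# shared fixtures, built in code

# parameter set with every rate constant and Vmax zeroed (Km kept
# positive); the RHS of this model is identically zero
zero_parameters <- function() {
  p <- default_parameters()
  kin <- p$kin
  kin[!grepl("^Km", names(kin))] <- 0
  kinetic_parameters(kin, diff_f = 0, kdist_f = 0, kdist_b = 0,
                     geometry = p$geometry)
}

# geometry without growth, so closed-form oracles see constant volumes
static_geometry <- function() {
  g <- default_geometry()
  g$g_n <- 0
  g$g_v <- 0
  g
}

# model with a single first-order reaction CHOL -> CHOC (linear decay
# of CHOL at rate k); everything else switched off
decay_model <- function(k = 1, x0 = 100) {
  p <- zero_parameters()
  kin <- p$kin
  kin["k_CholesterolTransport"] <- k
  state <- default_initial_state()
  state[] <- 0
  state["CHOL"] <- x0
  steroidogenesis_model(
    kinetic_parameters(kin, diff_f = 0, kdist_f = 0, kdist_b = 0,
                       geometry = static_geometry()),
    initial_state = state, dilution = FALSE)
}

# two-step first-order chain CHOC -> CHOM -> CHOR
chain_model <- function(k1 = 0.5, k2 = 0.3, a0 = 10) {
  p <- zero_parameters()
  kin <- p$kin
  kin["k_f_MTR"] <- k1
  state <- default_initial_state()
  state[] <- 0
  state["CHOC"] <- a0
  steroidogenesis_model(
    kinetic_parameters(kin, diff_f = 0, kdist_f = k2, kdist_b = 0,
                       geometry = static_geometry()),
    initial_state = state, dilution = FALSE)
}

# small noiseless synthetic calibration dataset from a model
noiseless_dataset <- function(model, species = c("PREG", "CORTICO", "CORT"),
                              times = c(0, 8, 24, 48, 72)) {
  spec <- synth_spec(cv = 0, lloq = 0, times = times, seed = 1)
  ds <- generate_timecourse(spec, model)
  raw <- attr(ds, "raw")[attr(ds, "raw")$species %in% species, ]
  out <- calibration_dataset(raw)
  attr(out, "raw") <- raw
  out
}

# reduced GA budget for fast recovery tests; the local search supplies
# the precision
fast_moa_config <- function(...) {
  args <- utils::modifyList(
    list(max_generations = 40, pop_size = 40, n_parents = 5,
         n_children = 12, duplicate = FALSE),
    list(...))
  do.call(moa_config, args)
}
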