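#' Specification for synthetic dataset generation
#'
#' Describes how to emulate the statistical structure of the in vitro
#' steroidogenesis assay: the assay time grid {0, 8, 24, 48, 72} h, two
#' compartments, 4 replicate wells per time point, multiplicative
#' log-normal measurement noise (LC-MS-like constant CV), and
#' steroid-specific LLOQ censoring (the minor steroids ALDO, TESTO and
#' E2 get the highest LLOQ, reproducing the censoring pathology of real
#' panels). True assay LLOQs are not public; the defaults are
#' placeholders on the synthetic concentration scale.
#'
#' @param planted_activities named enzyme-activity multipliers defining
#'   a known perturbation (ground truth for recovery benchmarks); NULL
#'   for the unperturbed control.
#' @param cv coefficient of variation of the multiplicative log-normal
#'   noise (default 0.1).
#' @param replicates wells per time point (default 4).
#' @param lloq named per-steroid LLOQ (nmol/L, medium scale).
#' @param times sampling times (h).
#' @param seed RNG seed recorded into every generated artifact.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(planted_activities = NULL, cv = 0.1,
                       replicates = 4, lloq = default_lloq(),
                       times = c(0, 8, 24, 48, 72), seed = 1) {
  stopifnot(cv >= 0, replicates >= 1)
  sp <- steroid_species()
  if (length(lloq) == 1L) lloq <- stats::setNames(rep(lloq, 14), sp)
  lloq <- lloq[sp]
  structure(list(planted_activities = planted_activities, cv = cv,
                 replicates = replicates, lloq = lloq, times = times,
                 seed = seed),
            class = "synth_spec")
}

#' @rdname synth_spec
#' @export
default_lloq <- function() {
  sp <- steroid_species()
  l <- stats::setNames(rep(0.02, 14), sp)
  l[c("ALDO", "TESTO", "E2")] <- 0.15
  l
}

# one multiplicative log-normal noise factor matrix with E[factor] = 1
.noise_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic steroid time-course dataset
#'
#' Simulates the model (with any planted activity perturbation), samples
#' both compartments at the spec's time grid, applies i.i.d.
#' multiplicative log-normal noise per replicate, and censors
#' observations below the LLOQ. Cholesterol (medium and total
#' intracellular) is included, mirroring the measured panel. The
#' noiseless ground-truth table and the spec (including the seed) are
#' attached as attributes.
#'
#' @param spec a [synth_spec()].
#' @param model baseline [steroidogenesis_model()].
#' @return a [calibration_dataset()] with attributes `truth` and `spec`.
#' @export
generate_timecourse <- function(spec, model = steroidogenesis_model()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  m <- if (is.null(spec$planted_activities)) model
       else set_activities(model, spec$planted_activities)
  rec <- sort(unique(c(0, spec$times)))
  tr <- simulate(m, record_times = rec)
  sp <- steroid_species()
  rows <- list()
  for (comp in c("medium", "cell")) {
    for (s in c(sp, "CHOL")) {
      truth <- vapply(spec$times, function(t)
        .sim_value(tr, comp, s, t), 0)
      lloq_s <- if (s == "CHOL") 0 else spec$lloq[s]
      for (j in seq_along(spec$times)) {
        vals <- truth[j] * .noise_factors(spec$replicates, spec$cv)
        rows[[length(rows) + 1L]] <- data.frame(
          compartment = comp, species = s, time_h = spec$times[j],
          replicate = seq_len(spec$replicates), value = vals,
          below_lloq = vals < lloq_s, stringsAsFactors = FALSE)
      }
    }
  }
  raw <- do.call(rbind, rows)
  out <- calibration_dataset(raw)
  attr(out, "truth") <- tr
  attr(out, "spec") <- spec
  attr(out, "raw") <- raw
  out
}

#' Generate a synthetic 72-h fold-change profile
#'
#' Simulates a treated arm (the spec's planted activities) and a control
#' arm (unperturbed), applies replicate-level multiplicative noise to
#' each arm's 72-h medium concentrations, censors each arm at the LLOQ
#' before taking the ratio, and returns the per-steroid
#' treated/control profile. A steroid censored in either arm is flagged
#' censored in the profile (ratio undefined or unreliable, as in real
#' panels where strong inhibition pushes ALDO or TESTO below the LLOQ).
#'
#' @param spec a [synth_spec()] with non-NULL `planted_activities`
#'   (all-ones for a null compound).
#' @param model baseline [steroidogenesis_model()].
#' @return a [foldchange_profile()] with attributes `truth_activities`
#'   and `spec`.
#' @export
generate_foldchange <- function(spec, model = steroidogenesis_model()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  sp <- lcms_steroids()
  rec <- c(0, 72)
  ctrl <- trajectory_concentration(
    simulate(model, record_times = rec), sp, "medium", 72)[1, ]
  treated_model <- if (is.null(spec$planted_activities)) model
                   else set_activities(model, spec$planted_activities)
  trt <- trajectory_concentration(
    simulate(treated_model, record_times = rec), sp, "medium", 72)[1, ]
  ctrl_obs <- ctrl * vapply(seq_along(sp), function(i)
    mean(.noise_factors(spec$replicates, spec$cv)), 0)
  trt_obs <- trt * vapply(seq_along(sp), function(i)
    mean(.noise_factors(spec$replicates, spec$cv)), 0)
  lloq <- spec$lloq[sp]
  censored <- trt_obs < lloq | ctrl_obs < lloq
  fc <- ifelse(ctrl_obs > 0, trt_obs / ctrl_obs, NA_real_)
  fc[censored | !is.finite(fc)] <- 1  # placeholder; flagged censored
  censored <- censored | !is.finite(trt_obs / ctrl_obs)
  names(fc) <- sp
  out <- foldchange_profile(fc, censored = censored)
  attr(out, "truth_activities") <- spec$planted_activities
  attr(out, "spec") <- spec
  out
}

#' Synthetic inhibitor panel with known mechanisms
#'
#' Builds a compound panel emulating a screening study: a mix of null
#' compounds (no steroidogenic action) and single- or two-enzyme
#' inhibitors tested at several "concentrations". Planted activity
#' follows a one-site binding law `a = 1 / (1 + dose/IC50)`, so higher
#' doses plant monotonically stronger inhibition. Returns the
#' fold-change profiles plus the ground-truth table for end-to-end
#' benchmarking of [estimate_moa()] and [cluster_profiles()].
#'
#' @param n_compounds number of compounds (>= 2; roughly one third are
#'   null compounds).
#' @param seed RNG seed.
#' @param model baseline model.
#' @param doses tested "concentrations" (arbitrary units).
#' @param cv measurement noise CV.
#' @return object of class `inhibitor_panel`: list with `profiles`
#'   (named list of [foldchange_profile()]s), `truth` (data.frame:
#'   compound, dose, target enzymes, planted activities), and `log2fc`
#'   (matrix for clustering).
#' @export
make_inhibitor_panel <- function(n_compounds = 6, seed = 1,
                                 model = steroidogenesis_model(),
                                 doses = c(1, 10, 100), cv = 0.1) {
  stopifnot(n_compounds >= 2)
  set.seed(seed)
  enz <- moa_enzymes()
  n_null <- max(1L, round(n_compounds / 3))
  kind <- c(rep("null", n_null), rep("inhibitor", n_compounds - n_null))
  profiles <- list()
  truth <- list()
  for (i in seq_len(n_compounds)) {
    name <- sprintf("C%02d", i)
    if (kind[i] == "null") {
      targets <- character(0)
      ic50 <- numeric(0)
    } else {
      n_t <- sample(1:2, 1)
      targets <- sample(enz, n_t)
      ic50 <- stats::setNames(10^stats::runif(n_t, 0, 1.5), targets)
    }
    for (dose in doses) {
      acts <- stats::setNames(rep(1, length(targets)), targets)
      if (length(targets))
        acts[] <- 1 / (1 + dose / ic50)
      sub_seed <- sample.int(.Machine$integer.max, 1)
      sp <- synth_spec(planted_activities = if (length(acts)) acts else
                         stats::setNames(1, enz[1]),
                       cv = cv, seed = sub_seed)
      id <- sprintf("%s_%g", name, dose)
      profiles[[id]] <- generate_foldchange(sp, model)
      truth[[id]] <- data.frame(
        compound = name, dose = dose, kind = kind[i],
        targets = paste(targets, collapse = "+"),
        activities = paste(sprintf("%s=%.3g", names(acts), acts),
                           collapse = ","),
        min_activity = if (length(targets)) min(acts) else 1,
        stringsAsFactors = FALSE)
    }
  }
  log2fc <- t(vapply(profiles, function(p) {
    v <- log2(p$fc)
    v[p$censored] <- 0
    v
  }, numeric(12)))
  colnames(log2fc) <- lcms_steroids()
  structure(list(profiles = profiles, truth = do.call(rbind, truth),
                 log2fc = log2fc, seed = seed),
            class = "inhibitor_panel")
}

#' @export
print.inhibitor_panel <- function(x, ...) {
  cat(sprintf("Synthetic inhibitor panel: %d profiles (%d compounds)\n",
              length(x$profiles), length(unique(x$truth$compound))))
  print(x$truth[, c("compound", "dose", "kind", "targets")],
        row.names = FALSE)
  invisible(x)
}
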