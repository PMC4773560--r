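#' Run the analysis pipeline
#'
#' Executes the requested stages against one model and writes their
#' outputs plus a manifest (stage, wall time, seed, objective values,
#' output file hashes) to a directory. A single global seed fans out to
#' deterministic per-stage child seeds so stages are individually
#' reproducible. An empty stage list writes the manifest only.
#'
#' Stages: `"simulate"` (72-h trajectory CSV), `"sensitivity"` (dynamic
#' sensitivity CSV + AUC ranking), `"scan"` (CYP17H x HSD3B2 phenotype
#' scan CSV), `"synth"` (synthetic fold-change panel), `"moa"`
#' (mechanism-of-action estimates for the synthetic panel, JSON, with
#' truth-table comparison).
#'
#' @param stages character vector of stage names (possibly empty).
#' @param out_dir output directory (created if missing).
#' @param seed global RNG seed.
#' @param model a [steroidogenesis_model()].
#' @param moa_settings a [moa_config()] used by the `"moa"` stage.
#' @param scan_multipliers grid for the `"scan"` stage.
#' @param n_compounds panel size for `"synth"`/`"moa"`.
#' @return the manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(stages = c("simulate", "sensitivity", "scan"),
                         out_dir, seed = 1,
                         model = steroidogenesis_model(),
                         moa_settings = moa_config(duplicate = FALSE,
                                                   max_generations = 200),
                         scan_multipliers = seq(0, 2, 0.1),
                         n_compounds = 4) {
  known <- c("simulate", "sensitivity", "scan", "synth", "moa")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  child_seed <- function(stage)
    (seed * 97L + match(stage, known) * 1009L) %% 2147483647L
  manifest <- list(seed = seed, stages = as.list(stages),
                   package = "adrenosim", results = list())
  panel <- NULL
  for (st in stages) {
    t0 <- Sys.time()
    info <- list(seed = child_seed(st))
    if (st == "simulate") {
      tr <- simulate(model)
      f <- file.path(out_dir, "trajectory.csv")
      write_trajectory(tr, f)
      info$files <- "trajectory.csv"
      info$n_steps <- tr$n_steps
    } else if (st == "sensitivity") {
      sm <- sensitivity_heatmap(model)
      f1 <- file.path(out_dir, "sensitivity.csv")
      write_sensitivity(sm, f1)
      rk <- auc_ranking(sm)
      f2 <- file.path(out_dir, "sensitivity_auc.csv")
      utils::write.csv(rk, f2, row.names = FALSE)
      info$files <- c("sensitivity.csv", "sensitivity_auc.csv")
      info$top_parameter <- rk$parameter[1]
    } else if (st == "scan") {
      sc <- scan_activity_grid(model, multipliers = scan_multipliers)
      f <- file.path(out_dir, "scan.csv")
      write_scan(sc, f)
      info$files <- "scan.csv"
      info$categories <- as.list(table(sc$category))
    } else if (st == "synth") {
      panel <- make_inhibitor_panel(n_compounds, seed = child_seed(st),
                                    model = model)
      f <- file.path(out_dir, "panel_log2fc.csv")
      utils::write.csv(panel$log2fc, f)
      utils::write.csv(panel$truth, file.path(out_dir, "panel_truth.csv"),
                       row.names = FALSE)
      info$files <- c("panel_log2fc.csv", "panel_truth.csv")
    } else if (st == "moa") {
      if (is.null(panel))
        panel <- make_inhibitor_panel(n_compounds,
                                      seed = child_seed("synth"),
                                      model = model)
      ests <- lapply(seq_along(panel$profiles), function(i) {
        fit <- estimate_moa(panel$profiles[[i]], model, moa_settings,
                            seed = child_seed(st) + i)
        list(profile = names(panel$profiles)[i],
             activities = as.list(round(coef(fit), 5)),
             fitness = fit$fitness,
             truth = panel$truth$activities[i])
      })
      f <- file.path(out_dir, "moa_estimates.json")
      jsonlite::write_json(ests, f, auto_unbox = TRUE, digits = NA)
      info$files <- "moa_estimates.json"
      info$mean_fitness <- mean(vapply(ests, `[[`, 0, "fitness"))
    }
    info$wall_time_s <- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    if (!is.null(info$files))
      info$sha <- as.list(tools::md5sum(file.path(out_dir, info$files)))
    manifest$results[[st]] <- info
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
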