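#' Classify the steroidogenic phenotype of a perturbed cell
#'
#' A steroid counts as "produced" when its 72-h medium concentration is
#' at least `theta` times the baseline value (default theta = 0.01).
#' Categories follow the functional classes: all 14 steroids produced;
#' mineralocorticoid-producing (ALDO produced, glucocorticoids DCORT and
#' CORT not); glucocorticoid-producing (the converse);
#' both-corticoid-producing; or terminated upstream (neither corticoid
#' branch).
#'
#' @param medium_72h named 72-h medium concentrations of the perturbed
#'   cell (all 14 steroids).
#' @param baseline_72h same for the unperturbed model.
#' @param theta production threshold relative to baseline.
#' @return character scalar, one of `"all_steroid"`,
#'   `"mineralocorticoid"`, `"glucocorticoid"`, `"both_corticoid"`,
#'   `"terminated_upstream"`. Steroids with zero baseline are excluded
#'   from the all-steroid test with a warning.
#' @export
classify_phenotype <- function(medium_72h, baseline_72h, theta = 0.01) {
  sp <- steroid_species()
  medium_72h <- medium_72h[sp]
  baseline_72h <- baseline_72h[sp]
  usable <- baseline_72h > 0
  if (!all(usable))
    warning("baseline is 0 for ", paste(sp[!usable], collapse = ", "),
            "; excluded from the all-steroid test")
  produced <- medium_72h >= theta * baseline_72h
  gluco <- any(produced[c("DCORT", "CORT")])
  aldo <- isTRUE(produced["ALDO"])
  if (all(produced[usable])) "all_steroid"
  else if (aldo && !gluco) "mineralocorticoid"
  else if (gluco && !aldo) "glucocorticoid"
  else if (gluco && aldo) "both_corticoid"
  else "terminated_upstream"
}

#' Two-dimensional enzyme-activity scan
#'
#' Simulates the model over 72 h for every combination of two enzymes'
#' activity multipliers (default CYP17H x HSD3B2, 0-200% in 10% steps:
#' a 21 x 21 = 441-cell grid) and classifies each cell's steroidogenic
#' phenotype with [classify_phenotype()]. Deterministic; a cell whose
#' integration fails is flagged (`NA` category) and the scan continues.
#'
#' @param model baseline [steroidogenesis_model()].
#' @param enzymes length-2 character vector of enzyme names.
#' @param multipliers activity multipliers for both axes (default
#'   `seq(0, 2, 0.1)`).
#' @param theta production threshold (see [classify_phenotype()]).
#' @param config an [integrator_config()].
#' @return object of class `activity_scan`: a data.frame with the two
#'   activity columns (percent), the 14 72-h medium steroid
#'   concentrations, and `category`.
#' @examples
#' \donttest{
#' sc <- scan_activity_grid(steroidogenesis_model(),
#'                          multipliers = seq(0, 2, 0.5))
#' table(sc$category)
#' }
#' @export
scan_activity_grid <- function(model, enzymes = c("CYP17H", "HSD3B2"),
                               multipliers = seq(0, 2, 0.1), theta = 0.01,
                               config = integrator_config()) {
  stopifnot(length(enzymes) == 2, all(enzymes %in% enzyme_names()))
  sp <- steroid_species()
  rec <- c(0, config$duration)
  base_tr <- simulate(model, config = config, record_times = rec)
  baseline <- trajectory_concentration(base_tr, sp, "medium",
                                       config$duration)[1, ]
  grid <- expand.grid(a1 = multipliers, a2 = multipliers)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    acts <- stats::setNames(c(grid$a1[i], grid$a2[i]), enzymes)
    med <- tryCatch({
      tr <- simulate(set_activities(model, acts), config = config,
                     record_times = rec)
      trajectory_concentration(tr, sp, "medium", config$duration)[1, ]
    }, error = function(e) NULL)
    res[[i]] <- if (is.null(med)) {
      c(stats::setNames(rep(NA_real_, 14), sp), category = NA_character_)
    } else {
      c(med, category = classify_phenotype(med, baseline, theta))
    }
  }
  steroids <- do.call(rbind, lapply(res, function(r)
    as.numeric(r[sp])))
  colnames(steroids) <- sp
  out <- data.frame(grid$a1 * 100, grid$a2 * 100, steroids,
                    category = vapply(res, `[[`, "", "category"),
                    stringsAsFactors = FALSE)
  names(out)[1:2] <- paste0(tolower(enzymes), "_pct")
  structure(out, enzymes = enzymes, theta = theta, baseline = baseline,
            class = c("activity_scan", "data.frame"))
}

#' @export
print.activity_scan <- function(x, ...) {
  cat(sprintf("Activity scan %s x %s, %d cells\n",
              attr(x, "enzymes")[1], attr(x, "enzymes")[2], nrow(x)))
  print(table(x$category, useNA = "ifany"))
  invisible(x)
}

#' @export
plot.activity_scan <- function(x, ...) {
  enz <- attr(x, "enzymes")
  a1 <- sort(unique(x[[1]]))
  a2 <- sort(unique(x[[2]]))
  cats <- c(all_steroid = "forestgreen", mineralocorticoid = "firebrick",
            glucocorticoid = "royalblue", both_corticoid = "purple",
            terminated_upstream = "gold")
  z <- matrix(match(x$category, names(cats)),
              length(a1), length(a2))[order(order(a1)), ]
  graphics::image(a1, a2, z, col = cats, zlim = c(1, 5),
                  xlab = paste(enz[1], "activity (%)"),
                  ylab = paste(enz[2], "activity (%)"), ...)
  graphics::legend("topright", legend = names(cats), fill = cats,
                   cex = 0.6, bg = "white")
  invisible(x)
}

#' Write a scan as CSV
#' @param x an `activity_scan`.
#' @param path output file.
#' @export
write_scan <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
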