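#' Names of the 42-item kinetic parameter inventory
#'
#' The kinetic parameters of the pathway in their canonical order:
#' nine transport/localization rate constants followed by the enzyme
#' constants of the nine steroidogenic enzymes (Km and Vmax per substrate
#' letter; CYP11B2 is first-order with a single rate constant). Legacy
#' listings of this inventory sometimes carry duplicated labels at
#' positions 16 and 25; the names used here resolve them to
#' `KmA_CYP17L` and `VmaxC_HSD3B2`, the only readings consistent with
#' the reaction table.
#'
#' @return character vector of length 42.
#' @export
kinetic_parameter_names <- function() {
  c("k_CholesterolTransport", "k_CEH", "k_f_MTR", "k_b_MTR",
    "k_f_acc", "k_b_acc", "k_f_loc", "k_b_loc", "k_OxysterolSynthesis",
    "Km_CYP11A1", "Vmax_CYP11A1",
    "KmA_CYP17H", "KmB_CYP17H", "VmaxA_CYP17H", "VmaxB_CYP17H",
    "KmA_CYP17L", "KmB_CYP17L", "VmaxA_CYP17L", "VmaxB_CYP17L",
    "KmA_HSD3B2", "KmB_HSD3B2", "KmC_HSD3B2",
    "VmaxA_HSD3B2", "VmaxB_HSD3B2", "VmaxC_HSD3B2",
    "KmA_CYP21A2", "KmB_CYP21A2", "VmaxA_CYP21A2", "VmaxB_CYP21A2",
    "KmA_CYP11B1", "KmB_CYP11B1", "VmaxA_CYP11B1", "VmaxB_CYP11B1",
    "k_CYP11B2",
    "KmA_HSD17B3", "KmB_HSD17B3", "VmaxA_HSD17B3", "VmaxB_HSD17B3",
    "KmA_CYP19A1", "KmB_CYP19A1", "VmaxA_CYP19A1", "VmaxB_CYP19A1")
}

#' Construct and validate a kinetic parameter set
#'
#' Bundles the 42-item kinetic inventory with per-steroid passive-diffusion
#' rate constants, the intramitochondrial CHOM/CHOR exchange pair, and the
#' cell-geometry parameters (exponential growth of cell number and
#' single-cell volume, constant medium volume).
#'
#' @param kin named numeric vector of length 42; names and order must
#'   match [kinetic_parameter_names()].
#' @param diff_f,diff_b named numeric vectors of length 14 (one per
#'   steroid): medium-to-cell and cell-to-medium diffusion rate constants
#'   (1/h). Symmetric by default.
#' @param kdist_f,kdist_b CHOM -> CHOR and CHOR -> CHOM exchange (1/h).
#' @param geometry list with `n0` (initial cell number), `g_n` (cell
#'   number growth rate, 1/h), `v0` (initial mean single-cell volume,
#'   mL), `g_v` (volume growth rate, 1/h), `v_med` (medium volume, mL).
#' @return object of class `kinetic_parameters`.
#' @seealso [default_parameters()], [read_parameters()]
#' @export
kinetic_parameters <- function(kin, diff_f, diff_b = diff_f,
                               kdist_f = 0.5, kdist_b = 0.25,
                               geometry = default_geometry()) {
  kin <- unlist(kin)
  nm <- kinetic_parameter_names()
  if (length(kin) != 42L)
    stop("'kin' must have length 42, got ", length(kin))
  if (is.null(names(kin)) || !all(names(kin) == nm)) {
    if (!is.null(names(kin)) && setequal(names(kin), nm)) {
      kin <- kin[nm]
    } else {
      missing <- setdiff(nm, names(kin))
      stop("kinetic parameter names do not match the 42-item inventory; ",
           if (length(missing)) paste0("missing: ",
                                       paste(missing, collapse = ", "))
           else "order or naming mismatch")
    }
  }
  sp <- steroid_species()
  diff_f <- .check_diff(diff_f, sp, "diff_f")
  diff_b <- .check_diff(diff_b, sp, "diff_b")
  km <- grepl("^Km", nm)
  if (any(!is.finite(kin)) )
    stop("non-finite kinetic parameter: ",
         paste(nm[!is.finite(kin)], collapse = ", "))
  if (any(kin[km] <= 0))
    stop("all Km must be > 0; offending: ",
         paste(nm[km][kin[km] <= 0], collapse = ", "))
  if (any(kin[!km] < 0))
    stop("rate constants and Vmax must be >= 0; offending: ",
         paste(nm[!km][kin[!km] < 0], collapse = ", "))
  if (kdist_f < 0 || kdist_b < 0) stop("kdist_f/kdist_b must be >= 0")
  g <- geometry
  need <- c("n0", "g_n", "v0", "g_v", "v_med")
  if (!all(need %in% names(g)))
    stop("geometry must contain: ", paste(need, collapse = ", "))
  if (g$n0 <= 0 || g$v0 <= 0 || g$v_med <= 0)
    stop("n0, v0 and v_med must be positive")
  structure(list(kin = kin, diff_f = diff_f, diff_b = diff_b,
                 kdist_f = kdist_f, kdist_b = kdist_b,
                 geometry = g[need]),
            class = "kinetic_parameters")
}

.check_diff <- function(d, sp, what) {
  d <- unlist(d)
  if (length(d) == 1L) d <- stats::setNames(rep(d, length(sp)), sp)
  if (length(d) != length(sp))
    stop("'", what, "' must have one entry per steroid (14)")
  if (is.null(names(d))) names(d) <- sp else d <- d[sp]
  if (any(!is.finite(d)) || any(d < 0))
    stop("'", what, "' must be finite and >= 0")
  d
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameter set: 42-item inventory + diffusion + geometry\n")
  cat(sprintf("  cells: n0 = %.3g, g_n = %.3g/h, v0 = %.3g mL, g_v = %.3g/h\n",
              x$geometry$n0, x$geometry$g_n, x$geometry$v0, x$geometry$g_v))
  cat(sprintf("  medium volume: %.3g mL\n", x$geometry$v_med))
  print(utils::head(round(x$kin, 4), 9))
  cat("  ... (", length(x$kin) - 9, " enzyme constants)\n", sep = "")
  invisible(x)
}

#' Default cell geometry
#'
#' Exponential growth of an NCI-H295R monolayer in a 6-well plate:
#' roughly 1e6 cells at stimulation, ~2 pL mean cell volume, slow growth
#' of both over 72 h, and 2 mL of culture medium.
#'
#' @return list with `n0`, `g_n`, `v0`, `g_v`, `v_med`.
#' @export
default_geometry <- function() {
  list(n0 = 1e6, g_n = 0.008, v0 = 2e-9, g_v = 0.002, v_med = 2.0)
}

#' Default (non-authoritative) kinetic parameter table
#'
#' A plausibility-checked default parameter set for users without a
#' calibrated table of their own. Orders of magnitude are chosen so that
#' simulated 72-h medium concentrations follow the characteristic
#' H295R ranking (PREG above CORTICO above CORT, ALDO far below) and the
#' major/moderate/minor steroid grouping, with intracellular steroid
#' concentrations well above the Km values (the saturation regime in
#' which these cells operate). These values are NOT fitted to
#' experimental time courses; calibrate with [fit_parameters()] before
#' quantitative use.
#'
#' @return object of class `kinetic_parameters`.
#' @export
default_parameters <- function() {
  kin <- c(
    k_CholesterolTransport = 1e-3,
    k_CEH = 0.05,
    k_f_MTR = 0.3, k_b_MTR = 0.1,
    k_f_acc = 0.2, k_b_acc = 0.02,
    k_f_loc = 0.4, k_b_loc = 0.2,
    k_OxysterolSynthesis = 0.02,
    Km_CYP11A1 = 5000, Vmax_CYP11A1 = 4000,
    KmA_CYP17H = 2500, KmB_CYP17H = 1500,
    VmaxA_CYP17H = 1600, VmaxB_CYP17H = 800,
    KmA_CYP17L = 1500, KmB_CYP17L = 1500,
    VmaxA_CYP17L = 250, VmaxB_CYP17L = 700,
    KmA_HSD3B2 = 2500, KmB_HSD3B2 = 1500, KmC_HSD3B2 = 1500,
    VmaxA_HSD3B2 = 1600, VmaxB_HSD3B2 = 1200, VmaxC_HSD3B2 = 700,
    KmA_CYP21A2 = 2500, KmB_CYP21A2 = 2500,
    VmaxA_CYP21A2 = 2000, VmaxB_CYP21A2 = 1600,
    KmA_CYP11B1 = 2000, KmB_CYP11B1 = 2000,
    VmaxA_CYP11B1 = 1500, VmaxB_CYP11B1 = 1200,
    k_CYP11B2 = 0.001,
    KmA_HSD17B3 = 2000, KmB_HSD17B3 = 2000,
    VmaxA_HSD17B3 = 160, VmaxB_HSD17B3 = 40,
    KmA_CYP19A1 = 2000, KmB_CYP19A1 = 2000,
    VmaxA_CYP19A1 = 260, VmaxB_CYP19A1 = 30)
  # lipophilicity-graded passive diffusion: upstream Delta5/Delta4
  # intermediates exchange slowly, end products faster
  diff_f <- c(PREG = 0.02, HPREG = 0.01, DHEA = 0.02, PROG = 0.01,
              HPROG = 0.01, DIONE = 0.02, TESTO = 0.05, DCORTICO = 0.04,
              DCORT = 0.04, CORTICO = 0.04, CORT = 0.04, ALDO = 0.04,
              E1 = 0.05, E2 = 0.05)
  kinetic_parameters(kin, diff_f = diff_f)
}

.param_unit <- function(name) {
  if (grepl("^Km", name)) "nmol/L"
  else if (grepl("^Vmax", name)) "nmol/L/h"
  else if (name == "n0") "cells"
  else if (name %in% c("v0", "v_med")) "mL"
  else "1/h"
}

.param_group <- function(name) {
  if (grepl("^(Km|Vmax|k_CYP11B2)", name)) "enzyme"
  else if (grepl("^k_diff", name)) "diffusion"
  else if (grepl("^k_dist", name)) "distribution"
  else if (name %in% c("n0", "g_n", "v0", "g_v", "v_med")) "proliferation"
  else "transport"
}

#' Parameter table input/output
#'
#' `parameter_table()` flattens a [kinetic_parameters] object into a
#' data.frame with columns `name`, `value`, `unit`, `group`;
#' `write_parameters()` writes it as CSV or JSON (by file extension);
#' `read_parameters()` (alias `load_parameters()`) reads either format
#' back, validating that every required name is present, that no unknown
#' names occur, and that units match the expected ones.
#'
#' @param params a `kinetic_parameters` object.
#' @param path file path ending in `.csv` or `.json`.
#' @return `read_parameters()` returns a validated `kinetic_parameters`
#'   object; a round trip through `write_parameters()` is the identity.
#' @examples
#' p <- read_parameters(system.file("extdata", "default_parameters.csv",
#'                                  package = "adrenosim"))
#' @export
parameter_table <- function(params) {
  stopifnot(inherits(params, "kinetic_parameters"))
  nm <- c(names(params$kin),
          paste0("k_diff_f_", names(params$diff_f)),
          paste0("k_diff_b_", names(params$diff_b)),
          "k_dist_f", "k_dist_b",
          names(params$geometry))
  val <- c(unname(params$kin), unname(params$diff_f), unname(params$diff_b),
           params$kdist_f, params$kdist_b, unlist(params$geometry))
  data.frame(name = nm, value = as.numeric(val),
             unit = vapply(nm, .param_unit, ""),
             group = vapply(nm, .param_group, ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname parameter_table
#' @export
write_parameters <- function(params, path) {
  tab <- parameter_table(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, digits = NA)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname parameter_table
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!all(c("name", "value") %in% names(tab)))
    stop("parameter file must have columns 'name' and 'value'")
  sp <- steroid_species()
  expected <- c(kinetic_parameter_names(),
                paste0("k_diff_f_", sp), paste0("k_diff_b_", sp),
                "k_dist_f", "k_dist_b", "n0", "g_n", "v0", "g_v", "v_med")
  unknown <- setdiff(tab$name, expected)
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         "; expected names are: ", paste(expected, collapse = ", "))
  missing <- setdiff(expected, tab$name)
  if (length(missing))
    stop("missing required parameter(s): ", paste(missing, collapse = ", "))
  if ("unit" %in% names(tab)) {
    want <- vapply(tab$name, .param_unit, "")
    bad <- tab$unit != want
    if (any(bad))
      stop("unit mismatch for ", paste(tab$name[bad], collapse = ", "),
           "; expected ", paste(unique(want[bad]), collapse = ", "),
           " (concentrations in nmol/L, time in hours, volumes in mL)")
  }
  v <- stats::setNames(tab$value, tab$name)
  kinetic_parameters(
    kin = v[kinetic_parameter_names()],
    diff_f = stats::setNames(v[paste0("k_diff_f_", sp)], sp),
    diff_b = stats::setNames(v[paste0("k_diff_b_", sp)], sp),
    kdist_f = unname(v["k_dist_f"]), kdist_b = unname(v["k_dist_b"]),
    geometry = as.list(v[c("n0", "g_n", "v0", "g_v", "v_med")]))
}

#' @rdname parameter_table
#' @export
load_parameters <- read_parameters
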