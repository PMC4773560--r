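#' Species of the steroidogenesis model
#'
#' The model state holds 7 cholesterol/oxysterol pools plus 14 steroids,
#' each steroid in two compartments (intracellular and culture medium):
#' 35 state variables in all. Concentrations are in nmol/L, time in hours.
#'
#' @return `steroid_species()` returns the 14 steroid abbreviations in
#'   pathway order; `cholesterol_pools()` the 7 cholesterol/oxysterol pool
#'   names; `lcms_steroids()` the 12 steroids quantified by LC-MS/MS
#'   (all steroids except the estrogens E1 and E2); `state_names()` the
#'   full 35-element state vector naming, with `_cell` / `_med` suffixes
#'   for the two steroid compartments.
#' @examples
#' steroid_species()
#' length(state_names())
#' @export
steroid_species <- function() {
  c("PREG", "HPREG", "DHEA", "PROG", "HPROG", "DIONE", "TESTO",
    "DCORTICO", "DCORT", "CORTICO", "CORT", "ALDO", "E1", "E2")
}

#' @rdname steroid_species
#' @export
cholesterol_pools <- function() {
  c("CHOL", "CHOS", "CHOC", "CHOM", "CHOR", "CHON", "OXY")
}

#' @rdname steroid_species
#' @export
lcms_steroids <- function() {
  setdiff(steroid_species(), c("E1", "E2"))
}

#' @rdname steroid_species
#' @export
state_names <- function() {
  c(cholesterol_pools(),
    paste0(steroid_species(), "_cell"),
    paste0(steroid_species(), "_med"))
}

#' The nine steroidogenic enzymes
#'
#' `enzyme_names()` lists all nine enzymes of the pathway. `moa_enzymes()`
#' lists the eight whose relative activities are estimated in
#' mechanism-of-action inference; CYP19A1 (aromatase) is held fixed at 1
#' because its products E1/E2 are not part of the 12-steroid LC-MS panel.
#'
#' @return character vector of enzyme identifiers.
#' @export
enzyme_names <- function() {
  c("CYP11A1", "CYP17H", "CYP17L", "HSD3B2", "CYP21A2", "CYP11B1",
    "CYP11B2", "HSD17B3", "CYP19A1")
}

#' @rdname enzyme_names
#' @export
moa_enzymes <- function() setdiff(enzyme_names(), "CYP19A1")

#' Reaction table of the C21-steroid biosynthesis pathway
#'
#' The 17 enzymatic reactions catalyzed by the nine steroidogenic enzymes.
#' Multi-substrate enzymes act through a single shared site: substrates
#' compete, and the substrate letter (A/B/C) fixes the pairing between a
#' substrate and its Km/Vmax parameters. All stoichiometry is 1:1. All
#' reactions except CYP11B2 (first-order) follow competing-substrate
#' rapid-equilibrium kinetics.
#'
#' @return data.frame with columns `enzyme`, `substrate`, `product`,
#'   `law` (`"competing"` or `"first_order"`), and `letter`.
#' @examples
#' rt <- reaction_table()
#' nrow(rt)           # 17 reactions
#' length(unique(rt$enzyme))  # 9 enzymes
#' @export
reaction_table <- function() {
  data.frame(
    enzyme = c("CYP11A1",
               "CYP17H", "CYP17H",
               "CYP17L", "CYP17L",
               "HSD3B2", "HSD3B2", "HSD3B2",
               "CYP21A2", "CYP21A2",
               "CYP11B1", "CYP11B1",
               "CYP11B2",
               "HSD17B3", "HSD17B3",
               "CYP19A1", "CYP19A1"),
    substrate = c("CHON",
                  "PREG", "PROG",
                  "HPREG", "HPROG",
                  "PREG", "HPREG", "DHEA",
                  "PROG", "HPROG",
                  "DCORTICO", "DCORT",
                  "CORTICO",
                  "DIONE", "E1",
                  "DIONE", "TESTO"),
    product = c("PREG",
                "HPREG", "HPROG",
                "DHEA", "DIONE",
                "PROG", "HPROG", "DIONE",
                "DCORTICO", "DCORT",
                "CORTICO", "CORT",
                "ALDO",
                "TESTO", "E2",
                "E1", "E2"),
    law = c("competing",
            rep("competing", 11),
            "first_order",
            rep("competing", 4)),
    letter = c("A",
               "A", "B",
               "A", "B",
               "A", "B", "C",
               "A", "B",
               "A", "B",
               "A",
               "A", "B",
               "A", "B"),
    stringsAsFactors = FALSE
  )
}
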