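with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Seeded toy mitochondrion model
#'
#' A deterministic 18-reaction, 10-metabolite stand-in for a mitochondrial
#' FBA model, used throughout the package's tests and examples.  It
#' contains: eight exchange reactions (glucose, oxygen, two amino-acid-like
#' carbon sources, 3-hydroxybutyrate, lactate, CO2, and NADH), a lumped
#' glycolysis and a lumped TCA reaction producing NADH, substrate
#' degradation routes, a lactate dehydrogenase overflow, a lumped electron
#' transport chain consuming NADH and O2 and producing ATP (P/O 2.5), two
#' biomass component reactions, and an ATP drain (`DM_atp`, the ATP
#' production objective).
#'
#' The uptake capacities are sized so that maximal ATP production is
#' oxygen-limited: NADH supply at full uptake (115 units before seed
#' jitter) exceeds the electron-transport capacity (2 x 50 = 100), so
#' closing the O2 exchange strictly lowers maximal ATP and the O2 uptake
#' bound dominates an elementary-effects screening.  The slack between
#' supply and respiratory capacity (15 units) is smaller than the NADH
#' export ceiling (30), which creates a genuine ATP-versus-NADH-export
#' trade-off for multi-objective runs.  The seed jitters every uptake
#' capacity by +-5 percent; the same seed yields a bitwise identical model.
#'
#' @param seed integer seed.
#' @param include_nadh_exchange include the NADH exchange reaction
#'   (`EX_nadh`); set `FALSE` to add it later with
#'   [add_exchange_reaction()].
#' @return A `metabolic_model` with named sets `biomass`, `inputs` and
#'   `atp_demand`.
#' @export
toy_mitochondrion <- function(seed = 42L, include_nadh_exchange = TRUE) {
  jit <- with_seed(seed, stats::runif(6, 0.95, 1.05))
  caps <- c(glc = 5, o2 = 50, aa1 = 5, aa2 = 5, bhb = 5, nadh = 5) * jit
  mets <- c("GLC", "O2", "AA1", "AA2", "BHB", "LAC", "CO2", "PYR",
            "NADH", "ATP")
  comp <- c(rep("matrix", 1), "intermembrane", rep("matrix", 8))
  rxn <- list(
    # id, named coefficient vector, lb, ub
    list("EX_glc",  c(GLC = -1),  -caps[["glc"]], 0),
    list("EX_o2",   c(O2 = -1),   -caps[["o2"]],  0),
    list("EX_aa1",  c(AA1 = -1),  -caps[["aa1"]], 0),
    list("EX_aa2",  c(AA2 = -1),  -caps[["aa2"]], 0),
    list("EX_bhb",  c(BHB = -1),  -caps[["bhb"]], 0),
    list("EX_lac",  c(LAC = -1),  0, 50),
    list("EX_co2",  c(CO2 = -1),  0, 1000),
    list("GLYC",    c(GLC = -1, PYR = 2, NADH = 2, ATP = 2), 0, 1000),
    list("TCA",     c(PYR = -1, NADH = 3, CO2 = 3), 0, 1000),
    list("AA1_DEG", c(AA1 = -1, PYR = 1, NADH = 2), 0, 1000),
    list("AA2_DEG", c(AA2 = -1, PYR = 1, NADH = 1, CO2 = 1), 0, 1000),
    list("BHB_DEG", c(BHB = -1, NADH = 5, CO2 = 4), 0, 1000),
    list("LDH",     c(PYR = -1, NADH = -1, LAC = 1), -1000, 1000),
    list("ETC",     c(NADH = -1, O2 = -0.5, ATP = 2.5), 0, 1000),
    list("BM_protein", c(AA1 = -1, AA2 = -1, ATP = -4), 0, 1000),
    list("BM_lipid",   c(PYR = -3, NADH = -1, ATP = -6), 0, 1000),
    list("DM_atp",  c(ATP = -1), 0, 1000))
  if (include_nadh_exchange)
    rxn <- append(rxn, list(list("EX_nadh", c(NADH = -1),
                                 -caps[["nadh"]], 30)), after = 7)
  ids <- vapply(rxn, `[[`, character(1), 1)
  S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  for (j in seq_along(rxn)) S[names(rxn[[j]][[2]]), j] <- rxn[[j]][[2]]
  lb <- vapply(rxn, `[[`, numeric(1), 3)
  ub <- vapply(rxn, `[[`, numeric(1), 4)
  exch <- grepl("^EX_", ids)
  metabolic_model(
    S, lb, ub, reversible = lb < 0, compartment = comp,
    is_exchange = exch,
    named_sets = list(biomass = c("BM_protein", "BM_lipid", "DM_atp"),
                      inputs = ids[exch],
                      atp_demand = "DM_atp"))
}
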