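#' Published integrated-density tables for the 6UG0 nitrogenase structure
#'
#' Per-atom integrated densities (electrons within a 1.05-angstrom sphere)
#' reported for the ten sulfur sites of each FeMo cluster in PDB entry
#' 6UG0: the 2mFo-DFc map and the 7100 eV anomalous map, for the cluster
#' in chain A (putative N2 at the 2B site) and the cluster in chain C
#' (putative N2 at 3A and 5A).  These are the raw `rho` columns only; the
#' sigma-unit columns and Av/SD footers are derived quantities that
#' [build_integration_report()] reproduces.
#'
#' @return tibble with columns `atom`, `chain`, `map` (`"2fofc"` or
#'   `"anomalous"`), `rho`.
#' @export
nitrogenase_rho_tables <- function() {
  atoms <- c("Cys", "S2B", "S3A", "S5A", "S1A", "S2A", "S4A", "S1B",
    "S3B", "S4B")
  bind_rows(
    tibble(atom = atoms, chain = "A", map = "2fofc",
      rho = c(19.2, 21.6, 21.7, 20.4, 17.8, 20.9, 25.3, 22.3, 22.4, 23.6)),
    tibble(atom = atoms, chain = "C", map = "2fofc",
      rho = c(21.7, 23.6, 25.4, 25.2, 29.0, 27.1, 27.2, 30.5, 26.6, 24.3)),
    tibble(atom = atoms, chain = "A", map = "anomalous",
      rho = c(12.0, 6.0, 9.0, 8.4, 8.4, 11.2, 9.4, 7.3, 8.1, 10.0)),
    tibble(atom = atoms, chain = "C", map = "anomalous",
      rho = c(14.0, 11.9, 8.6, 8.8, 9.7, 13.0, 11.5, 9.7, 8.2, 8.8))
  )
}

#' Published per-region RSZD scores for the 6UG0 quantum refinements
#'
#' Real-space difference-density Z scores per region reported for the
#' competing ligand interpretations of the 6UG0 FeMo clusters: chain A
#' (2B site, regions Arg96/Cys275/Arg359/His442/HCA601/FeMo/2B) and
#' chain C (3A and 5A sites, regions Arg96/Cys275/Arg359/His442/HCA/
#' FeMo/3A/5A).  Row sums and model orderings are the quantities this
#' package's [aggregate_report()] and [rank_models()] operate on.
#'
#' @return tibble with columns `chain`, `model`, `group`, `rszd`.
#' @export
nitrogenase_rszd_tables <- function() {
  a_groups <- c("Arg96", "Cys275", "Arg359", "His442", "HCA601", "FeMo",
    "2B")
  c_groups <- c("Arg96", "Cys275", "Arg359", "His442", "HCA", "FeMo",
    "3A", "5A")
  arow <- function(model, v) {
    tibble(chain = "A", model = model, group = a_groups, rszd = v)
  }
  crow <- function(model, v) {
    tibble(chain = "C", model = model, group = c_groups, rszd = v)
  }
  bind_rows(
    arow("S2- q=-3", c(0.2, 0.3, 0.7, 1.0, 6.6, 10.9, 2.1)),
    arow("N2 q=-1", c(0.2, 0.4, 0.6, 1.0, 6.9, 11.2, 2.7)),
    arow("N2 q=-3", c(0.2, 0.3, 0.6, 1.1, 6.6, 11.4, 3.5)),
    crow("S2-/S2- q=-3", c(0.3, 0.1, 1.5, 0.7, 1.6, 7.7, 3.0, 1.4)),
    crow("S2-/N2 q=-1", c(0.3, 0.1, 1.3, 0.6, 1.7, 8.5, 2.9, 3.3)),
    crow("S2-/N2 q=-3", c(0.4, 0.1, 1.4, 0.7, 1.6, 7.2, 3.1, 3.7)),
    crow("S2-/NNH2 q=-1", c(0.3, 0.1, 1.3, 0.7, 1.7, 8.9, 2.8, 5.7)),
    crow("N2/S2- q=-1", c(0.4, 0.1, 1.6, 0.5, 1.8, 8.6, 6.3, 1.2)),
    crow("N2/S2- q=-3", c(0.3, 0.1, 1.4, 0.5, 1.8, 8.6, 5.1, 1.3)),
    crow("NNH2/S2- q=-1", c(0.3, 0.1, 1.6, 0.5, 1.8, 8.4, 6.7, 1.1)),
    crow("N2/N2 q=+1", c(0.5, 0.1, 1.6, 0.7, 1.8, 9.3, 6.1, 3.2))
  )
}
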