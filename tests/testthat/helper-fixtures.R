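# Fixtures built in code at test time.

toy_model_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "# two-metabolite example network",
    "R1\tglc_e => A\t0",
    "R2\tglc_e => B\t0",
    "R3\tA <=> B\t1",
    "R4\tA => waste_e\t0",
    "R5\tB => waste_e\t0"
  ), path)
  path
}

toy_thermo_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "metabolite_id\tdfG0_kJ_per_mol\tc_min_M\tc_max_M",
    "A\t-10\t1e-7\t1",
    "B\t-10\t1e-7\t1",
    "[exempt]",
    "R1", "R2", "R4", "R5"
  ), path)
  path
}

# minimal SBML document mirroring the toy network
toy_sbml <- function(path = tempfile(fileext = ".xml")) {
  ref <- function(sp, st = NULL) {
    sprintf('<speciesReference species="%s"%s/>', sp,
            if (is.null(st)) "" else sprintf(' stoichiometry="%s"', st))
  }
  rxn <- function(id, rev, reac, prod) {
    paste0('<reaction id="', id, '" reversible="', rev, '">',
           '<listOfReactants>', paste(reac, collapse = ""), '</listOfReactants>',
           '<listOfProducts>', paste(prod, collapse = ""), '</listOfProducts>',
           '</reaction>')
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="toy"><listOfSpecies>',
    '<species id="A" boundaryCondition="false"/>',
    '<species id="B" boundaryCondition="false"/>',
    '<species id="glc_x" boundaryCondition="true"/>',
    '<species id="waste_x" boundaryCondition="true"/>',
    '</listOfSpecies><listOfReactions>',
    rxn("R1", "false", ref("glc_x"), ref("A")),
    rxn("R2", "false", ref("glc_x"), ref("B")),
    rxn("R3", "true", ref("A"), ref("B")),
    rxn("R4", "false", ref("A"), ref("waste_x")),
    rxn("R5", "false", ref("B"), ref("waste_x")),
    '</listOfReactions></model></sbml>')
  writeLines(doc, path)
  path
}

# chain network 0 -> A -> 0 (two irreversible reactions)
chain_network <- function() {
  metabolic_network(matrix(c(1, -1), 1L, 2L,
                           dimnames = list("A", c("Rin", "Rout"))),
                    reversible = c(FALSE, FALSE))
}

# single irreversible conversion A -> B with exempt boundary reactions;
# gap = dfG0[B] - dfG0[A] controls feasibility of the conversion
gap_fixture <- function(gap) {
  S <- matrix(c(1, 0, -1, 1, 0, -1), nrow = 2L,
              dimnames = list(c("A", "B"), c("Rin", "Rconv", "Rout")))
  net <- metabolic_network(S, reversible = rep(FALSE, 3L))
  th <- thermo_data(net, dfG0 = c(A = 0, B = gap),
                    exempt_reactions = c("Rin", "Rout"))
  list(network = net, thermo = th)
}
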