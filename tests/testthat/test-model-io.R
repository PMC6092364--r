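test_that("constructor enforces shapes and unique ids", {
  expect_error(metabolic_model("X1", c("R1", "R2"), matrix(1, 1, 1),
                               c(FALSE, FALSE), c(0, 0), c(1, 1)),
               "S must be")
  expect_error(metabolic_model(c("X1", "X1"), "R1", matrix(c(1, -1), 2, 1),
                               FALSE, 0, 1), "duplicate metabolite")
  expect_error(metabolic_model("X1", c("R1", "R1"), matrix(c(1, 1), 1, 2),
                               c(FALSE, FALSE), c(0, 0), c(1, 1)),
               "duplicate reaction")
  m <- chain_model()
  expect_s3_class(m, "metabolic_model")
  expect_identical(n_metabolites(m), 1L)
  expect_identical(n_reactions(m), 2L)
})

test_that("validate_model flags structural oddities without erroring", {
  expect_identical(nrow(validate_model(chain_model())), 0L)

  m <- chain_model()
  m$lb[2] <- 5; m$ub[2] <- 3
  f <- validate_model(m)
  expect_true("bound_inversion" %in% f$type)
  expect_identical(f$id[f$type == "bound_inversion"], "R2")

  orphan <- metabolic_model(c("X1", "X2"), c("R1", "R2"),
                            matrix(c(1, 0, -1, 0), 2, 2),
                            c(FALSE, FALSE), c(0, 0), c(10, 10))
  f <- validate_model(orphan)
  expect_true(any(f$type == "unused_metabolite" & f$id == "X2"))

  onesided <- metabolic_model("X1", c("R1", "R2"),
                              matrix(c(1, 1), 1, 2),
                              c(FALSE, FALSE), c(0, 0), c(10, 10))
  expect_true("never_consumed" %in% validate_model(onesided)$type)
})

test_that("tsv triplet write/load round trip is exact", {
  for (seed in 1:5) {
    m <- random_model(6, 9, density = 0.35, fraction_reversible = 0.4,
                      seed = seed)
    prefix <- file.path(withr::local_tempdir(), "m")
    write_model(m, prefix)
    m2 <- load_model(prefix, "tsv_triplet")
    expect_identical(m2$S, m$S)
    expect_identical(m2$reversible, m$reversible)
    expect_identical(m2$lb, m$lb)
    expect_identical(m2$ub, m$ub)
    expect_identical(m2$objective, m$objective)
  }
})

test_that("malformed or missing files raise format errors", {
  expect_error(load_model(file.path(tempdir(), "nope"), "tsv_triplet"),
               "not found")
  bad <- file.path(withr::local_tempdir(), "bad")
  writeLines("metabolite\treaction", paste0(bad, "_stoich.tsv"))
  writeLines("reaction\treversible\tlb\tub", paste0(bad, "_reactions.tsv"))
  expect_error(load_model(bad, "tsv_triplet"), "malformed")
  j <- file.path(withr::local_tempdir(), "trunc.json")
  writeLines('{"metabolites": [', j)
  expect_error(load_model(j), "parse")
})

test_that("BiGG JSON models load with bounds, objective and subsystems", {
  doc <- list(
    metabolites = list(list(id = "a_c", compartment = "c"),
                       list(id = "b_c", compartment = "c"),
                       list(id = "x_b", compartment = "b")),
    reactions = list(
      list(id = "R1", metabolites = list(a_c = 1, x_b = -1),
           lower_bound = 0, upper_bound = 10, objective_coefficient = 0,
           subsystem = "Uptake"),
      list(id = "R2", metabolites = list(a_c = -1, b_c = 1),
           lower_bound = -1000, upper_bound = 1000,
           objective_coefficient = 0, subsystem = "Core"),
      list(id = "R3", metabolites = list(b_c = -1),
           lower_bound = 0, upper_bound = 1000, objective_coefficient = 1,
           subsystem = "Biomass")))
  path <- file.path(withr::local_tempdir(), "mini.json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  m <- load_model(path)
  # boundary metabolite x_b must be dropped from the rows
  expect_identical(m$metabolite_ids, c("a_c", "b_c"))
  expect_identical(m$reversible, c(FALSE, TRUE, FALSE))
  expect_identical(m$objective, c(0, 0, 1))
  expect_identical(unname(m$subsystem["R2"]), "Core")
  expect_identical(m$S["a_c", "R2"], -1)
})

test_that("SBML L3/fbc models load bounds via parameters and objectives", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2">
 <model id="mini">
  <listOfParameters>
   <parameter id="lb0" value="0" constant="true"/>
   <parameter id="lbneg" value="-1000" constant="true"/>
   <parameter id="ub" value="1000" constant="true"/>
  </listOfParameters>
  <listOfSpecies>
   <species id="M_a_c" compartment="c" boundaryCondition="false"/>
   <species id="M_b_c" compartment="c" boundaryCondition="false"/>
   <species id="M_x_b" compartment="e" boundaryCondition="true"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="R_R1" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub">
    <listOfReactants><speciesReference species="M_x_b" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="M_a_c" stoichiometry="1"/></listOfProducts>
   </reaction>
   <reaction id="R_R2" reversible="true" fbc:lowerFluxBound="lbneg" fbc:upperFluxBound="ub">
    <listOfReactants><speciesReference species="M_a_c" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="M_b_c" stoichiometry="2"/></listOfProducts>
   </reaction>
   <reaction id="R_R3" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub">
    <listOfReactants><speciesReference species="M_b_c" stoichiometry="1"/></listOfReactants>
   </reaction>
  </listOfReactions>
  <fbc:listOfObjectives fbc:activeObjective="obj">
   <fbc:objective fbc:id="obj" fbc:type="maximize">
    <fbc:listOfFluxObjectives>
     <fbc:fluxObjective fbc:reaction="R_R3" fbc:coefficient="1"/>
    </fbc:listOfFluxObjectives>
   </fbc:objective>
  </fbc:listOfObjectives>
 </model>
</sbml>'
  path <- file.path(withr::local_tempdir(), "mini.xml")
  writeLines(sbml, path)
  m <- load_model(path)
  expect_identical(m$metabolite_ids, c("a_c", "b_c"))  # boundary species dropped
  expect_identical(m$reaction_ids, c("R1", "R2", "R3"))
  expect_identical(m$reversible, c(FALSE, TRUE, FALSE))
  expect_identical(m$lb, c(0, -1000, 0))
  expect_identical(m$S["b_c", "R2"], 2)
  expect_identical(m$objective, c(0, 0, 1))
})

test_that("bundled E. coli core model has the published dimensions", {
  m <- load_model(ecoli_core_path(), "tsv_triplet")
  expect_identical(n_metabolites(m), 72L)
  expect_identical(n_reactions(m), 95L)
  expect_identical(length(unique(m$subsystem)), 11L)
  expect_identical(sum(m$reversible), 59L)
  expect_identical(m$reaction_ids[m$objective != 0], "Biomass_Ecoli_core")
})

test_that("reversibility conflicts resolve in favour of bounds with a warning", {
  prefix <- file.path(withr::local_tempdir(), "conf")
  writeLines(c("metabolite\treaction\tcoefficient", "X1\tR1\t1", "X1\tR2\t-1"),
             paste0(prefix, "_stoich.tsv"))
  writeLines(c("reaction\treversible\tlb\tub\tobjective",
               "R1\t0\t-5\t10\t0", "R2\t0\t0\t10\t1"),
             paste0(prefix, "_reactions.tsv"))
  expect_warning(m <- load_model(prefix, "tsv_triplet"), "reversible")
  expect_identical(m$reversible, c(TRUE, FALSE))
})
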