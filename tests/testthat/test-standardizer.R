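# Structure standardization and parent extraction.

test_that("already-standard structures are fixed points", {
  s <- standardize_structure("c1ccccc1")
  expect_identical(s$status, "standardized")
  expect_identical(s$canonical_smiles, "c1ccccc1")
  expect_identical(s$inchi, "InChI=1S/C6H6/c1-2-4-6-5-3-1/h1-6H")
  again <- standardize_structure(s$canonical_smiles)
  expect_identical(again$inchi, s$inchi)
  expect_identical(again$canonical_smiles, s$canonical_smiles)
})

test_that("salt and solvent stripping recovers the organic parent", {
  # sodium acetate -> acetic acid (reference-pipeline behaviour)
  s <- standardize_structure("CC(=O)[O-].[Na+]")
  expect_identical(s$canonical_smiles, "CC(=O)O")
  expect_false(s$is_mixture)
  # ethanol solvate of phenol -> phenol
  s2 <- standardize_structure("CCO.c1ccccc1O")
  expect_identical(s2$inchi, standardize_structure("Oc1ccccc1")$inchi)
  # duplicate fragments collapse
  s3 <- standardize_structure("CC(=O)O.CC(=O)O")
  expect_identical(s3$canonical_smiles, "CC(=O)O")
  # stripping never empties the molecule: bare salt survives
  s4 <- standardize_structure("[Na+].[Cl-]")
  expect_identical(s4$status, "standardized")
  expect_true(grepl("Na", s4$canonical_smiles))
})

test_that("wildcards, garbage and isotopes are handled per the rules", {
  w <- standardize_structure("*CC")
  expect_identical(w$status, "rejected")
  expect_identical(w$reason, "wildcard")
  g <- standardize_structure("not_a_smiles_Q")
  expect_identical(g$status, "rejected")
  expect_identical(g$reason, "unparseable")
  e <- standardize_structure("")
  expect_identical(e$reason, "unparseable")
  # deuterated methanol loses its isotope label
  d <- standardize_structure("[2H]OC")
  expect_identical(d$inchi, "InChI=1S/CH4O/c1-2/h2H,1H3")
  c13 <- standardize_structure("[13CH4]")
  expect_identical(c13$inchi, "InChI=1S/CH4/h1H4")
})

test_that("stereochemistry and tautomers are preserved, resonance is not", {
  cis <- standardize_structure("C/C=C\\C")
  trans <- standardize_structure("C/C=C/C")
  expect_false(identical(cis$inchi, trans$inchi))
  # same molecule written with different atom orders -> identical InChI
  a <- standardize_structure("c1ccccc1CCN")
  b <- standardize_structure("NCCc1ccccc1")
  expect_identical(a$inchi, b$inchi)
  # tautomer spellings stay distinct (no tautomer canonicalization)
  keto <- standardize_structure("CC(=O)CC(C)=O")
  enol <- standardize_structure("CC(O)=CC(C)=O")
  expect_false(identical(keto$inchi, enol$inchi))
})

test_that("charge-separated groups survive neutralization", {
  nb <- standardize_structure("c1ccccc1[N+](=O)[O-]")
  expect_identical(nb$status, "standardized")
  expect_true(grepl("\\[N\\+\\]", nb$canonical_smiles))
  quat <- standardize_structure("C[N+](C)(C)C.[Cl-]")
  expect_true(grepl("\\[N\\+\\]", quat$canonical_smiles))
  expect_false(grepl("Cl", quat$canonical_smiles))
})

test_that("true mixtures are retained and flagged", {
  m <- standardize_structure("c1ccccc1.CCCCCCCC")
  expect_identical(m$status, "standardized")
  expect_true(m$is_mixture)
  expect_true(grepl(".", m$canonical_smiles, fixed = TRUE))
})

test_that("standardize_table conserves rows and is idempotent on parents", {
  smis <- fixture_smiles()
  set.seed(401)
  raw <- data.frame(
    smiles = c(unname(smis), "*CC", "garbage(((", "CC(=O)[O-].[Na+]"),
    dataset = "mix")
  std <- standardize_table(raw)
  expect_identical(nrow(std), nrow(raw))  # conservation
  expect_identical(sum(std$status == "standardized") +
                     sum(std$status == "rejected"), nrow(raw))
  expect_setequal(std$reject_reason[std$status == "rejected"],
                  c("wildcard", "unparseable"))
  ok <- std[std$status == "standardized", ]
  re <- standardize_table(data.frame(smiles = ok$canonical_smiles,
                                     dataset = "again"))
  expect_identical(re$inchi, ok$inchi)               # idempotence
  expect_identical(re$canonical_smiles, ok$canonical_smiles)
})

test_that("output InChI is invariant under atom-order permutation", {
  set.seed(402)
  for (smi in fixture_smiles()) {
    base <- standardize_structure(smi)
    for (rep in 1:3) {
      perm <- permute_smiles(base$canonical_smiles)
      expect_identical(standardize_structure(perm)$inchi, base$inchi,
                       info = smi)
    }
  }
})

test_that("parent + known counterion always recovers the parent InChI", {
  set.seed(403)
  counterions <- c("Cl", "[Na+]", "O[N+]([O-])=O", "OS(O)(=O)=O",
                   "CC(O)=O", "CS(O)(=O)=O")
  parents <- c("CCNc1nc(Cl)nc(NC(C)C)n1", "Nc1ccccc1", "OC(=O)c1ccccc1O",
               "CN1CCC(CC1)c1ccccc1", "Cn1cnc2c1c(=O)n(C)c(=O)n2C")
  for (p in parents) {
    want <- standardize_structure(p)$inchi
    for (ci in counterions) {
      got <- standardize_structure(paste0(p, ".", ci))$inchi
      expect_identical(got, want, info = paste(p, "+", ci))
    }
  }
})
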