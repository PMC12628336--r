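# Functional-group catalogue handling and enrichment statistics.

mini_catalogue <- function() {
  read_fg_catalogue(system.file("extdata", "fg_catalogue_mini.txt",
                                package = "chemcov"))
}

test_that("catalogue parsing accepts both shipped formats", {
  cat1 <- mini_catalogue()
  expect_true(all(c("name", "smarts") %in% names(cat1)))
  expect_gte(nrow(cat1), 10)
  # annotated 'Name: SMARTS' form (as in the Open Babel classification file)
  td <- withr::local_tempdir()
  f <- file.path(td, "cat.txt")
  writeLines(c("# comment", "Nitro: [NX3](=O)=O", "",
               "Halide: [F,Cl,Br,I]"), f)
  cat2 <- read_fg_catalogue(f)
  expect_identical(cat2$name, c("Nitro", "Halide"))
  expect_identical(cat2$smarts[2], "[F,Cl,Br,I]")
})

test_that("presence is binary, correct, and permutation-invariant", {
  catalogue <- mini_catalogue()
  sm <- ob_canonical(c(nb = "O=[N+]([O-])c1ccccc1",
                       dinitro = "O=[N+]([O-])c1ccc(cc1)[N+](=O)[O-]",
                       ethane = "CC",
                       phenol = "Oc1ccccc1"))
  names(sm) <- c("nb", "dinitro", "ethane", "phenol")
  m <- match_functional_groups(sm, catalogue)
  expect_type(m[1, 1], "logical")
  expect_true(m["nb", "nitro"])
  expect_true(m["dinitro", "nitro"])      # two groups still count once
  expect_false(any(m["ethane", ]))
  expect_true(m["phenol", "phenol"])
  expect_false(m["phenol", "nitro"])
  # atom-order permutation leaves the presence row unchanged
  set.seed(406)
  perm <- ob_canonical(permute_smiles(sm[["dinitro"]]))
  names(perm) <- "permuted"
  expect_identical(unname(match_functional_groups(perm, catalogue)[1, ]),
                   unname(m["dinitro", ]))
  # a non-compiling pattern is an error naming the pattern
  bad <- rbind(catalogue, data.frame(name = "broken", smarts = "[[[Q"))
  expect_error(match_functional_groups(sm, bad), "broken")
})

test_that("pattern filtering keeps exactly the observed groups", {
  lib <- fixture_lib()
  catalogue <- mini_catalogue()
  gt <- lib$ground_truth
  sm <- stats::setNames(lib$molecules$canonical_smiles, lib$molecules$inchi)
  pq <- match_functional_groups(sm[gt$query_universe], catalogue)
  pr <- match_functional_groups(sm[gt$reference_universe], catalogue)
  ret <- filter_patterns(list(pq, pr))
  # the generator vocabulary is present, the decoys are dropped
  planted <- colnames(gt$fg_query)[colSums(gt$fg_query) +
                                     colSums(gt$fg_reference) > 0]
  expect_setequal(ret$retained, planted)
  expect_true(all(c("sulfonamide", "aldehyde", "nitrile") %in% ret$dropped))
  # retention is monotone: adding molecules never un-retains
  ret_small <- filter_patterns(list(pq[1:10, , drop = FALSE]))
  expect_true(all(ret_small$retained %in%
                    filter_patterns(list(pq))$retained))
  # matching recovers the generator's planted presence matrix exactly
  expect_identical(pq[, colnames(gt$fg_query)],
                   gt$fg_query[rownames(pq), ])
})

test_that("proportion differences are exact and antisymmetric", {
  pq <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                 TRUE, FALSE, FALSE, FALSE), ncol = 2,
               dimnames = list(paste0("q", 1:4), c("g1", "g2")))
  pr <- matrix(c(TRUE, FALSE, FALSE, FALSE, FALSE,
                 TRUE, TRUE, TRUE, TRUE, TRUE), ncol = 2,
               dimnames = list(paste0("r", 1:5), c("g1", "g2")))
  rows <- proportion_difference(pq, pr)
  expect_equal(rows$difference[rows$group == "g1"], 0.5 - 0.2)
  expect_equal(rows$difference[rows$group == "g2"], 0.25 - 1)
  rev <- proportion_difference(pr, pq)
  expect_equal(rev$difference, -rows$difference)
  expect_equal(proportion_difference(pq, pq)$difference, c(0, 0))
  expect_error(proportion_difference(pq[0, , drop = FALSE], pr), "empty")
})

test_that("top-k ranking is deterministic with lexicographic ties", {
  rows <- data.frame(group = c("b", "a", "c"),
                     p_query = 0, p_reference = 0,
                     difference = c(0.2, 0.2, -0.1))
  expect_message(tk <- top_k_enrichment(rows, k = 10), "3 groups")
  expect_identical(nrow(tk$most_positive), 3L)
  expect_identical(tk$most_positive$group[1:2], c("a", "b"))  # tie rule
  expect_identical(tk$most_negative$group[1], "c")
  same <- data.frame(group = c("z", "y", "x"), p_query = 0,
                     p_reference = 0, difference = 0)
  tk2 <- top_k_enrichment(same, k = 2)
  expect_identical(tk2$most_positive$group, c("x", "y"))
})

test_that("planted frequency differences are recovered within binomial noise", {
  lib <- fixture_lib()
  gt <- lib$ground_truth
  rows <- proportion_difference(gt$fg_query, gt$fg_reference)
  # realized frequencies vs planted config probabilities: 3 binomial SDs
  cfg_q <- lib$config$fg_frequencies$query
  cfg_r <- lib$config$fg_frequencies$reference
  nq <- nrow(gt$fg_query); nr <- nrow(gt$fg_reference)
  for (g in names(cfg_q)) {
    # site competition can only suppress planted groups, never inflate them
    tol_q <- 3 * sqrt(cfg_q[[g]] * (1 - cfg_q[[g]]) / nq)
    expect_lt(rows$p_query[rows$group == g] - cfg_q[[g]], tol_q)
  }
  # the strongest planted contrast (halogen: query-enriched) is recovered
  tk <- top_k_enrichment(rows, k = 1)
  expect_identical(tk$most_positive$group, "halogen")
})
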