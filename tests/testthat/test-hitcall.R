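# Conservative hit-call aggregation and endpoint-set construction.

test_that("the conservative truth table holds", {
  expect_identical(aggregate_calls(c("positive", "negative", "negative")),
                   "positive")
  expect_identical(aggregate_calls(c("negative", "negative")), "negative")
  expect_identical(aggregate_calls("positive"), "positive")
  expect_identical(aggregate_calls(character(0)), NA_character_)
})

test_that("aggregation is monotone under added evidence", {
  set.seed(405)
  for (rep in 1:50) {
    calls <- sample(c("positive", "negative"), sample(1:6, 1), replace = TRUE)
    base <- aggregate_calls(calls)
    # adding a positive never flips positive -> negative
    expect_identical(aggregate_calls(c(calls, "positive")), "positive")
    # adding a negative never flips the call away from positive
    with_neg <- aggregate_calls(c(calls, "negative"))
    if (base == "positive") expect_identical(with_neg, "positive")
    if (base == "negative") expect_identical(with_neg, "negative")
  }
})

test_that("alias mapping, equivocal dropping and error provenance work", {
  df <- data.frame(
    inchi = paste0("I", 1:5),
    test_type = c("Ames", "in vitro MN", "in vivo CA", "AMES", "in vitro MCGM"),
    call = c("Positive", "negative", "equivocal", "NEGATIVE", "positive"),
    dataset = "src")
  expect_message(res <- load_assay_results(df), "dropped 1")
  expect_identical(nrow(res), 4L)
  expect_setequal(res$test_type, c("ames", "invitro_mn", "invitro_mcgm"))
  bad <- df; bad$test_type[2] <- "comet"
  expect_error(load_assay_results(bad), "comet")
})

test_that("endpoint sets partition by test type with a pooled union", {
  df <- data.frame(
    inchi = c("A", "A", "A", "B", "C"),
    test_type = c("ames", "ames", "invitro_mn", "ames", "invivo_ca"),
    call = c("positive", "negative", "negative", "negative", "positive"),
    dataset = "s")
  eps <- build_endpoint_sets(load_assay_results(df))
  expect_identical(sort(names(eps)), sort(c(test_types(), "all")))
  # substance with only Ames data is in ames + all only
  expect_true("B" %in% eps$ames$members)
  expect_false("B" %in% eps$invitro_mn$members)
  expect_true("B" %in% eps$all$members)
  # per-test aggregation then pooled positive-anywhere rule
  expect_identical(unname(eps$ames$calls["A"]), "positive")
  expect_identical(unname(eps$invitro_mn$calls["A"]), "negative")
  expect_identical(unname(eps$all$calls["A"]), "positive")
  # union property
  expect_setequal(eps$all$members,
                  unique(unlist(lapply(eps[test_types()], `[[`, "members"))))
  for (tt in test_types()) {
    expect_true(all(eps[[tt]]$members %in% eps$all$members))
  }
  expect_identical(endpoint_readouts(eps$ames),
                   c(positive = 1L, negative = 1L))
})

test_that("generated endpoint sizes and calls are recovered exactly", {
  lib <- fixture_lib()
  eps <- build_endpoint_sets(load_assay_results(lib$assays))
  gt <- lib$ground_truth
  for (tt in names(gt$endpoint_sizes)) {
    expect_identical(length(eps[[tt]]$members),
                     unname(gt$endpoint_sizes[[tt]]), info = tt)
    expect_identical(eps[[tt]]$calls[names(gt$endpoint_calls[[tt]])],
                     gt$endpoint_calls[[tt]], info = tt)
  }
})

test_that("positive-call frequency matches the binomial expectation", {
  # with k i.i.d. results at per-result rate p, P(call positive) = 1-(1-p)^k;
  # check the realized frequency across a larger generated assay table
  cfg <- synth_config(n_query_sets = 1L, n_reference_sets = 2L,
                      query_set_size = 5L, reference_set_size = 220L,
                      overlap_fraction = 0, positive_rate = 0.3, seed = 31L)
  lib <- generate_library(cfg)
  res <- load_assay_results(lib$assays)
  ag <- tapply(res$call, list(res$inchi, res$test_type),
               function(x) aggregate_calls(x))
  k_tab <- table(res$inchi, res$test_type)
  p <- 0.3
  # expected positive probability per substance-test given its k
  ks <- as.vector(k_tab[k_tab > 0])
  calls <- as.vector(ag[!is.na(ag)])
  expected <- mean(1 - (1 - p)^ks)
  observed <- mean(calls == "positive")
  n <- length(calls)
  sd3 <- 3 * sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), sd3 + 0.02)
})
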