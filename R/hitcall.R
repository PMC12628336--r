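# Conservative hit-call aggregation: a substance is negative for a test type
# only when every available result is negative; one positive result anywhere
# makes it positive.

.TEST_TYPES <- c("ames", "invitro_mcgm", "invitro_mn", "invitro_ca",
                 "invivo_mn", "invivo_ca")

#' Canonical genotoxicity test-type vocabulary
#' @return character vector of the six canonical test-type labels.
#' @export
test_types <- function() .TEST_TYPES

#' Default test-type alias table
#'
#' Maps common source spellings ("Ames", "in vitro MN", ...) onto the
#' canonical labels.
#'
#' @return named character vector (alias -> canonical).
#' @export
default_test_aliases <- function() {
  c("ames" = "ames", "in vitro mcgm" = "invitro_mcgm",
    "in vitro mn" = "invitro_mn", "in vitro ca" = "invitro_ca",
    "in vivo mn" = "invivo_mn", "in vivo ca" = "invivo_ca",
    "invitro_mcgm" = "invitro_mcgm", "invitro_mn" = "invitro_mn",
    "invitro_ca" = "invitro_ca", "invivo_mn" = "invivo_mn",
    "invivo_ca" = "invivo_ca", "mcgm" = "invitro_mcgm")
}

#' Load and validate assay result records
#'
#' Normalizes test-type labels via the alias table and call labels to
#' positive/negative. Records whose call is neither (equivocal, inconclusive,
#' ...) are dropped with a logged count; unknown test types are an error with
#' row provenance.
#'
#' @param df data.frame with columns `inchi`, `test_type`, `call` and
#'   optionally `dataset`.
#' @param aliases named character vector mapping source labels to canonical
#'   test types.
#' @return validated data.frame `[inchi, test_type, call, dataset]`.
#' @export
load_assay_results <- function(df, aliases = default_test_aliases()) {
  stopifnot(all(c("inchi", "test_type", "call") %in% names(df)))
  if (is.null(df$dataset)) df$dataset <- "unknown"
  tt <- aliases[tolower(trimws(df$test_type))]
  if (anyNA(tt)) {
    bad <- which(is.na(tt))[1]
    stop("unknown test type '", df$test_type[bad], "' (row ", bad,
         ", dataset ", df$dataset[bad], ")")
  }
  call <- tolower(trimws(df$call))
  keep <- call %in% c("positive", "negative")
  if (any(!keep)) {
    message("dropped ", sum(!keep), " assay records with non-binary calls")
  }
  data.frame(inchi = df$inchi[keep], test_type = unname(tt[keep]),
             call = call[keep], dataset = df$dataset[keep],
             stringsAsFactors = FALSE)
}

#' Aggregate assay calls for one substance and test type
#'
#' Positive iff at least one result is positive; negative iff all results are
#' negative (unanimity rule). An empty result list yields `NA` (no call; the
#' substance is absent from that endpoint set).
#'
#' @param calls character vector of "positive"/"negative".
#' @return `"positive"`, `"negative"`, or `NA_character_`.
#' @export
aggregate_calls <- function(calls) {
  if (!length(calls)) return(NA_character_)
  if (any(calls == "positive")) "positive" else "negative"
}

#' Build the six endpoint sets plus the all-genotoxicity union
#'
#' Membership of an endpoint set is having at least one result of that test
#' type; the aggregated call applies the unanimity rule per test. The
#' all-genotoxicity set is the union of the six, with its call computed over
#' the pooled result list of every type (equivalent to "positive in any test").
#'
#' @param results validated data.frame from [load_assay_results()].
#' @return named list of endpoint sets; each is a list with `test_type`,
#'   `members` (sorted InChIs) and `calls` (named character vector).
#' @export
build_endpoint_sets <- function(results) {
  out <- list()
  for (tt in .TEST_TYPES) {
    sub <- results[results$test_type == tt, ]
    calls <- vapply(split(sub$call, sub$inchi), aggregate_calls, character(1))
    out[[tt]] <- list(test_type = tt, members = sort(names(calls)),
                      calls = calls)
  }
  calls_all <- vapply(split(results$call, results$inchi), aggregate_calls,
                      character(1))
  out[["all"]] <- list(test_type = "all", members = sort(names(calls_all)),
                       calls = calls_all)
  out
}

#' Positive/negative readout counts of an endpoint set
#'
#' @param endpoint one element of [build_endpoint_sets()].
#' @return named integer vector `c(positive=, negative=)`.
#' @export
endpoint_readouts <- function(endpoint) {
  c(positive = sum(endpoint$calls == "positive"),
    negative = sum(endpoint$calls == "negative"))
}
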