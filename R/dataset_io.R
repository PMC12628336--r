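# Loading named collections, merging them into a deduplicated substance
# universe keyed by InChI, and per-set accounting (counts, exclusivity).

#' Load one named dataset of raw SMILES entries
#'
#' Reads a CSV/TSV file (delimiter chosen by extension) and returns one raw
#' entry per row. `n_initial` accounting counts unique raw SMILES strings
#' (exact text match after whitespace trim).
#'
#' @param path file path.
#' @param name dataset name recorded as provenance.
#' @param category one of `"pesticide"`, `"genotoxicity"`, `"reference"`.
#' @param smiles_col name of the SMILES column (default `"smiles"`).
#' @return data.frame `[dataset, category, row_id, smiles]` with attribute
#'   `n_initial`.
#' @export
load_dataset <- function(path, name, category = c("pesticide",
                                                  "genotoxicity",
                                                  "reference"),
                         smiles_col = "smiles") {
  category <- match.arg(category)
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!smiles_col %in% names(df)) {
    stop("dataset '", name, "': missing SMILES column '", smiles_col, "'")
  }
  if (!nrow(df)) {
    warning("dataset '", name, "' is empty")
    out <- data.frame(dataset = character(0), category = character(0),
                      row_id = character(0), smiles = character(0))
    attr(out, "n_initial") <- 0L
    return(out)
  }
  smiles <- trimws(df[[smiles_col]])
  out <- data.frame(dataset = name, category = category,
                    row_id = paste0(name, ":", seq_along(smiles)),
                    smiles = smiles, stringsAsFactors = FALSE)
  attr(out, "n_initial") <- length(unique(smiles))
  out
}

#' Merge standardized sets into a substance universe
#'
#' One record per unique InChI; `sources` and `categories` are the unions of
#' the contributing datasets. Merging is order-independent: records are keyed
#' by InChI and sources are sorted.
#'
#' @param std data.frame from [standardize_table()], with an additional
#'   `category` column (carried through from [load_dataset()]).
#' @return data.frame `[inchi, canonical_smiles, sources, categories]` with
#'   `;`-joined provenance columns, ordered by InChI.
#' @export
merge_universe <- function(std) {
  ok <- std[std$status == "standardized" & !is.na(std$inchi), ]
  if (!nrow(ok)) {
    return(data.frame(inchi = character(0), canonical_smiles = character(0),
                      sources = character(0), categories = character(0)))
  }
  if (is.null(ok$category)) ok$category <- "pesticide"
  sp <- split(ok, ok$inchi)
  out <- data.frame(
    inchi = names(sp),
    canonical_smiles = vapply(sp, function(d) d$canonical_smiles[[1]],
                              character(1)),
    sources = vapply(sp, function(d)
      paste(sort(unique(d$dataset)), collapse = ";"), character(1)),
    categories = vapply(sp, function(d)
      paste(sort(unique(d$category)), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$inchi), , drop = FALSE]
}

#' Per-dataset substance sets from a standardized table
#'
#' @param std data.frame from [standardize_table()].
#' @return named list of character vectors of unique InChIs per dataset.
#' @export
substance_sets <- function(std) {
  ok <- std[std$status == "standardized" & !is.na(std$inchi), ]
  lapply(split(ok$inchi, ok$dataset), function(x) sort(unique(x)))
}

#' Exclusive substance counts
#'
#' A substance is exclusive to a set if it occurs in no other set of the
#' comparison universe. By default the comparison universe is the supplied
#' list itself (same-category comparison); pass additional sets via `across`
#' to widen it.
#'
#' @param sets named list of InChI vectors.
#' @param across optional further sets included in the comparison universe
#'   but not reported on.
#' @return named integer vector of exclusive counts, parallel to `sets`.
#' @export
exclusivity <- function(sets, across = list()) {
  all_sets <- c(sets, across)
  membership <- table(unlist(lapply(all_sets, unique)))
  vapply(sets, function(members) {
    sum(membership[unique(members)] == 1L)
  }, integer(1))
}
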