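# Coverage statistics between substance sets: exact InChI overlap,
# similarity-threshold overlap, intra-set diversity, scaffold statistics and
# missing-scaffold gap ranking.

#' Exact InChI overlap between two sets
#'
#' @param a,b character vectors of InChIs.
#' @return list with `count`, `members` (the intersection) and `fraction`
#'   (`count / |a|`). Symmetric in the count, directional in the fraction.
#' @export
exact_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  members <- intersect(a, b)
  list(count = length(members), members = members,
       fraction = if (length(a)) length(members) / length(a) else NA_real_)
}

#' Similarity-threshold overlap
#'
#' Counts members of `a` whose maximum Tanimoto similarity to any member of
#' `b` meets the threshold. Exact matches have similarity 1 and are always
#' included. Directional: `similarity_overlap(a, b, ...)` is in general not
#' equal to `similarity_overlap(b, a, ...)`.
#'
#' @param a,b character vectors of InChIs.
#' @param fingerprints logical fingerprint matrix with rownames covering all
#'   members of both sets.
#' @param threshold Tanimoto threshold (default 0.75).
#' @param comparator `">="` (default, "at least") or `">"`.
#' @param chunk internal row-block size for the similarity scan.
#' @return list with `count`, `members`, `fraction`.
#' @export
similarity_overlap <- function(a, b, fingerprints, threshold = 0.75,
                               comparator = c(">=", ">"), chunk = 512L) {
  comparator <- match.arg(comparator)
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) {
    return(list(count = 0L, members = character(0),
                fraction = if (length(a)) 0 else NA_real_))
  }
  missing <- setdiff(c(a, b), rownames(fingerprints))
  if (length(missing)) {
    stop("missing fingerprint for substance ", missing[[1]])
  }
  cmp <- match.fun(comparator)
  hits <- logical(length(a))
  B <- fingerprints[b, , drop = FALSE]
  for (start in seq(1L, length(a), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(a))
    sims <- tanimoto_matrix(fingerprints[a[idx], , drop = FALSE], B)
    hits[idx] <- apply(sims, 1, function(s) any(cmp(s, threshold)))
  }
  list(count = sum(hits), members = a[hits],
       fraction = if (length(a)) sum(hits) / length(a) else NA_real_)
}

#' Mean pairwise Tanimoto similarity within a set
#'
#' Arithmetic mean over all unordered distinct pairs (self-pairs excluded).
#'
#' @param ids character vector of InChIs (at least 2, else `NA`).
#' @param fingerprints logical fingerprint matrix with matching rownames.
#' @return numeric scalar in `[0, 1]`, or `NA` for sets smaller than 2.
#' @export
mean_pairwise_tanimoto <- function(ids, fingerprints) {
  ids <- unique(ids)
  n <- length(ids)
  if (n < 2L) return(NA_real_)
  sims <- tanimoto_matrix(fingerprints[ids, , drop = FALSE])
  mean(sims[upper.tri(sims)])
}

#' Scaffold statistics of a substance set
#'
#' Number of unique Murcko scaffolds, mean and SD of molecules per scaffold,
#' singleton count and singleton fraction. The empty (acyclic) scaffold
#' counts as one scaffold class by default.
#'
#' @param ids character vector of InChIs.
#' @param scaffolds named character vector mapping InChI -> scaffold SMILES
#'   (`""` for acyclic molecules).
#' @param include_acyclic count the acyclic class as a scaffold (default
#'   TRUE); when FALSE acyclic molecules are excluded from the statistics.
#' @return list `(n_scaffolds, mean_per_scaffold, sd_per_scaffold,
#'   n_singletons, singleton_fraction, n_molecules)`.
#' @export
scaffold_stats <- function(ids, scaffolds, include_acyclic = TRUE) {
  ids <- unique(ids)
  sc <- scaffolds[ids]
  if (anyNA(sc)) stop("missing scaffold for ", sum(is.na(sc)), " substances")
  if (!include_acyclic) sc <- sc[sc != ""]
  if (!length(sc)) {
    return(list(n_scaffolds = 0L, mean_per_scaffold = NA_real_,
                sd_per_scaffold = NA_real_, n_singletons = 0L,
                singleton_fraction = NA_real_, n_molecules = 0L))
  }
  counts <- table(sc)
  list(n_scaffolds = length(counts),
       mean_per_scaffold = length(sc) / length(counts),
       sd_per_scaffold = stats::sd(as.numeric(counts)),
       n_singletons = sum(counts == 1L),
       singleton_fraction = sum(counts == 1L) / length(counts),
       n_molecules = length(sc))
}

#' Scaffolds of a query set absent from every reference set
#'
#' Ranks the scaffold gaps by the number of query molecules bearing them,
#' descending (ties by scaffold SMILES for determinism). The empty acyclic
#' scaffold never constitutes a gap.
#'
#' @param query character vector of query-set InChIs.
#' @param references list of character vectors of reference-set InChIs.
#' @param scaffolds named character vector (InChI -> scaffold SMILES).
#' @return data.frame `[scaffold_smiles, count_in_query, pct_of_query]`,
#'   ranked.
#' @export
missing_scaffolds <- function(query, references, scaffolds) {
  query <- unique(query)
  qs <- scaffolds[query]
  covered <- unique(unlist(lapply(references, function(r)
    scaffolds[unique(r)])))
  counts <- table(qs[!(qs %in% covered) & qs != "" & !is.na(qs)])
  out <- data.frame(scaffold_smiles = as.character(names(counts)),
                    count_in_query = as.integer(counts),
                    stringsAsFactors = FALSE)
  if (!nrow(out)) {
    out$pct_of_query <- numeric(0)
    return(out)
  }
  out$pct_of_query <- 100 * out$count_in_query / length(query)
  out <- out[order(-out$count_in_query, out$scaffold_smiles), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise coverage report
#'
#' The per-pair overlap summary: exact and similarity overlap of `a` against
#' `b`, with fractions relative to `|a|`.
#'
#' @inheritParams similarity_overlap
#' @param set_a,set_b display names.
#' @return one-row data.frame mirroring the coverage-table columns.
#' @export
coverage_report <- function(a, b, fingerprints, set_a = "a", set_b = "b",
                            threshold = 0.75, comparator = ">=") {
  ex <- exact_overlap(a, b)
  si <- similarity_overlap(a, b, fingerprints, threshold = threshold,
                           comparator = comparator)
  data.frame(set_a = set_a, set_b = set_b, n_a = length(unique(a)),
             n_b = length(unique(b)), exact_overlap = ex$count,
             exact_fraction = ex$fraction, similarity_overlap = si$count,
             similarity_fraction = si$fraction, threshold = threshold,
             stringsAsFactors = FALSE)
}
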