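# Structure validation, standardization and parent extraction.
#
# Every downstream identity decision (deduplication, overlap) is made on the
# standard InChI of the parent structure produced here. The rule sequence:
#
#   standardize: reject wildcards, parse, canonicalize (kekulization,
#     hydrogen removal and triple-bond normalization are part of the backend's
#     canonical form), neutralize +1/-1 charges where a proton shift suffices
#     (charge-separated groups such as nitro stay as written). Stereochemistry
#     and tautomeric form are preserved as given.
#   get_parent: clear isotopes; drop solvent fragments unless that would
#     empty the molecule; then drop salt fragments under the same guard;
#     collapse duplicate fragments (stereo-distinct fragments are kept);
#     neutralize what remains.
#
# Multi-fragment survivors (true mixtures) are retained and flagged, never
# silently dropped.

.frag_key_cache <- new.env(parent = emptyenv())

.load_fragment_list <- function(path, tiered = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[\t ]+")
  smiles <- vapply(parts, `[[`, character(1), 2L)
  keys <- ob_inchi(ob_neutralize(smiles))
  if (!tiered) return(unique(keys[!is.na(keys)]))
  tier <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]]
                 else "inorganic", character(1))
  ok <- !is.na(keys)
  list(inorganic = unique(keys[ok & tier == "inorganic"]),
       organic = unique(keys[ok & tier == "organic"]))
}

#' Default salt and solvent fragment lists
#'
#' The versioned lists shipped with the package, keyed by InChI of the
#' neutralized fragment. Salts are split into two stripping tiers: bare
#' inorganic counterions (removed first) and organic salt formers, so that a
#' salt of an organic acid resolves to the acid rather than to nothing.
#'
#' @return for solvents a character vector of InChI keys; for salts a list
#'   with `inorganic` and `organic` key vectors.
#' @name fragment_lists
NULL

#' @rdname fragment_lists
#' @export
default_salt_keys <- function() {
  if (is.null(.frag_key_cache$salts)) {
    .frag_key_cache$salts <- .load_fragment_list(
      system.file("extdata", "salts.smi", package = "chemcov"),
      tiered = TRUE)
  }
  .frag_key_cache$salts
}

#' @rdname fragment_lists
#' @export
default_solvent_keys <- function() {
  if (is.null(.frag_key_cache$solvents)) {
    .frag_key_cache$solvents <- .load_fragment_list(
      system.file("extdata", "solvents.smi", package = "chemcov"))
  }
  .frag_key_cache$solvents
}

#' Standardize one structure to its parent form
#'
#' Runs the full standardize + get_parent sequence on a single SMILES and
#' returns either the standardized parent or a rejection record.
#'
#' @param smiles raw SMILES text.
#' @param salt_keys,solvent_keys InChI keys of fragments to strip; defaults to
#'   the shipped lists.
#' @return a list with `status` ("standardized" or "rejected"); on success
#'   `canonical_smiles`, `inchi`, `is_mixture`; on rejection `reason`
#'   (one of "wildcard", "unparseable", "standardization_failure").
#' @export
standardize_structure <- function(smiles,
                                  salt_keys = default_salt_keys(),
                                  solvent_keys = default_solvent_keys()) {
  rej <- function(reason) list(status = "rejected", reason = reason,
                               canonical_smiles = NA_character_,
                               inchi = NA_character_, is_mixture = NA)
  if (is.na(smiles) || !nzchar(trimws(smiles))) return(rej("unparseable"))
  smiles <- trimws(smiles)
  if (smiles_has_wildcard(smiles)) return(rej("wildcard"))
  can <- ob_canonical(smiles)
  if (is.na(can)) return(rej("unparseable"))
  std <- ob_neutralize(can)
  if (is.na(std)) return(rej("standardization_failure"))
  parent <- get_parent(std, salt_keys = salt_keys,
                       solvent_keys = solvent_keys)
  if (is.null(parent)) return(rej("standardization_failure"))
  c(list(status = "standardized"), parent, list(reason = NA_character_))
}

#' Parent extraction
#'
#' Isotope clearing, solvent and salt stripping (each guarded against
#' emptying the molecule), duplicate-fragment collapse, and final
#' neutralization. Stereo-distinct fragments are not duplicates.
#'
#' @param smiles a standardized SMILES.
#' @inheritParams standardize_structure
#' @return list with `canonical_smiles`, `inchi`, `is_mixture`; `NULL` on an
#'   internal failure.
#' @export
get_parent <- function(smiles,
                       salt_keys = default_salt_keys(),
                       solvent_keys = default_solvent_keys()) {
  can <- ob_canonical(smiles_strip_isotopes(smiles))
  if (is.na(can)) return(NULL)
  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (!length(frags)) return(NULL)
  if (length(frags) > 1L) {
    keys <- ob_inchi(ob_neutralize(frags))
    if (anyNA(keys)) return(NULL)
    if (!is.list(salt_keys)) salt_keys <- list(organic = salt_keys)
    for (strip in c(list(solvent_keys), unname(salt_keys))) {
      drop <- keys %in% strip
      if (any(drop) && !all(drop)) {
        frags <- frags[!drop]
        keys <- keys[!drop]
      }
      if (length(frags) == 1L) break
    }
    # duplicate collapse on the stereo-retaining InChI of each fragment
    stereo_keys <- ob_inchi(frags)
    if (anyNA(stereo_keys)) return(NULL)
    frags <- frags[!duplicated(stereo_keys)]
  }
  final <- ob_neutralize(paste(frags, collapse = "."))
  if (is.na(final)) return(NULL)
  final <- ob_canonical(final)
  inchi <- ob_inchi(final)
  if (is.na(final) || is.na(inchi)) return(NULL)
  list(canonical_smiles = final, inchi = inchi,
       is_mixture = grepl(".", final, fixed = TRUE))
}

#' Standardize a table of raw entries
#'
#' Vectorized driver for [standardize_structure()] over a data frame of raw
#' rows. Every input row appears exactly once in the output, either as a
#' standardized structure or as a rejection record (conservation contract).
#'
#' @param entries data.frame with columns `smiles`, `dataset` and optionally
#'   `row_id` (generated when absent).
#' @inheritParams standardize_structure
#' @param verbose log a line per rejection.
#' @return data.frame `[dataset, row_id, input_smiles, canonical_smiles,
#'   inchi, status, reject_reason, is_mixture]`.
#' @export
standardize_table <- function(entries,
                              salt_keys = default_salt_keys(),
                              solvent_keys = default_solvent_keys(),
                              verbose = FALSE) {
  stopifnot(is.data.frame(entries), all(c("smiles", "dataset") %in%
                                          names(entries)))
  if (is.null(entries$row_id)) {
    entries$row_id <- paste0(entries$dataset, ":", seq_len(nrow(entries)))
  }
  res <- lapply(entries$smiles, standardize_structure,
                salt_keys = salt_keys, solvent_keys = solvent_keys)
  out <- data.frame(
    dataset = entries$dataset,
    row_id = entries$row_id,
    input_smiles = entries$smiles,
    canonical_smiles = vapply(res, `[[`, character(1), "canonical_smiles"),
    inchi = vapply(res, `[[`, character(1), "inchi"),
    status = vapply(res, `[[`, character(1), "status"),
    reject_reason = vapply(res, `[[`, character(1), "reason"),
    is_mixture = vapply(res, function(x) isTRUE(x$is_mixture), logical(1)),
    stringsAsFactors = FALSE)
  if (verbose) {
    bad <- out[out$status == "rejected", ]
    for (i in seq_len(nrow(bad))) {
      message("rejected [", bad$reject_reason[i], "] ", bad$dataset[i], "/",
              bad$row_id[i], ": ", bad$input_smiles[i])
    }
  }
  out
}
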