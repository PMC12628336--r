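# SMARTS functional-group catalogue handling and per-group proportion
# differences between a query domain and reference sets.

#' Read a SMARTS functional-group catalogue
#'
#' Accepts either the two-column form `name<TAB/space>SMARTS` or the
#' annotated `Name: SMARTS` form used by the Open Babel functional-group
#' classification file. Lines starting with `#` are comments.
#'
#' @param path catalogue file.
#' @return data.frame `[name, smarts]`.
#' @export
read_fg_catalogue <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  colon <- grepl("^[^ \t]+:[ \t]", lines)
  name <- character(length(lines))
  smarts <- character(length(lines))
  name[colon] <- sub(":.*$", "", lines[colon])
  smarts[colon] <- trimws(sub("^[^ \t]+:[ \t]+", "", lines[colon]))
  parts <- strsplit(lines[!colon], "[ \t]+")
  name[!colon] <- vapply(parts, `[[`, character(1), 1L)
  smarts[!colon] <- vapply(parts, function(p)
    paste(p[-1], collapse = ""), character(1))
  ok <- nzchar(smarts)
  data.frame(name = name[ok], smarts = smarts[ok], stringsAsFactors = FALSE)
}

#' Locate the installed Open Babel functional-group catalogue
#'
#' Finds `SMARTS_InteLigand.txt` (the ~300-entry functional-group
#' classification list distributed with Open Babel) in the Open Babel data
#' directory next to the `obabel` executable.
#'
#' @return path to the catalogue file, or `NA` if not found.
#' @export
default_fg_catalogue_path <- function() {
  ob <- Sys.which("obabel")
  roots <- c(if (nzchar(ob)) file.path(dirname(dirname(ob)), "share",
                                       "openbabel"),
             "/usr/share/openbabel", "/usr/local/share/openbabel")
  for (root in roots) {
    hit <- Sys.glob(file.path(root, "*", "SMARTS_InteLigand.txt"))
    if (length(hit)) return(hit[[1]])
  }
  NA_character_
}

#' Match a functional-group catalogue against a set of structures
#'
#' Binary presence per substance and group (at least one substructure match;
#' match multiplicity is deliberately not recorded).
#'
#' @param smiles character vector of canonical SMILES, named by substance id.
#' @param catalogue data.frame `[name, smarts]`.
#' @return logical matrix substances x groups.
#' @export
match_functional_groups <- function(smiles, catalogue) {
  ids <- if (!is.null(names(smiles))) names(smiles) else smiles
  present <- matrix(FALSE, nrow = length(smiles), ncol = nrow(catalogue),
                    dimnames = list(ids, catalogue$name))
  if (!length(smiles)) return(present)
  refs <- ob_mol_refs(smiles)
  for (k in seq_len(nrow(catalogue))) {
    counts <- tryCatch(
      suppressWarnings(ChemmineOB::smartsSearch_OB(refs, catalogue$smarts[k],
                                                   uniqueMatches = TRUE)),
      error = function(e) NULL)
    if (is.null(counts)) {
      stop("SMARTS pattern failed to compile: '", catalogue$name[k], "' (",
           catalogue$smarts[k], ")")
    }
    present[, k] <- counts > 0
  }
  present
}

#' Filter a catalogue to patterns observed in the analyzed sets
#'
#' A pattern is retained iff it matches at least one substance in at least
#' one of the supplied presence matrices.
#'
#' @param presence_list list of logical presence matrices sharing columns.
#' @return list with `retained` (character vector of group names) and
#'   `dropped`.
#' @export
filter_patterns <- function(presence_list) {
  any_match <- Reduce(`|`, lapply(presence_list, function(m) colSums(m) > 0))
  list(retained = names(any_match)[any_match],
       dropped = names(any_match)[!any_match])
}

#' Per-group proportion differences between a query and a reference set
#'
#' `difference = p_query - p_reference` per functional group; a negative
#' value means the group is overrepresented in the reference set.
#'
#' @param presence_query,presence_reference logical presence matrices with
#'   identical columns.
#' @param groups optional subset of group names (e.g. the retained
#'   catalogue).
#' @return data.frame `[group, p_query, p_reference, difference]`.
#' @export
proportion_difference <- function(presence_query, presence_reference,
                                  groups = colnames(presence_query)) {
  if (!nrow(presence_query) || !nrow(presence_reference)) {
    stop("proportion_difference: empty set")
  }
  pq <- colMeans(presence_query[, groups, drop = FALSE])
  pr <- colMeans(presence_reference[, groups, drop = FALSE])
  data.frame(group = groups, p_query = unname(pq), p_reference = unname(pr),
             difference = unname(pq - pr), stringsAsFactors = FALSE)
}

#' Top-k over- and underrepresented functional groups
#'
#' @param rows data.frame from [proportion_difference()].
#' @param k list length per direction (default 10).
#' @return list with `most_positive` and `most_negative` data.frames, ranked;
#'   ties broken lexicographically by group name.
#' @export
top_k_enrichment <- function(rows, k = 10L) {
  if (nrow(rows) < k) {
    message("top_k_enrichment: only ", nrow(rows), " groups available")
  }
  pos <- rows[order(-rows$difference, rows$group), , drop = FALSE]
  neg <- rows[order(rows$difference, rows$group), , drop = FALSE]
  list(most_positive = utils::head(pos, k), most_negative = utils::head(neg, k))
}
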