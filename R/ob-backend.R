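#' @importFrom ChemmineOB convertFormat forEachMol prop_OB smartsSearch_OB
#' @importFrom ChemmineR smiles2sdf atomblock bondblock cid
NULL

# Open Babel molecule references straight from (validated) SMILES; used for
# property calculation and SMARTS matching without any intermediate molblock
# rewrite. One ref per input; callers must pass parseable SMILES.
ob_mol_refs <- function(smiles) {
  if (!length(smiles)) return(list())
  refs <- ChemmineOB::forEachMol("SMILES",
                                 paste0(paste(smiles, collapse = "\n"), "\n"),
                                 identity)
  if (length(refs) != length(smiles)) {
    stop("Open Babel parsed ", length(refs), " of ", length(smiles),
         " structures; inputs must be pre-validated SMILES")
  }
  refs
}

# Single source of truth for every Open Babel round trip.  All conversions are
# per-molecule: a malformed SMILES inside a batch aborts the remaining records
# in Open Babel's stream interface, so batching is only safe for structures
# that already passed validation.

ob_convert1 <- function(smiles, to, options = NULL) {
  if (is.na(smiles) || !nzchar(smiles)) return(NA_character_)
  args <- list(from = "SMI", to = to, source = paste0(smiles, "\n"))
  if (!is.null(options)) args$options <- options
  out <- tryCatch(suppressWarnings(do.call(convertFormat, args)),
                  error = function(e) NA_character_)
  if (is.na(out)) return(NA_character_)
  out <- strsplit(out, "[\t\n]")[[1]]
  out <- out[nzchar(out)]
  if (!length(out)) NA_character_ else out[[1]]
}

#' Canonical SMILES via Open Babel
#'
#' Vectorized canonicalization. Unparseable entries yield `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES (`NA` where parsing failed).
#' @export
ob_canonical <- function(smiles) {
  vapply(smiles, ob_convert1, character(1), to = "CAN", USE.NAMES = FALSE)
}

#' Standard InChI via Open Babel
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of standard InChI strings (`NA` on failure).
#' @export
ob_inchi <- function(smiles) {
  out <- vapply(smiles, ob_convert1, character(1), to = "INCHI",
                USE.NAMES = FALSE)
  out[!is.na(out) & !startsWith(out, "InChI=")] <- NA_character_
  out
}

# Neutralize +1/-1 charges where a proton can be added or removed; Open Babel
# leaves charge-separated groups (nitro, N-oxide) and quaternary N untouched.
ob_neutralize <- function(smiles) {
  opts <- data.frame(names = "neutralize", args = "")
  vapply(smiles, ob_convert1, character(1), to = "CAN", options = opts,
         USE.NAMES = FALSE)
}

# Canonical SMILES from a V2000 molblock (used for scaffold canonicalization).
ob_molblock_to_can <- function(molblock) {
  out <- tryCatch(
    suppressWarnings(convertFormat("SDF", "CAN", source = molblock)),
    error = function(e) NA_character_)
  if (is.na(out)) return(NA_character_)
  out <- strsplit(out, "[\t\n]")[[1]]
  out <- out[nzchar(out)]
  if (!length(out)) NA_character_ else out[[1]]
}

# ---- SMILES text utilities ------------------------------------------------

#' Detect wildcard atoms in raw SMILES text
#'
#' Variable-composition entries are flagged on the raw text (any `*` token)
#' before any parsing is attempted.
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
smiles_has_wildcard <- function(smiles) {
  grepl("*", smiles, fixed = TRUE)
}

# Set all isotopes to 0 at the SMILES text level: strip leading mass numbers
# inside bracket atoms ("[13CH3]" -> "[CH3]", "[2H]" -> "[H]"). Bracket
# hydrogens left behind are folded back into implicit hydrogens on
# re-canonicalization.
smiles_strip_isotopes <- function(smiles) {
  gsub("\\[[0-9]+", "[", smiles)
}

.SMILES_ATOM_RE <- "\\[[^]]*\\]|Cl|Br|[BCNOPSFI]|[bcnops]"

# Atom tokens of a SMILES string, in writing order.
smiles_atom_tokens <- function(smiles) {
  regmatches(smiles, gregexpr(.SMILES_ATOM_RE, smiles))[[1]]
}

# Number of aromatic atoms, read off the canonical (aromatic-form) SMILES:
# lowercase organic-subset symbols plus bracket atoms with a lowercase
# element symbol ([nH], [n+], [se], ...).
smiles_aromatic_count <- function(canonical_smiles) {
  vapply(canonical_smiles, function(s) {
    if (is.na(s)) return(NA_integer_)
    tok <- smiles_atom_tokens(s)
    brk <- startsWith(tok, "[")
    n <- sum(tok %in% c("b", "c", "n", "o", "p", "s"))
    if (any(brk)) {
      sym <- sub("^\\[[0-9]*", "", tok[brk])
      n <- n + sum(grepl("^[a-z]", sym))
    }
    as.integer(n)
  }, integer(1), USE.NAMES = FALSE)
}

# ---- molecular graphs from Open Babel SDF ---------------------------------

# Old-style SDF atom-line charge codes.
.SDF_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

# Default valences used to infer implicit hydrogen counts from a kekulized
# connection table. Multi-valent elements list every allowed valence.
.VALENCES <- list(B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
                  F = 1, Cl = 1, Br = 1, I = 1, Si = 4, Se = c(2, 4, 6),
                  As = c(3, 5), Sn = c(2, 4), H = 1)

implicit_h_count <- function(elem, charge, bond_order_sum) {
  val <- .VALENCES[[elem]]
  if (is.null(val)) return(0L)
  # protonation shifts the usual valence (N+ -> 4, O- -> 1, ...)
  val <- val + ifelse(elem %in% c("C"), abs(charge) * -1, charge)
  val <- val[val >= bond_order_sum]
  if (!length(val)) return(0L)
  as.integer(min(val) - bond_order_sum)
}

#' Build lightweight molecular graphs
#'
#' Parses (already validated) SMILES through Open Babel into plain R graph
#' structures: element, formal charge, implicit hydrogen count, bond list
#' with kekulized bond orders, ring membership and smallest set of smallest
#' rings. These graphs back the fingerprint, descriptor-count and scaffold
#' computations. Pass canonical SMILES to guarantee a deterministic
#' kekulization.
#'
#' @param smiles character vector of valid SMILES.
#' @return a list of `mol_graph` objects (NULL where conversion failed).
#' @export
mol_graphs <- function(smiles) {
  if (!length(smiles)) return(list())
  out <- vector("list", length(smiles))
  ntok <- vapply(smiles, function(s) {
    if (is.na(s)) return(0L)
    length(smiles_atom_tokens(s))
  }, integer(1), USE.NAMES = FALSE)
  # single-heavy-atom molecules break the SDF round trip; build directly
  for (i in which(ntok == 1L)) {
    out[[i]] <- .single_atom_graph(smiles_atom_tokens(smiles[[i]])[[1]])
  }
  multi <- which(ntok > 1L)
  if (length(multi)) {
    ids <- paste0("m", multi)
    sm <- smiles[multi]
    names(sm) <- ids
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(sm))
    have <- match(ChemmineR::cid(sdf), ids)
    for (k in seq_along(have)) {
      i <- multi[have[k]]
      if (is.na(i)) next
      out[[i]] <- tryCatch(.graph_from_sdf(sdf[[k]]),
                           error = function(e) NULL)
    }
  }
  out
}

.single_atom_graph <- function(token) {
  inner <- sub("^\\[([0-9]*)", "", sub("\\]$", "", token))
  elem <- regmatches(inner, regexpr("^[A-Za-z][a-z]?", inner))
  if (!length(elem)) return(NULL)
  if (elem %in% c("b", "c", "n", "o", "p", "s")) elem <- toupper(elem)
  rest <- sub("^[A-Za-z][a-z]?", "", inner)
  charge <- 0L
  cm <- regmatches(rest, regexpr("[+-][0-9]*$|[+]+$|[-]+$", rest))
  if (length(cm) && nzchar(cm)) {
    sign <- if (startsWith(cm, "-")) -1L else 1L
    digits <- gsub("[+-]", "", cm)
    charge <- sign * if (nzchar(digits)) as.integer(digits) else
      nchar(gsub("[^+-]", "", cm))
  }
  hm <- regmatches(rest, regexpr("H[0-9]*", rest))
  nH <- if (length(hm) && nzchar(hm)) {
    d <- sub("H", "", hm)
    if (nzchar(d)) as.integer(d) else 1L
  } else implicit_h_count(elem, charge, 0)
  g <- list(n = 1L, elem = elem, charge = charge, nH = nH,
            bi = integer(0), bj = integer(0), bo = integer(0),
            adj = list(integer(0)), badj = list(integer(0)), degree = 0L,
            ring_bond = logical(0), ring_atom = FALSE, n_rings = 0L,
            n_components = 1L, sssr = list())
  class(g) <- "mol_graph"
  g
}

.graph_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  elem <- sub("_.*$", "", rownames(ab))
  chg_col <- ab[, "C6"]
  charge <- unname(.SDF_CHARGE[as.character(chg_col)])
  charge[is.na(charge)] <- 0L
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = as.integer(length(bb) > 0))
  nb <- if (length(bb)) nrow(bb) else 0L
  bi <- if (nb) as.integer(bb[, 1]) else integer(0)
  bj <- if (nb) as.integer(bb[, 2]) else integer(0)
  bo <- if (nb) as.integer(bb[, 3]) else integer(0)
  adj <- vector("list", n)
  badj <- vector("list", n)
  for (k in seq_len(nb)) {
    adj[[bi[k]]] <- c(adj[[bi[k]]], bj[k])
    adj[[bj[k]]] <- c(adj[[bj[k]]], bi[k])
    badj[[bi[k]]] <- c(badj[[bi[k]]], k)
    badj[[bj[k]]] <- c(badj[[bj[k]]], k)
  }
  bosum <- numeric(n)
  for (k in seq_len(nb)) {
    o <- min(bo[k], 3L)  # treat any exotic order code as triple at most
    bosum[bi[k]] <- bosum[bi[k]] + o
    bosum[bj[k]] <- bosum[bj[k]] + o
  }
  nH <- vapply(seq_len(n), function(a)
    implicit_h_count(elem[a], charge[a], bosum[a]), integer(1))
  g <- list(n = n, elem = elem, charge = charge, nH = nH,
            bi = bi, bj = bj, bo = bo, adj = adj, badj = badj,
            degree = lengths(adj))
  g <- c(g, .ring_perception(g))
  class(g) <- "mol_graph"
  g
}

# Bridges by edge-removal reachability restricted to small molecules would be
# quadratic; instead run one iterative DFS (Tarjan low-link) per component.
.find_bridges <- function(g) {
  n <- g$n
  nb <- length(g$bi)
  if (!nb) return(logical(0))
  disc <- integer(n); low <- integer(n); timer <- 0L
  is_bridge <- logical(nb)
  parent_edge <- integer(n)
  for (root in seq_len(n)) {
    if (disc[root] > 0L) next
    stack <- list(list(v = root, ei = 0L))
    parent_edge[root] <- 0L
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$ei == 0L) {
        timer <- timer + 1L
        disc[v] <- timer; low[v] <- timer
      }
      edges <- g$badj[[v]]
      advanced <- FALSE
      while (fr$ei < length(edges)) {
        fr$ei <- fr$ei + 1L
        e <- edges[fr$ei]
        w <- if (g$bi[e] == v) g$bj[e] else g$bi[e]
        if (e == parent_edge[v]) next
        if (disc[w] > 0L) {
          low[v] <- min(low[v], disc[w])
        } else {
          parent_edge[w] <- e
          stack[[length(stack)]] <- fr
          stack[[length(stack) + 1L]] <- list(v = w, ei = 0L)
          advanced <- TRUE
          break
        }
      }
      if (!advanced) {
        stack[[length(stack)]] <- NULL
        pe <- parent_edge[v]
        if (pe > 0L) {
          u <- if (g$bi[pe] == v) g$bj[pe] else g$bi[pe]
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) is_bridge[pe] <- TRUE
        }
      }
    }
  }
  is_bridge
}

.n_components <- function(g) {
  n <- g$n
  seen <- logical(n); ncomp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in g$adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  ncomp
}

.ring_perception <- function(g) {
  is_bridge <- .find_bridges(g)
  ring_bond <- !is_bridge
  ring_atom <- logical(g$n)
  ring_atom[c(g$bi[ring_bond], g$bj[ring_bond])] <- TRUE
  ncomp <- .n_components(g)
  n_rings <- length(g$bi) - g$n + ncomp  # cyclomatic number == |SSSR|
  list(ring_bond = ring_bond, ring_atom = ring_atom,
       n_rings = as.integer(n_rings), n_components = ncomp,
       sssr = .sssr(g, ring_bond, n_rings))
}

# SSSR: shortest cycle through every ring bond (BFS with that bond removed),
# then a greedy GF(2)-independent selection by increasing cycle size.
.sssr <- function(g, ring_bond, n_rings) {
  if (n_rings <= 0L) return(list())
  cand <- list()
  for (e in which(ring_bond)) {
    path <- .bfs_path(g, g$bi[e], g$bj[e], skip_edge = e)
    if (is.null(path)) next
    bonds <- logical(length(g$bi))
    bonds[e] <- TRUE
    for (k in seq_len(length(path) - 1L)) {
      b <- .bond_between(g, path[k], path[k + 1L])
      bonds[b] <- TRUE
    }
    cand[[length(cand) + 1L]] <- list(atoms = path, bonds = bonds,
                                      size = length(path))
  }
  cand <- cand[order(vapply(cand, `[[`, integer(1), "size"))]
  basis <- list(); rings <- list()
  for (cy in cand) {
    v <- cy$bonds
    for (b in basis) if (v[b$pivot]) v <- xor(v, b$vec)
    if (any(v)) {
      basis[[length(basis) + 1L]] <- list(vec = v, pivot = which(v)[1])
      rings[[length(rings) + 1L]] <- cy
      if (length(rings) == n_rings) break
    }
  }
  rings
}

.bond_between <- function(g, a, b) {
  for (e in g$badj[[a]]) if (g$bi[e] == b || g$bj[e] == b) return(e)
  stop("no bond between atoms ", a, " and ", b)
}

.bfs_path <- function(g, from, to, skip_edge) {
  prev <- integer(g$n)
  prev[from] <- -1L
  queue <- from
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (e in g$badj[[v]]) {
      if (e == skip_edge) next
      w <- if (g$bi[e] == v) g$bj[e] else g$bi[e]
      if (prev[w] != 0L) next
      prev[w] <- v
      if (w == to) {
        path <- w
        while (path[1] != from) path <- c(prev[path[1]], path)
        return(path)
      }
      queue <- c(queue, w)
    }
  }
  NULL
}
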