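# Circular fingerprints, physicochemical descriptors and Murcko scaffolds.
#
# Fingerprints are an ECFP-style iterative neighbourhood hash (radius 2,
# folded to 2048 bits). Bit positions are deterministic for a given parent
# structure because every graph is built from the canonical SMILES, which
# fixes atom order and kekulization; the hashing scheme is frozen by
# regression fixtures in the test suite.

.HASH_MOD <- 2147483647  # 2^31 - 1; keeps double arithmetic exact

.hash_ints <- function(x) {
  h <- 17
  for (v in x) h <- (h * 31 + v) %% .HASH_MOD
  h
}

.ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                    P = 15, S = 16, Cl = 17, As = 33, Se = 34, Br = 35,
                    Sn = 50, I = 53)

#' Circular (Morgan-type) fingerprint matrix
#'
#' Computes radius-`radius` circular fingerprints folded to `n_bits` bits for
#' a vector of canonical SMILES. Atom environments are hashed from initial
#' invariants (atomic number, heavy-atom degree, implicit hydrogen count,
#' formal charge, ring membership) and iteratively extended over sorted
#' (bond order, neighbour id) pairs, the standard ECFP construction.
#'
#' @param smiles character vector of canonical SMILES.
#' @param radius neighbourhood radius (default 2).
#' @param n_bits folded length (default 2048).
#' @return logical matrix `length(smiles) x n_bits`; rows named by `names(smiles)`
#'   when present, else by the SMILES.
#' @export
morgan_fp <- function(smiles, radius = 2L, n_bits = 2048L) {
  graphs <- mol_graphs(smiles)
  out <- matrix(FALSE, nrow = length(smiles), ncol = n_bits)
  rownames(out) <- if (!is.null(names(smiles))) names(smiles) else smiles
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (is.null(g)) next
    out[i, .morgan_bits(g, radius, n_bits)] <- TRUE
  }
  out
}

.morgan_bits <- function(g, radius, n_bits) {
  z <- .ATOMIC_NUMBER[g$elem]
  z[is.na(z)] <- 0
  inv <- vapply(seq_len(g$n), function(a) {
    .hash_ints(c(z[a], g$degree[a], g$nH[a], g$charge[a] + 10,
                 as.integer(g$ring_atom[a])))
  }, numeric(1))
  feats <- inv
  for (r in seq_len(radius)) {
    nxt <- inv
    for (a in seq_len(g$n)) {
      es <- g$badj[[a]]
      if (length(es)) {
        nb <- ifelse(g$bi[es] == a, g$bj[es], g$bi[es])
        o <- ord <- order(g$bo[es], inv[nb])
        pairs <- rbind(g$bo[es][ord], inv[nb][ord])
        nxt[a] <- .hash_ints(c(r, inv[a], as.vector(pairs)))
      } else {
        nxt[a] <- .hash_ints(c(r, inv[a]))
      }
    }
    inv <- nxt
    feats <- c(feats, inv)
  }
  unique(as.integer(unique(feats) %% n_bits) + 1L)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`. Two all-zero fingerprints are defined as identical
#' (similarity 1); an all-zero against a non-empty fingerprint scores 0.
#'
#' @param a,b logical fingerprint vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}

#' All-pairs Tanimoto similarity between two fingerprint matrices
#'
#' @param A,B logical matrices with the same number of columns.
#' @return numeric matrix `nrow(A) x nrow(B)`.
#' @export
tanimoto_matrix <- function(A, B = A) {
  if (ncol(A) != ncol(B)) stop("fingerprint length mismatch")
  Ai <- matrix(as.integer(A), nrow = nrow(A))
  Bi <- matrix(as.integer(B), nrow = nrow(B))
  inter <- tcrossprod(Ai, Bi)
  pa <- rowSums(Ai)
  pb <- rowSums(Bi)
  un <- outer(pa, pb, `+`) - inter
  sim <- ifelse(un == 0, 1, inter / un)
  rownames(sim) <- rownames(A)
  colnames(sim) <- rownames(B)
  sim
}

# ---- Murcko scaffolds -----------------------------------------------------

#' Murcko scaffold SMILES
#'
#' Extracts the molecular framework: ring systems plus the linkers between
#' them, with all side chains removed; atoms attached to the framework by a
#' double or triple bond (e.g. exocyclic carbonyl oxygens) are retained, the
#' usual scaffold convention. Acyclic molecules yield the empty scaffold `""`.
#'
#' @param smiles character vector of canonical SMILES.
#' @return character vector of canonical scaffold SMILES (`""` = acyclic,
#'   `NA` = failed conversion).
#' @export
murcko_scaffold <- function(smiles) {
  graphs <- mol_graphs(smiles)
  vapply(seq_along(smiles), function(i) {
    g <- graphs[[i]]
    if (is.null(g)) return(NA_character_)
    .scaffold_of_graph(g)
  }, character(1))
}

.scaffold_of_graph <- function(g) {
  if (!any(g$ring_bond)) return("")
  keep <- rep(TRUE, g$n)
  repeat {
    deg <- integer(g$n)
    for (e in seq_along(g$bi)) {
      if (keep[g$bi[e]] && keep[g$bj[e]]) {
        deg[g$bi[e]] <- deg[g$bi[e]] + 1L
        deg[g$bj[e]] <- deg[g$bj[e]] + 1L
      }
    }
    drop <- keep & !g$ring_atom & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  # re-attach atoms multiple-bonded directly to the framework
  repeat {
    added <- FALSE
    for (e in seq_along(g$bi)) {
      if (g$bo[e] < 2L) next
      a <- g$bi[e]; b <- g$bj[e]
      if (keep[a] && !keep[b]) { keep[b] <- TRUE; added <- TRUE }
      else if (keep[b] && !keep[a]) { keep[a] <- TRUE; added <- TRUE }
    }
    if (!added) break
  }
  ob_molblock_to_can(.subgraph_molblock(g, keep))
}

# Minimal V2000 molblock of an induced subgraph (charges via M CHG).
.subgraph_molblock <- function(g, keep) {
  idx <- which(keep)
  remap <- integer(g$n)
  remap[idx] <- seq_along(idx)
  eb <- which(keep[g$bi] & keep[g$bj])
  lines <- c("", " chemcov", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     length(idx), length(eb)))
  for (a in idx) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, g$elem[a]))
  }
  for (e in eb) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              remap[g$bi[e]], remap[g$bj[e]], g$bo[e]))
  }
  chg <- idx[g$charge[idx] != 0L]
  if (length(chg)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", remap[chg],
                                            g$charge[chg]), collapse = "")))
  }
  paste(c(lines, "M  END", "$$$$", ""), collapse = "\n")
}

# ---- physicochemical descriptors ------------------------------------------

.DESCRIPTOR_NAMES <- c("mw", "logp", "tpsa", "hba", "hbd", "heavy_atoms",
                       "n_count", "o_count", "s_count", "halogen_count",
                       "bridgehead_count", "chiral_centers", "aromatic_atoms",
                       "ring_count", "frac_sp3_carbon", "formal_charge")

#' The 16 physicochemical descriptors
#'
#' Molecular weight, Crippen-type logP, topological polar surface area,
#' hydrogen-bond acceptor and donor counts (Open Babel definitions), heavy
#' atom count, nitrogen/oxygen/sulfur counts, halogen count (F, Cl, Br, I),
#' bridgehead atom count, potential stereocenter count, aromatic atom count,
#' SSSR ring count, fraction of sp3-hybridized carbons and net formal charge.
#'
#' @param smiles character vector of canonical SMILES.
#' @return data.frame with one row per input and 16 named columns; rows with
#'   failed computations carry `NA` and are flagged via the `ok` attribute.
#' @export
physchem_descriptors <- function(smiles) {
  n <- length(smiles)
  out <- as.data.frame(matrix(NA_real_, nrow = n,
                              ncol = length(.DESCRIPTOR_NAMES)))
  names(out) <- .DESCRIPTOR_NAMES
  rownames(out) <- if (!is.null(names(smiles))) names(smiles) else NULL
  if (!n) return(out)
  props <- tryCatch(
    suppressWarnings(ChemmineOB::prop_OB(ob_mol_refs(smiles))),
    error = function(e) NULL)
  if (!is.null(props) && nrow(props) == n) {
    out$mw <- props$MW
    out$logp <- props$logP
    out$tpsa <- props$TPSA
    out$hba <- props$HBA2
    out$hbd <- props$HBD
  }
  graphs <- mol_graphs(smiles)
  for (i in seq_len(n)) {
    g <- graphs[[i]]
    if (is.null(g)) next
    heavy <- g$elem != "H"
    out$heavy_atoms[i] <- sum(heavy)
    out$n_count[i] <- sum(g$elem == "N")
    out$o_count[i] <- sum(g$elem == "O")
    out$s_count[i] <- sum(g$elem == "S")
    out$halogen_count[i] <- sum(g$elem %in% c("F", "Cl", "Br", "I"))
    out$ring_count[i] <- g$n_rings
    out$formal_charge[i] <- sum(g$charge)
    out$bridgehead_count[i] <- .bridgehead_count(g)
    out$chiral_centers[i] <- .stereocenter_count(g)
    is_c <- g$elem == "C"
    nc <- sum(is_c)
    if (nc == 0) {
      out$frac_sp3_carbon[i] <- 0
    } else {
      unsat <- logical(g$n)
      for (e in seq_along(g$bi)) {
        if (g$bo[e] >= 2L) unsat[c(g$bi[e], g$bj[e])] <- TRUE
      }
      out$frac_sp3_carbon[i] <- sum(is_c & !unsat) / nc
    }
  }
  out$aromatic_atoms <- as.numeric(smiles_aromatic_count(smiles))
  attr(out, "ok") <- stats::complete.cases(out)
  out
}

# Bridgehead atoms: atoms with >= 3 ring bonds that sit in two SSSR rings
# sharing at least two bonds (fused pairs that only share one bond, as in
# naphthalene, do not create bridgeheads).
.bridgehead_count <- function(g) {
  rings <- g$sssr
  if (length(rings) < 2L) return(0L)
  ring_deg <- integer(g$n)
  for (e in which(g$ring_bond)) {
    ring_deg[g$bi[e]] <- ring_deg[g$bi[e]] + 1L
    ring_deg[g$bj[e]] <- ring_deg[g$bj[e]] + 1L
  }
  bh <- logical(g$n)
  for (i in seq_len(length(rings) - 1L)) {
    for (j in seq(i + 1L, length(rings))) {
      shared_bonds <- sum(rings[[i]]$bonds & rings[[j]]$bonds)
      if (shared_bonds >= 2L) {
        common <- intersect(rings[[i]]$atoms, rings[[j]]$atoms)
        bh[common[ring_deg[common] >= 3L]] <- TRUE
      }
    }
  }
  sum(bh)
}

# Potential stereocenters (assigned + unassigned): atoms bearing four
# distinguishable substituent branches, with at most one implicit hydrogen.
# Branch identity is judged by Weisfeiler-Lehman refinement on the graph with
# the candidate atom masked; an approximation of CIP analysis that is exact
# for acyclic environments and conservative inside symmetric rings.
.stereocenter_count <- function(g) {
  cand <- which(g$elem %in% c("C", "Si") &
                  g$degree + g$nH == 4L & g$nH <= 1L)
  if (!length(cand)) return(0L)
  count <- 0L
  for (a in cand) {
    nbrs <- g$adj[[a]]
    cls <- .wl_classes_masked(g, a)
    ids <- cls[nbrs]
    if (g$nH[a] == 1L) ids <- c(ids, -1)
    if (!anyDuplicated(ids)) count <- count + 1L
  }
  count
}

.wl_classes_masked <- function(g, mask) {
  z <- .ATOMIC_NUMBER[g$elem]
  z[is.na(z)] <- 0
  inv <- z * 100 + g$nH * 10 + (g$charge + 3)
  inv[mask] <- -99
  for (iter in seq_len(min(g$n, 24L))) {
    nxt <- inv
    for (a in seq_len(g$n)) {
      if (a == mask) next
      es <- g$badj[[a]]
      keep <- vapply(es, function(e) g$bi[e] != mask && g$bj[e] != mask,
                     logical(1))
      es <- es[keep]
      if (!length(es)) { nxt[a] <- .hash_ints(inv[a]); next }
      nb <- ifelse(g$bi[es] == a, g$bj[es], g$bi[es])
      ord <- order(g$bo[es], inv[nb])
      nxt[a] <- .hash_ints(c(inv[a], rbind(g$bo[es][ord], inv[nb][ord])))
    }
    if (length(unique(nxt)) == length(unique(inv))) { inv <- nxt; break }
    inv <- nxt
  }
  inv
}
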