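# Shared fixtures, built once per test session. Everything is generated in
# code from fixed seeds; no stored binary data.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small clean synthetic corpus (2 query + 2 reference sets, ~100 molecules).
fixture_lib <- function() {
  with_cache("lib", generate_library(synth_config(
    n_query_sets = 2L, n_reference_sets = 2L, query_set_size = 25L,
    reference_set_size = 30L, seed = 11L)))
}

# The same corpus with injected salt/wildcard/duplicate artifacts.
fixture_lib_corrupt <- function() {
  with_cache("lib_corrupt", inject_artifacts(fixture_lib()))
}

# Fingerprints over the clean corpus universe, keyed by InChI.
fixture_fps <- function() {
  with_cache("fps", {
    lib <- fixture_lib()
    fp <- morgan_fp(stats::setNames(lib$molecules$canonical_smiles,
                                    lib$molecules$inchi))
    fp
  })
}

# A deterministic set of drug/pesticide-like SMILES used for structure-level
# property tests (valid, diverse, no salts).
fixture_smiles <- function() {
  c(benzene = "c1ccccc1", toluene = "Cc1ccccc1",
    phenol = "Oc1ccccc1", aniline = "Nc1ccccc1",
    nitrobenzene = "O=[N+]([O-])c1ccccc1",
    chlorpyrifos = "CCOP(=S)(OCC)Oc1nc(Cl)c(Cl)cc1Cl",
    atrazine = "CCNc1nc(Cl)nc(NC(C)C)n1",
    caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    ddt = "Clc1ccc(cc1)C(c1ccc(Cl)cc1)C(Cl)(Cl)Cl",
    alanine = "CC(N)C(=O)O",
    naphthalene = "c1ccc2ccccc2c1",
    hexane = "CCCCCC",
    ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    norbornane = "C1CC2CCC1C2")
}

# Independent O(n^2) similarity-scan oracle for overlap operations.
brute_force_similarity_count <- function(a, b, fps, threshold, cmp = `>=`) {
  count <- 0L
  hits <- character(0)
  for (x in a) {
    best <- 0
    for (y in b) best <- max(best, tanimoto(fps[x, ], fps[y, ]))
    if (cmp(best, threshold)) { count <- count + 1L; hits <- c(hits, x) }
  }
  list(count = count, members = hits)
}

brute_force_mean_pairwise <- function(ids, fps) {
  tot <- 0; np <- 0L
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      tot <- tot + tanimoto(fps[ids[i], ], fps[ids[j], ])
      np <- np + 1L
    }
  }
  tot / np
}

# Naive trustworthiness from the rank definition, kept structurally
# independent of the package implementation.
brute_force_trustworthiness <- function(dX, dY, k) {
  n <- nrow(dX)
  s <- 0
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    orig_sorted <- others[order(dX[i, others])]
    emb_sorted <- others[order(dY[i, others])]
    for (j in emb_sorted[seq_len(k)]) {
      r <- which(orig_sorted == j)
      if (r > k) s <- s + (r - k)
    }
  }
  1 - 2 * s / (n * k * (2 * n - 3 * k - 1))
}

# Random atom-order permutation of a SMILES via its molecular graph: rebuild
# through Open Babel from a shuffled-atom molblock.
permute_smiles <- function(smiles) {
  g <- mol_graphs(smiles)[[1]]
  if (is.null(g)) return(NA_character_)
  perm <- sample(g$n)
  inv <- integer(g$n); inv[perm] <- seq_len(g$n)
  lines <- c("", " perm", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     g$n, length(g$bi)))
  for (a in perm) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, g$elem[a]))
  }
  for (e in seq_along(g$bi)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              inv[g$bi[e]], inv[g$bj[e]], g$bo[e]))
  }
  chg <- which(g$charge != 0L)
  if (length(chg)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", inv[chg],
                                            g$charge[chg]), collapse = "")))
  }
  block <- paste(c(lines, "M  END", "$$$$", ""), collapse = "\n")
  out <- ChemmineOB::convertFormat("SDF", "SMI", source = block)
  out <- strsplit(out, "[\t\n]")[[1]]
  out <- out[nzchar(out)]
  if (!length(out)) NA_character_ else out[[1]]
}
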