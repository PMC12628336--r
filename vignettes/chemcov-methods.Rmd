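---
title: "Chemical-space coverage analysis with chemcov: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical-space coverage analysis with chemcov}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

Regulatory read-across and QSAR both rest on one assumption: that the
substances for which reference data exist cover the chemical neighbourhood of
the substance under assessment. `chemcov` quantifies that assumption for any
query domain (the motivating case is pesticide active substances, metabolites
and impurities) against any collection of reference sets (the motivating case
is public genotoxicity datasets for the six standard test types: Ames, in
vitro mammalian cell gene mutation, in vitro/in vivo micronucleus, in
vitro/in vivo chromosomal aberration).

Coverage is measured on four complementary axes:

1. **Identity** — exact overlap of standard-InChI keys after structure
   standardization.
2. **Similarity** — the fraction of one set within a Tanimoto threshold
   (default at least 0.75 on radius-2, 2048-bit circular fingerprints) of the
   other.
3. **Scaffolds** — Murcko framework counts, molecules-per-scaffold, singleton
   fractions, and a ranked list of query scaffolds absent from every
   reference set (the concrete "data gap" output).
4. **Functional groups and global shape** — per-group proportion differences
   against a SMARTS catalogue, plus PCA of 16 physicochemical descriptors and
   a UMAP embedding of the fingerprints.

## Standardization and identity

All identity decisions are made on the standard InChI of the *parent*
structure. The standardization sequence is:

* reject entries whose raw SMILES text contains the wildcard atom `*`
  (variable-composition substances cannot be assigned a structure);
* parse and canonicalize through Open Babel (this fixes kekulization,
  removes explicit hydrogens and normalizes triple-bond forms);
* neutralize +1/−1 centres where a proton shift suffices; charge-separated
  groups written as such (nitro, N-oxides) and quaternary nitrogens are left
  alone;
* clear isotope labels; strip solvent fragments, then inorganic counterions,
  then organic salt formers — each stage skipped if it would delete every
  fragment; collapse duplicate fragments (stereo-distinct fragments are not
  duplicates); neutralize what remains.

Two choices deserve justification. First, the salt list is applied in two
tiers (inorganic before organic): a one-pass rule with a global
"don't-empty" guard would keep *both* fragments of sodium acetate, because
acetate itself is a listed salt former; stripping bare counterions first
resolves such salts to the organic acid, which is the behaviour of the
reference structure pipelines used in curation practice. Second, tautomer
canonicalization is deliberately **not** applied and stereo descriptors are
retained: identity is "the structure as provided, standardized", so two
tautomeric or stereoisomeric spellings remain distinct substances.

Multi-fragment survivors (true mixtures) are retained and flagged rather
than silently dropped; downstream statistics treat them like any other
substance.

Conservation is a package invariant: every input row appears exactly once in
the standardization output, either as a parent structure or as a rejection
record with a reason (`wildcard`, `unparseable`, `standardization_failure`).

## Hit-call aggregation

Assay evidence is aggregated conservatively per substance and test type: a
substance is *negative* only if every available result is negative; a single
positive makes it *positive*, whatever the count of negatives. The
all-endpoints call applies the same rule to the pooled result list, which is
equivalent to "positive in at least one test". Records with non-binary calls
(equivocal, inconclusive) are dropped at load time with a logged count —
the aggregation rule is defined only over binary calls. Aggregation is
monotone: extra evidence can only move a call toward positive.

## Fingerprints, descriptors, scaffolds

Fingerprints are ECFP-style circular fingerprints: initial atom invariants
(atomic number, heavy-atom degree, implicit hydrogen count, formal charge,
ring membership) are iteratively hashed over sorted (bond order, neighbour)
lists for two rounds and folded to 2048 bits. Because circular-fingerprint
bit values are toolkit-specific, the package freezes its own bit semantics
with regression fixtures; all *statistics* built on the bits (Tanimoto
similarity, threshold overlap, diversity means) are toolkit-agnostic
contracts tested against brute-force oracles. Graphs are always built from
the canonical SMILES, which makes kekulization — and therefore every bit —
deterministic across runs and platforms.

The 16 descriptors are molecular weight, logP and topological polar surface
area, hydrogen-bond donor/acceptor counts (Open Babel's definitions),
heavy-atom, N, O, S and halogen (F, Cl, Br, I) counts, bridgehead atoms
(atoms with three or more ring bonds shared by two smallest-set rings that
share at least two bonds), potential stereocentres (structure-based, counted
whether or not configuration is assigned, via neighbour-branch
distinguishability under Weisfeiler–Lehman refinement — exact for acyclic
environments, conservative in symmetric rings), aromatic atoms, SSSR ring
count, the fraction of sp³ carbons, and net formal charge.

Murcko scaffolds keep ring systems and the linkers between them, drop side
chains, and retain atoms double- or triple-bonded directly to the framework
(so cyclohexanone keeps its carbonyl oxygen while acetophenone reduces to
benzene). Acyclic molecules map to the empty scaffold, which by default
counts as one scaffold class in set statistics (configurable), since a
diversity summary that silently ignores acyclic chemistry overstates ring
diversity.

## Overlap semantics

Exact overlap is symmetric in the count; similarity overlap is directional
by construction (the fraction of A within reach of B is not the fraction of
B within reach of A) and both orientations are reported. The similarity
threshold is compared with `>=` ("at least 0.75"); the comparator is
configurable. Exact matches always satisfy the similarity criterion because
self-similarity is 1. Mean pairwise Tanimoto is the mean over unordered
distinct pairs. Two all-zero fingerprints are defined as similarity 1 and an
all-zero against anything else as 0; the case does not arise in real data.

## Projections

PCA is computed on z-scored descriptors by default: the 16 descriptors mix
units (g/mol, Å², counts, fractions) and unscaled PCA is dominated by
molecular weight; a raw mode is available for sensitivity analysis, and the
explained-variance share of the first two components is reported for both
interpretations of interest. Constant columns are dropped with a warning.

Butina sphere-exclusion clustering at Tanimoto-distance cutoff 0.5 ranks
molecules by neighbour count (ties by input index), makes the best-connected
unassigned molecule a centroid, and assigns its unassigned neighbours —
deterministic and order-invariant given the tie rule.

UMAP embeds the fingerprints (Jaccard metric, fixed random state) over a
grid of `n_neighbors` × `min_dist`; every cell is scored by rank-based
trustworthiness and the argmax is selected, ties resolved toward smaller
`n_neighbors` then smaller `min_dist`. Scoring "against a clustering" is not
well defined for the standard trustworthiness statistic, which compares two
*spaces*; the package therefore scores the embedding against the fingerprint
Jaccard space by default and offers a cluster-anchored variant (distances to
Butina centroid profiles) as an alternative reference. The embedding itself
runs in a single external `python`/umap-learn process for the whole grid;
parameter search, scoring and selection are R-side and tested against a
brute-force implementation of the trustworthiness rank formula and against
an external reference value.

## The synthetic-data generator

Every pipeline stage is testable without downloading anything because the
generator builds corpora with exact, realized ground truth:

* molecules are aromatic ring-system templates (17 heterocycles, plus
  two- and three-ring assemblies linked by single bonds, ~5000 distinct
  frameworks) decorated with substituents that map one-to-one onto
  functional-group SMARTS classes (halogen, nitro, primary aromatic amine,
  carboxylic acid, ester, ring methyl, aryl ether, phenol);
* per-domain decoration probabilities plant functional-group frequency
  profiles; group draws happen once per molecule, before any
  uniqueness-collision retry, and scaffolds are resampled rather than
  groups truncated, so realized frequencies are unbiased estimates of the
  planted ones;
* sets share members with a configurable probability (planting exact
  overlaps and exclusivity counts); unused frameworks drive Murcko
  singleton rates;
* assay tables draw per-test coverage and per-result positive rates i.i.d.;
* artifact injection appends salt/solvent adducts, replaces a fraction of
  query rows with wildcard entries, and duplicates rows verbatim — with a
  manifest, so tests can assert that the standardizer rejects *exactly* the
  corrupted rows and recovers parents from salted ones.

Ground truth is *realized* bookkeeping (actual memberships, InChIs,
scaffolds, group attachments), so deterministic quantities (universe size,
per-set counts, exclusives, overlaps, endpoint sizes, uncovered scaffolds)
must be reproduced exactly by the pipeline, while planted probabilities are
recovered within binomial tolerance. Everything is a pure function of the
config seed: identical config, identical corpus.

What the generator does **not** emulate: realistic pesticide property
distributions, correlated assay calls across tests, tautomer/stereo
corruption, or activity cliffs. Passing tests therefore demonstrate the
correctness of the accounting and the statistics, not chemical realism of
the corpus.

## Problem sizes and defaults

The default test corpora use 2 query + 2 reference sets of 25–30 molecules
(~100 substances); frequency-recovery checks use 1000 molecules; the full
report round trip uses 3 query sets of 260 and 4 reference sets of 400
(~2000 unique substances), chosen as a faithful small-scale analogue of a
multi-source curation study: enough substances for stable scaffold and
similarity statistics while a complete run (generation, corruption,
standardization, merge, hit calls, descriptors, overlap, enrichment, PCA,
UMAP grid) finishes in a few minutes on a single CPU. Default thresholds
follow regulatory-conservative practice: Tanimoto at least 0.75 for
"similar", Butina cutoff 0.5, top-10 rankings, radius-2/2048-bit
fingerprints, per-test coverage probabilities shaped like the public
genotoxicity landscape (Ames-dominant, in vivo chromosomal aberration
scarce), 30% per-result positive rate.

## Numerical and degenerate-input choices

* Single-atom molecules are built directly from the SMILES token (the SDF
  round trip cannot represent them).
* Hashing uses exact double-precision integer arithmetic mod 2³¹−1; no
  platform-dependent hashing is involved.
* Empty endpoint sets (a test type with no records) are carried through
  reporting with zero counts and excluded from enrichment, where proportions
  would be undefined.
* Sets smaller than 2 report `NA` diversity; sets smaller than the
  trustworthiness neighbourhood are an error.
* All percentages in the report bundle are recomputable from their count
  columns, which the test suite asserts.

## Known limitations

* Open Babel's logP/TPSA/HBA/HBD parameterizations differ numerically from
  other toolkits' (the contracts on counts are toolkit-independent; the
  continuous descriptors are backend-defined and documented as such).
* Potential-stereocentre counting is heuristic in highly symmetric ring
  systems.
* The ~300-pattern functional-group catalogue is resolved from the installed
  Open Babel data directory; catalogue version changes move the
  retained-pattern count.
* Similarity overlap is a dense scan (blocked matrix products); for
  million-substance collections an indexed search would be preferable.
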