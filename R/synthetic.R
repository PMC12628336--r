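# Synthetic multi-source chemical collections with known ground truth.
#
# Molecules are built by decorating aromatic ring-system templates with
# substituents that map one-to-one onto functional-group SMARTS classes, so
# planted group frequencies, scaffold memberships, set overlaps and assay
# calls are all exactly known. Every random draw flows from the config seed;
# the same config reproduces the same corpus byte for byte.

# Ring-system templates. `{1}`..`{3}` mark substitution sites, all on
# aromatic carbons so that attachment-sensitive SMARTS classes (aromatic
# amine, phenol, aryl ether, ring methyl) behave identically on every
# scaffold. Ring-closure digits 1-2 only; linked-pair partners are shifted
# to 5-6.
.SCAFFOLD_TEMPLATES <- c(
  benzene       = "c1c{1}c{2}cc{3}c1",
  pyridine      = "c1c{1}c{2}nc{3}c1",
  pyrimidine    = "c1nc{1}nc{2}c1",
  pyrazine      = "c1nc{1}c{2}nc1",
  pyridazine    = "c1c{1}c{2}cnn1",
  triazine      = "c1nc{1}nc{2}n1",
  thiophene     = "c1c{1}c{2}c{3}s1",
  furan         = "c1c{1}cc{2}o1",
  pyrrole       = "c1c{1}cc{2}[nH]1",
  imidazole     = "c1nc{1}c{2}[nH]1",
  pyrazole      = "c1c{1}c{2}n[nH]1",
  thiazole      = "c1nc{1}c{2}s1",
  oxazole       = "c1nc{1}c{2}o1",
  naphthalene   = "c1cc{1}c2cc{2}cc{3}c2c1",
  quinoline     = "c1cc{1}c2nc{2}ccc2c1",
  benzimidazole = "c1cc{1}c2c(c1)nc{2}[nH]2",
  indole        = "c1cc{1}c2c(c1)c{2}c[nH]2"
)

.n_sites <- function(tmpl) {
  lengths(regmatches(tmpl, gregexpr("\\{[0-9]\\}", tmpl)))
}

.resolve_template <- function(tmpl, subs) {
  ns <- .n_sites(tmpl)
  subs <- c(subs, rep("", max(0L, ns - length(subs))))
  for (i in seq_len(ns)) {
    rep_i <- if (nzchar(subs[i])) paste0("(", subs[i], ")") else ""
    tmpl <- sub(paste0("{", i, "}"), rep_i, tmpl, fixed = TRUE)
  }
  tmpl
}

# Scaffold identifiers: a single template name or a "a+b"/"a+b+c" chain of
# ring systems linked by single bonds (each link consumes site 1 of its
# carrier). Ring-closure digits of deeper partners are shifted to avoid
# clashes.
.scaffold_smiles <- function(id, subs = character(0)) {
  parts <- strsplit(id, "+", fixed = TRUE)[[1]]
  digit_maps <- c("12", "34", "56", "78")
  bare <- NULL
  for (k in rev(seq_along(parts))) {
    tmpl <- .SCAFFOLD_TEMPLATES[[parts[k]]]
    link <- if (!is.null(bare)) paste0("-", bare) else character(0)
    if (k == 1L) return(.resolve_template(tmpl, c(link, subs)))
    bare <- chartr("12", digit_maps[k], .resolve_template(tmpl, link))
  }
}

.scaffold_free_sites <- function(id) {
  parts <- strsplit(id, "+", fixed = TRUE)[[1]]
  ns <- .n_sites(.SCAFFOLD_TEMPLATES[[parts[1]]])
  if (length(parts) > 1L) ns - 1L else ns
}

# Substituent SMILES per functional-group class. Halogen draws one of the
# four halogens at attach time.
.GROUP_SUBSTITUENTS <- list(
  halogen = c("F", "Cl", "Br", "I"),
  nitro = "[N+](=O)[O-]",
  arom_amine = "N",
  carboxylic_acid = "C(=O)O",
  ester = "C(=O)OC",
  methyl = "C",
  aryl_ether = "OC",
  phenol = "O"
)

#' Synthetic corpus configuration
#'
#' Defaults describe a compact multi-source study: a few query (pesticide-
#' like) collections and reference (genotoxicity-like) collections with 20%
#' inter-set duplication, scaffold-structured chemistry, distinct planted
#' functional-group profiles per domain, light file corruption, and six-test
#' assay tables with per-test coverage probabilities.
#'
#' @param n_query_sets,n_reference_sets number of collections per domain.
#' @param query_set_size,reference_set_size molecules per collection
#'   (recycled vectors).
#' @param overlap_fraction probability that a new set slot reuses an already
#'   generated molecule instead of creating a fresh one.
#' @param singleton_rate probability that a fresh molecule takes a
#'   never-used scaffold (driving Murcko singleton counts).
#' @param fg_frequencies list with `query` and `reference` named probability
#'   vectors over the supported functional-group classes.
#' @param salt_rate,wildcard_rate,duplicate_row_rate corruption probabilities
#'   used by [inject_artifacts()].
#' @param per_test_coverage named probabilities that a reference-domain
#'   substance has data for each genotoxicity test type.
#' @param positive_rate per-result probability of a "positive" call.
#' @param seed integer seed governing every draw.
#' @return config list of class `chemcov_synth_config`.
#' @export
synth_config <- function(n_query_sets = 3L, n_reference_sets = 4L,
                         query_set_size = 120L, reference_set_size = 150L,
                         overlap_fraction = 0.2, singleton_rate = 0.3,
                         fg_frequencies = list(
                           query = c(halogen = 0.55, nitro = 0.08,
                                     arom_amine = 0.10, carboxylic_acid = 0.15,
                                     ester = 0.20, methyl = 0.30,
                                     aryl_ether = 0.15, phenol = 0.10),
                           reference = c(halogen = 0.20, nitro = 0.25,
                                         arom_amine = 0.30,
                                         carboxylic_acid = 0.10, ester = 0.10,
                                         methyl = 0.30, aryl_ether = 0.20,
                                         phenol = 0.15)),
                         salt_rate = 0.05, wildcard_rate = 0.02,
                         duplicate_row_rate = 0.03,
                         per_test_coverage = c(ames = 0.95,
                                               invitro_mcgm = 0.17,
                                               invitro_mn = 0.07,
                                               invitro_ca = 0.19,
                                               invivo_mn = 0.07,
                                               invivo_ca = 0.03),
                         positive_rate = 0.3, seed = 42L) {
  cfg <- list(n_query_sets = n_query_sets,
              n_reference_sets = n_reference_sets,
              query_set_size = rep_len(query_set_size, n_query_sets),
              reference_set_size = rep_len(reference_set_size,
                                           n_reference_sets),
              overlap_fraction = overlap_fraction,
              singleton_rate = singleton_rate,
              fg_frequencies = fg_frequencies,
              salt_rate = salt_rate, wildcard_rate = wildcard_rate,
              duplicate_row_rate = duplicate_row_rate,
              per_test_coverage = per_test_coverage,
              positive_rate = positive_rate, seed = as.integer(seed))
  probs <- c(overlap_fraction, singleton_rate, unlist(fg_frequencies),
             salt_rate, wildcard_rate, duplicate_row_rate,
             per_test_coverage, positive_rate)
  stopifnot(all(probs >= 0 & probs <= 1))
  class(cfg) <- "chemcov_synth_config"
  cfg
}

#' Generate a synthetic multi-source corpus
#'
#' Builds the molecule universe, the per-set raw tables, the assay-result
#' table and the realized ground truth. Deterministic in `config$seed`.
#'
#' @param config from [synth_config()].
#' @return list of class `chemcov_synth_library`: `sets` (named list of raw
#'   data.frames `[smiles, dataset]`), `set_category`, `assays`
#'   (`[smiles, test_type, call, dataset]`), `molecules` (universe table) and
#'   `ground_truth` (see [ground_truth_report()]).
#' @export
generate_library <- function(config = synth_config()) {
  stopifnot(inherits(config, "chemcov_synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(config$seed)

  singles <- names(.SCAFFOLD_TEMPLATES)
  pairs <- as.vector(outer(singles, singles, function(a, b)
    paste0(a, "+", b)))
  triples <- as.vector(outer(pairs, singles, function(a, b)
    paste0(a, "+", b)))
  rare_stream <- c(sample(c(singles, pairs)), sample(triples))
  core_pool <- sample(singles, 8L)
  rare_next <- 1L

  mol <- new.env(parent = emptyenv())
  mol$tab <- list()   # inchi -> record
  mol$inchis <- character(0)
  scaffold_can_cache <- new.env(parent = emptyenv())

  scaffold_canonical <- function(id) {
    if (is.null(scaffold_can_cache[[id]])) {
      scaffold_can_cache[[id]] <- murcko_scaffold(
        ob_canonical(.scaffold_smiles(id)))
    }
    scaffold_can_cache[[id]]
  }

  new_molecule <- function(category) {
    freq <- config$fg_frequencies[[category]]
    # groups are drawn once per molecule (outside the uniqueness-retry loop)
    # so that collisions do not bias the realized group frequencies
    drawn <- names(freq)[stats::runif(length(freq)) < freq]
    # at most 3 groups fit any template; beyond that is vanishingly rare
    if (length(drawn) > 3L) drawn <- sample(drawn, 3L)
    for (attempt in seq_len(80L)) {
      # after repeated collisions fall back to an unused scaffold (keeps the
      # group marginals intact); as a last resort redraw the groups
      if (attempt > 40L) {
        drawn <- names(freq)[stats::runif(length(freq)) < freq]
        if (length(drawn) > 3L) drawn <- sample(drawn, 3L)
      }
      groups <- drawn
      need <- length(groups)
      take_rare <- (stats::runif(1) < config$singleton_rate ||
                      attempt > 10L) && rare_next <= length(rare_stream)
      sid <- NULL
      if (take_rare &&
            .scaffold_free_sites(rare_stream[[rare_next]]) >= need) {
        sid <- rare_stream[[rare_next]]
        rare_next <<- rare_next + 1L
      }
      if (is.null(sid)) {
        pool <- core_pool[vapply(core_pool, .scaffold_free_sites,
                                 integer(1)) >= need]
        if (!length(pool)) {
          pool <- singles[vapply(singles, .scaffold_free_sites,
                                 integer(1)) >= need]
        }
        sid <- sample(pool, 1L)
      }
      nsites <- .scaffold_free_sites(sid)
      subs <- vapply(groups, function(g) {
        opts <- .GROUP_SUBSTITUENTS[[g]]
        if (length(opts) > 1L) sample(opts, 1L) else opts
      }, character(1))
      placed <- character(nsites)
      if (length(subs)) {
        placed[sample.int(nsites, length(subs))] <- unname(subs)
      }
      smi <- .scaffold_smiles(sid, placed)
      can <- ob_canonical(smi)
      inchi <- ob_inchi(can)
      if (is.na(can) || is.na(inchi) || inchi %in% mol$inchis) next
      rec <- list(inchi = inchi, smiles = smi, canonical_smiles = can,
                  scaffold_id = sid, scaffold = scaffold_canonical(sid),
                  groups = names(subs), category = category)
      mol$tab[[inchi]] <- rec
      mol$inchis <- c(mol$inchis, inchi)
      return(inchi)
    }
    stop("failed to assemble a fresh unique molecule after 80 attempts")
  }

  sets <- list()
  set_category <- character(0)
  specs <- rbind(
    data.frame(name = sprintf("query%02d", seq_len(config$n_query_sets)),
               category = "query", size = config$query_set_size),
    data.frame(name = sprintf("ref%02d", seq_len(config$n_reference_sets)),
               category = "reference", size = config$reference_set_size))
  for (r in seq_len(nrow(specs))) {
    cat_r <- specs$category[r]
    members <- character(0)
    for (slot in seq_len(specs$size[r])) {
      reused <- FALSE
      if (stats::runif(1) < config$overlap_fraction &&
            length(mol$inchis) > length(members)) {
        cand <- setdiff(mol$inchis, members)
        if (length(cand)) {
          members <- c(members, sample(cand, 1L))
          reused <- TRUE
        }
      }
      if (!reused) members <- c(members, new_molecule(cat_r))
    }
    sets[[specs$name[r]]] <- members
    set_category[specs$name[r]] <- cat_r
  }

  molecules <- do.call(rbind, lapply(mol$tab, function(rec) {
    data.frame(inchi = rec$inchi, smiles = rec$smiles,
               canonical_smiles = rec$canonical_smiles,
               scaffold_id = rec$scaffold_id, scaffold = rec$scaffold,
               groups = paste(rec$groups, collapse = ";"),
               category = rec$category, stringsAsFactors = FALSE)
  }))
  rownames(molecules) <- molecules$inchi

  # assay results over the reference-domain universe
  ref_universe <- sort(unique(unlist(sets[set_category == "reference"])))
  assay_rows <- list()
  for (inchi in ref_universe) {
    for (tt in names(config$per_test_coverage)) {
      if (stats::runif(1) >= config$per_test_coverage[[tt]]) next
      k <- 1L + stats::rbinom(1L, 2L, 0.25)
      calls <- ifelse(stats::runif(k) < config$positive_rate,
                      "positive", "negative")
      assay_rows[[length(assay_rows) + 1L]] <- data.frame(
        inchi = inchi, test_type = tt, call = calls,
        dataset = sample(names(sets)[set_category == "reference"], 1L),
        stringsAsFactors = FALSE)
    }
  }
  assays <- if (length(assay_rows)) do.call(rbind, assay_rows) else
    data.frame(inchi = character(0), test_type = character(0),
               call = character(0), dataset = character(0))
  assays$smiles <- molecules[assays$inchi, "smiles"]

  raw_sets <- lapply(names(sets), function(nm) {
    data.frame(smiles = molecules[sets[[nm]], "smiles"], dataset = nm,
               stringsAsFactors = FALSE)
  })
  names(raw_sets) <- names(sets)

  lib <- list(sets = raw_sets, set_members = sets,
              set_category = set_category, assays = assays,
              molecules = molecules, config = config)
  lib$ground_truth <- .build_ground_truth(lib)
  class(lib) <- "chemcov_synth_library"
  lib
}

.build_ground_truth <- function(lib) {
  sets <- lib$set_members
  cat <- lib$set_category
  molecules <- lib$molecules
  q_sets <- sets[cat == "query"]
  r_sets <- sets[cat == "reference"]
  q_universe <- sort(unique(unlist(q_sets)))
  r_universe <- sort(unique(unlist(r_sets)))
  universe <- sort(unique(c(q_universe, r_universe)))

  group_names <- names(.GROUP_SUBSTITUENTS)
  fg_presence <- function(ids) {
    m <- sapply(group_names, function(g) {
      vapply(strsplit(molecules[ids, "groups"], ";"), function(gs)
        g %in% gs, logical(1))
    })
    matrix(m, nrow = length(ids), dimnames = list(ids, group_names))
  }

  scaffolds <- stats::setNames(molecules$scaffold, molecules$inchi)
  q_scaffolds <- unique(scaffolds[q_universe])
  r_scaffolds <- unique(scaffolds[r_universe])
  uncovered <- table(scaffolds[q_universe][
    !(scaffolds[q_universe] %in% r_scaffolds)])
  uncovered <- sort(uncovered, decreasing = TRUE)

  endpoint_sizes <- integer(0)
  endpoint_calls <- list()
  if (nrow(lib$assays)) {
    for (tt in unique(lib$assays$test_type)) {
      sub <- lib$assays[lib$assays$test_type == tt, ]
      calls <- vapply(split(sub$call, sub$inchi),
                      function(x) if (any(x == "positive")) "positive"
                      else "negative", character(1))
      endpoint_sizes[[tt]] <- length(calls)
      endpoint_calls[[tt]] <- calls
    }
    all_calls <- vapply(split(lib$assays$call, lib$assays$inchi),
                        function(x) if (any(x == "positive")) "positive"
                        else "negative", character(1))
    endpoint_sizes[["all"]] <- length(all_calls)
    endpoint_calls[["all"]] <- all_calls
  }

  list(
    n_universe = length(universe),
    universe = universe,
    query_universe = q_universe,
    reference_universe = r_universe,
    sets = sets,
    set_category = cat,
    n_initial = vapply(lib$sets, function(d) length(unique(d$smiles)),
                       integer(1)),
    n_curated = lengths(sets),
    exclusive_query = exclusivity(q_sets),
    exclusive_reference = exclusivity(r_sets),
    exact_overlap_query_reference = length(intersect(q_universe, r_universe)),
    scaffolds = scaffolds,
    n_query_scaffolds = length(q_scaffolds),
    uncovered_scaffolds = uncovered,
    fg_query = fg_presence(q_universe),
    fg_reference = fg_presence(r_universe),
    endpoint_sizes = endpoint_sizes,
    endpoint_calls = endpoint_calls)
}

#' Regenerate the ground truth for a config
#'
#' Same config and seed always reproduce the identical ground truth.
#'
#' @param config from [synth_config()].
#' @return the `ground_truth` element of [generate_library()].
#' @export
ground_truth_report <- function(config = synth_config()) {
  generate_library(config)$ground_truth
}

#' Corrupt a clean synthetic corpus
#'
#' Applies the configured corruption rates to the raw set tables: a fraction
#' of rows gets a salt/solvent adduct appended, a fraction of query-set rows
#' is replaced by wildcard (`*`) entries of variable composition, and a
#' fraction of rows is duplicated verbatim. Assay tables are left intact.
#' Returns the corrupted library, a corruption manifest, and the ground
#' truth recomputed for the post-corruption memberships (wildcarded rows
#' drop out of their set).
#'
#' @param lib from [generate_library()].
#' @param config corruption rates; defaults to `lib$config`.
#' @return modified `chemcov_synth_library` with `manifest` attached.
#' @export
inject_artifacts <- function(lib, config = lib$config) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(config$seed + 1L)
  adducts <- c("Cl", "[Na+]", "OS(O)(=O)=O", "CC(O)=O", "O", "CCO")
  manifest <- list()
  for (nm in names(lib$sets)) {
    df <- lib$sets[[nm]]
    n <- nrow(df)
    u <- stats::runif(n)
    wild <- if (lib$set_category[[nm]] == "query") {
      which(u < config$wildcard_rate)
    } else integer(0)
    salt <- setdiff(which(u < config$wildcard_rate + config$salt_rate), wild)
    for (i in salt) {
      df$smiles[i] <- paste0(df$smiles[i], ".", sample(adducts, 1L))
      manifest[[length(manifest) + 1L]] <- data.frame(
        dataset = nm, row = i, type = "salt", stringsAsFactors = FALSE)
    }
    if (length(wild)) {
      removed <- lib$set_members[[nm]][wild]
      for (i in wild) {
        df$smiles[i] <- paste0("*C", i)
        manifest[[length(manifest) + 1L]] <- data.frame(
          dataset = nm, row = i, type = "wildcard", stringsAsFactors = FALSE)
      }
      lib$set_members[[nm]] <- setdiff(lib$set_members[[nm]], removed)
    }
    dup_pool <- setdiff(seq_len(n), wild)
    ndup <- stats::rbinom(1L, length(dup_pool), config$duplicate_row_rate)
    if (ndup > 0L) {
      dups <- sample(dup_pool, ndup)
      df <- rbind(df, df[dups, , drop = FALSE])
      for (i in dups) {
        manifest[[length(manifest) + 1L]] <- data.frame(
          dataset = nm, row = i, type = "duplicate", stringsAsFactors = FALSE)
      }
    }
    rownames(df) <- NULL
    lib$sets[[nm]] <- df
  }
  lib$manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(dataset = character(0), row = integer(0),
               type = character(0))
  lib$ground_truth <- .build_ground_truth(lib)
  lib
}

#' Write a synthetic corpus to disk
#'
#' Emits the CSV dialects the pipeline consumes: one `sets/<name>.csv` per
#' collection, `assays.csv`, and `ground_truth.json` with the headline
#' realized statistics.
#'
#' @param lib from [generate_library()] / [inject_artifacts()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_synthetic_corpus <- function(lib, dir) {
  dir.create(file.path(dir, "sets"), recursive = TRUE, showWarnings = FALSE)
  for (nm in names(lib$sets)) {
    utils::write.csv(lib$sets[[nm]], file.path(dir, "sets",
                                               paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(lib$assays[, c("smiles", "test_type", "call", "dataset")],
                   file.path(dir, "assays.csv"), row.names = FALSE)
  gt <- lib$ground_truth
  jsonlite::write_json(list(
    n_universe = gt$n_universe,
    n_initial = as.list(gt$n_initial),
    n_curated = as.list(gt$n_curated),
    exclusive_query = as.list(gt$exclusive_query),
    exclusive_reference = as.list(gt$exclusive_reference),
    exact_overlap_query_reference = gt$exact_overlap_query_reference,
    n_query_scaffolds = gt$n_query_scaffolds,
    uncovered_scaffolds = as.list(gt$uncovered_scaffolds),
    endpoint_sizes = as.list(gt$endpoint_sizes),
    seed = lib$config$seed), file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE)
  invisible(dir)
}
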