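# End-to-end orchestration: standardize -> merge -> hitcall -> descriptors ->
# overlap/scaffolds -> functional groups -> projections, with a report bundle
# mirroring the per-set, per-reference-set and per-endpoint summary tables.

#' Assemble a pipeline run configuration
#'
#' @param datasets data.frame or list of lists with `path`, `name`,
#'   `category` (`"pesticide"`/query vs `"genotoxicity"`/reference).
#' @param assays optional path to an assay CSV `[smiles, test_type, call,
#'   dataset]`.
#' @param out_dir output directory for the report bundle.
#' @param tanimoto_threshold similarity-overlap threshold (default 0.75,
#'   compared with `>=`).
#' @param butina_cutoff Tanimoto-distance cutoff for Butina clustering.
#' @param top_k list length for scaffold-gap and enrichment rankings.
#' @param fp_radius,fp_bits fingerprint spec (radius 2, 2048 bits).
#' @param pca_scale z-score descriptors before PCA (default TRUE).
#' @param fg_catalogue path to a SMARTS catalogue; default is the compact
#'   catalogue shipped with the package; see [default_fg_catalogue_path()]
#'   for the full Open Babel list.
#' @param umap FALSE (skip), or a list with optional `n_neighbors`,
#'   `min_dist` grids, `k`, `max_n` (subsample cap).
#' @param smiles_col SMILES column name in the dataset files.
#' @param seed seed for every stochastic stage.
#' @return config list of class `chemcov_run_config`.
#' @export
run_config <- function(datasets, assays = NULL, out_dir = tempfile("chemcov"),
                       tanimoto_threshold = 0.75, butina_cutoff = 0.5,
                       top_k = 10L, fp_radius = 2L, fp_bits = 2048L,
                       pca_scale = TRUE,
                       fg_catalogue = system.file("extdata",
                                                  "fg_catalogue_mini.txt",
                                                  package = "chemcov"),
                       umap = FALSE, smiles_col = "smiles", seed = 42L) {
  if (is.data.frame(datasets)) {
    datasets <- lapply(seq_len(nrow(datasets)), function(i)
      as.list(datasets[i, ]))
  }
  stopifnot(tanimoto_threshold >= 0, tanimoto_threshold <= 1,
            butina_cutoff >= 0, butina_cutoff <= 1, top_k >= 1)
  cfg <- list(datasets = datasets, assays = assays, out_dir = out_dir,
              tanimoto_threshold = tanimoto_threshold,
              butina_cutoff = butina_cutoff, top_k = as.integer(top_k),
              fp_radius = as.integer(fp_radius),
              fp_bits = as.integer(fp_bits), pca_scale = pca_scale,
              fg_catalogue = fg_catalogue, umap = umap,
              smiles_col = smiles_col, seed = as.integer(seed))
  class(cfg) <- "chemcov_run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return `chemcov_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

.category_side <- function(x) {
  ifelse(x %in% c("pesticide", "query"), "query", "reference")
}

.set_summary_row <- function(name, ids, n_initial, n_exclusive, fps,
                             scaffolds) {
  st <- scaffold_stats(ids, scaffolds)
  data.frame(
    dataset = name, n_initial = n_initial, n_curated = length(ids),
    n_exclusive = n_exclusive, n_scaffolds = st$n_scaffolds,
    mean_per_scaffold = st$mean_per_scaffold,
    sd_per_scaffold = st$sd_per_scaffold,
    n_singletons = st$n_singletons,
    singleton_fraction = st$singleton_fraction,
    mean_pairwise_tanimoto = mean_pairwise_tanimoto(ids, fps),
    stringsAsFactors = FALSE)
}

#' Run the full coverage pipeline
#'
#' Executes every stage on the configured datasets and writes the report
#' bundle (`table_1.csv` per-query-set, `table_2.csv` per-reference-set,
#' `table_3.csv` per-endpoint, `table_4.csv` descriptor means/SDs,
#' `scaffold_gaps.csv`, `fg_enrichment.csv`, `coords_pca.csv`, optional
#' `coords_umap.csv`, `standardization.csv`, and `manifest.json` recording
#' seed, thresholds and stage counters).
#'
#' @param config from [run_config()] / [read_run_config()].
#' @param verbose print stage progress.
#' @return invisible list with every table plus the intermediate objects
#'   (`universe`, `fingerprints`, `scaffolds`, `descriptors`, `endpoints`).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "chemcov_run_config"))
  say <- function(...) if (verbose) message("[chemcov] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  say("loading ", length(config$datasets), " datasets")
  raws <- lapply(config$datasets, function(d) {
    load_dataset(d$path, d$name, d$category, smiles_col = config$smiles_col)
  })
  n_initial <- vapply(raws, attr, integer(1), "n_initial")
  names(n_initial) <- vapply(raws, function(r) r$dataset[1], character(1))
  entries <- do.call(rbind, raws)

  say("standardizing ", nrow(entries), " rows")
  std <- standardize_table(entries[, c("smiles", "dataset", "row_id")])
  std$category <- entries$category
  stopifnot(nrow(std) == nrow(entries))  # conservation
  universe <- merge_universe(std)
  sets <- substance_sets(std)
  side <- .category_side(entries$category[match(names(sets),
                                                entries$dataset)])
  q_sets <- sets[side == "query"]
  r_sets <- sets[side == "reference"]
  q_universe <- sort(unique(unlist(q_sets)))
  r_universe <- sort(unique(unlist(r_sets)))

  say("universe: ", nrow(universe), " substances (",
      length(q_universe), " query, ", length(r_universe), " reference)")

  smiles_of <- stats::setNames(universe$canonical_smiles, universe$inchi)

  say("fingerprints, scaffolds, descriptors")
  fps <- morgan_fp(smiles_of, radius = config$fp_radius,
                   n_bits = config$fp_bits)
  rownames(fps) <- universe$inchi
  scaffolds <- stats::setNames(murcko_scaffold(smiles_of), universe$inchi)
  desc <- physchem_descriptors(smiles_of)
  rownames(desc) <- universe$inchi

  # ---- endpoints from assay records ---------------------------------------
  endpoints <- NULL
  if (!is.null(config$assays)) {
    say("aggregating assay calls")
    adf <- utils::read.csv(config$assays, stringsAsFactors = FALSE)
    key <- unique(adf$smiles)
    kstd <- standardize_table(data.frame(smiles = key, dataset = "assay"))
    imap <- stats::setNames(kstd$inchi, key)
    adf$inchi <- imap[adf$smiles]
    adf <- adf[!is.na(adf$inchi), ]
    results <- load_assay_results(adf)
    endpoints <- build_endpoint_sets(results)
  }

  # ---- tables 1 and 2 ------------------------------------------------------
  say("per-set summaries")
  excl_q <- exclusivity(q_sets)
  excl_r <- exclusivity(r_sets)
  table_1 <- do.call(rbind, c(
    lapply(names(q_sets), function(nm) .set_summary_row(
      nm, q_sets[[nm]], n_initial[[nm]], excl_q[[nm]], fps, scaffolds)),
    list(.set_summary_row("total", q_universe, NA_integer_, NA_integer_,
                          fps, scaffolds))))

  table_2 <- do.call(rbind, c(
    lapply(names(r_sets), function(nm) {
      row <- .set_summary_row(nm, r_sets[[nm]], n_initial[[nm]],
                              excl_r[[nm]], fps, scaffolds)
      cov <- coverage_report(r_sets[[nm]], q_universe, fps,
                             set_a = nm, set_b = "query_total",
                             threshold = config$tanimoto_threshold)
      cbind(row, cov[, c("exact_overlap", "exact_fraction",
                         "similarity_overlap", "similarity_fraction")])
    }),
    if (length(r_sets)) list({
      row <- .set_summary_row("total", r_universe, NA_integer_, NA_integer_,
                              fps, scaffolds)
      cov <- coverage_report(r_universe, q_universe, fps,
                             set_a = "total", set_b = "query_total",
                             threshold = config$tanimoto_threshold)
      cbind(row, cov[, c("exact_overlap", "exact_fraction",
                         "similarity_overlap", "similarity_fraction")])
    })))

  # ---- table 3: endpoint summaries ----------------------------------------
  table_3 <- NULL
  endpoint_ids <- list()
  if (!is.null(endpoints)) {
    say("endpoint summaries")
    endpoint_ids <- lapply(endpoints, `[[`, "members")
    ep_excl <- exclusivity(endpoint_ids[names(endpoint_ids) != "all"])
    rows <- lapply(names(endpoints), function(nm) {
      ep <- endpoints[[nm]]
      ids <- ep$members
      row <- .set_summary_row(nm, ids, NA_integer_,
                              if (nm %in% names(ep_excl)) ep_excl[[nm]]
                              else NA_integer_, fps, scaffolds)
      cov <- coverage_report(ids, q_universe, fps, set_a = nm,
                             set_b = "query_total",
                             threshold = config$tanimoto_threshold)
      ro <- endpoint_readouts(ep)
      cbind(row, cov[, c("exact_overlap", "exact_fraction",
                         "similarity_overlap", "similarity_fraction")],
            data.frame(n_positive = ro[["positive"]],
                       n_negative = ro[["negative"]]))
    })
    q_row <- .set_summary_row("query_total", q_universe, NA_integer_,
                              length(setdiff(q_universe, r_universe)),
                              fps, scaffolds)
    q_cov <- coverage_report(q_universe, q_universe, fps,
                             set_a = "query_total", set_b = "query_total",
                             threshold = config$tanimoto_threshold)
    rows[[length(rows) + 1L]] <- cbind(
      q_row, q_cov[, c("exact_overlap", "exact_fraction",
                       "similarity_overlap", "similarity_fraction")],
      data.frame(n_positive = NA_integer_, n_negative = NA_integer_))
    table_3 <- do.call(rbind, rows)
  }

  # ---- table 4: descriptor means/SDs --------------------------------------
  say("descriptor summaries")
  desc_sets <- c(list(query_total = q_universe), endpoint_ids)
  table_4 <- do.call(rbind, lapply(names(desc_sets), function(nm) {
    ids <- intersect(desc_sets[[nm]], rownames(desc))
    d <- desc[ids, , drop = FALSE]
    d <- d[stats::complete.cases(d), , drop = FALSE]
    mu <- colMeans(d)
    sdv <- apply(d, 2, stats::sd)
    out <- data.frame(dataset = nm, n = nrow(d), stringsAsFactors = FALSE)
    for (v in names(mu)) {
      out[[paste0(v, "_mean")]] <- mu[[v]]
      out[[paste0(v, "_sd")]] <- sdv[[v]]
    }
    out
  }))

  # ---- scaffold gaps -------------------------------------------------------
  refs_for_gaps <- if (length(endpoint_ids)) {
    endpoint_ids[names(endpoint_ids) != "all"]
  } else r_sets
  gaps <- missing_scaffolds(q_universe, refs_for_gaps, scaffolds)
  scaffold_gaps <- utils::head(gaps, config$top_k)

  # ---- functional groups ---------------------------------------------------
  say("functional groups")
  catalogue <- read_fg_catalogue(config$fg_catalogue)
  fg_sets <- c(list(query_total = q_universe),
               if (length(endpoint_ids)) endpoint_ids else
                 list(reference_total = r_universe))
  fg_sets <- fg_sets[lengths(fg_sets) > 0L]  # empty endpoints carry no data
  presence <- lapply(fg_sets, function(ids)
    match_functional_groups(smiles_of[ids], catalogue))
  retained <- filter_patterns(presence)
  fg_rows <- list()
  for (nm in setdiff(names(fg_sets), "query_total")) {
    rows <- proportion_difference(presence$query_total, presence[[nm]],
                                  groups = retained$retained)
    rows <- cbind(data.frame(reference_set = nm), rows)
    fg_rows[[nm]] <- rows
  }
  fg_enrichment <- do.call(rbind, fg_rows)
  rownames(fg_enrichment) <- NULL

  # ---- projections ---------------------------------------------------------
  say("PCA")
  ok <- rownames(desc)[stats::complete.cases(desc)]
  pca <- pca_project(desc[ok, , drop = FALSE], scale. = config$pca_scale)
  coords_pca <- data.frame(inchi = ok, x = pca$coords[, 1],
                           y = pca$coords[, 2],
                           in_query = ok %in% q_universe,
                           in_reference = ok %in% r_universe,
                           stringsAsFactors = FALSE)

  coords_umap <- NULL
  umap_sel <- NULL
  if (!isFALSE(config$umap)) {
    say("UMAP grid search")
    u <- config$umap
    ids <- rownames(fps)
    max_n <- if (!is.null(u$max_n)) u$max_n else 1000L
    if (length(ids) > max_n) {
      set.seed(config$seed)
      ids <- sort(sample(ids, max_n))
    }
    gs <- umap_grid_search(
      fps[ids, , drop = FALSE],
      n_neighbors = if (!is.null(u$n_neighbors)) u$n_neighbors else
        c(2L, 3L, 5L, 10L, 15L, 30L),
      min_dist = if (!is.null(u$min_dist)) u$min_dist else
        c(0, 0.01, 0.1, 0.25, 0.5),
      k = if (!is.null(u$k)) u$k else 5L,
      seed = config$seed)
    umap_sel <- gs
    coords_umap <- data.frame(inchi = ids, x = gs$best$coords[, 1],
                              y = gs$best$coords[, 2],
                              in_query = ids %in% q_universe,
                              in_reference = ids %in% r_universe,
                              stringsAsFactors = FALSE)
  }

  # ---- write bundle --------------------------------------------------------
  say("writing bundle to ", config$out_dir)
  wr <- function(df, name) {
    if (!is.null(df)) utils::write.csv(df, file.path(config$out_dir, name),
                                       row.names = FALSE)
  }
  wr(std, "standardization.csv")
  wr(universe, "universe.csv")
  wr(table_1, "table_1.csv")
  wr(table_2, "table_2.csv")
  wr(table_3, "table_3.csv")
  wr(table_4, "table_4.csv")
  wr(scaffold_gaps, "scaffold_gaps.csv")
  wr(fg_enrichment, "fg_enrichment.csv")
  wr(coords_pca, "coords_pca.csv")
  wr(coords_umap, "coords_umap.csv")
  manifest <- list(
    seed = config$seed,
    tanimoto_threshold = config$tanimoto_threshold,
    butina_cutoff = config$butina_cutoff,
    fingerprint = list(radius = config$fp_radius, n_bits = config$fp_bits),
    pca_scale = config$pca_scale,
    pca_explained_variance_pc1_pc2 = sum(pca$explained_variance[1:2]),
    umap_selected = if (!is.null(umap_sel)) list(
      n_neighbors = umap_sel$best$n_neighbors,
      min_dist = umap_sel$best$min_dist,
      score = umap_sel$best$score) else NULL,
    counters = list(
      rows_in = nrow(entries),
      rows_standardized = sum(std$status == "standardized"),
      rows_rejected = sum(std$status == "rejected"),
      reject_reasons = as.list(table(std$reject_reason[
        std$status == "rejected"])),
      n_universe = nrow(universe),
      n_query = length(q_universe),
      n_reference = length(r_universe),
      fg_patterns_total = nrow(catalogue),
      fg_patterns_retained = length(retained$retained)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(
    standardization = std, universe = universe, sets = sets,
    set_side = side, q_universe = q_universe, r_universe = r_universe,
    fingerprints = fps, scaffolds = scaffolds, descriptors = desc,
    endpoints = endpoints, table_1 = table_1, table_2 = table_2,
    table_3 = table_3, table_4 = table_4, scaffold_gaps = scaffold_gaps,
    all_scaffold_gaps = gaps, fg_enrichment = fg_enrichment,
    fg_retained = retained, pca = pca, coords_pca = coords_pca,
    coords_umap = coords_umap, umap = umap_sel, manifest = manifest))
}
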