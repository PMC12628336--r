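# Low-dimensional views of the chemical space: PCA of the physicochemical
# descriptors, Butina sphere-exclusion clustering of fingerprints, rank-based
# trustworthiness, and a UMAP grid search scored by trustworthiness.

#' PCA projection of a descriptor matrix
#'
#' Per-column z-scoring by default (the descriptors mix units; unscaled PCA
#' is dominated by molecular weight). Constant columns are dropped with a
#' warning under scaling.
#'
#' @param X numeric matrix/data.frame (rows = substances, complete cases
#'   only).
#' @param scale. z-score columns first (default TRUE).
#' @param k number of components to return as coordinates (default 2).
#' @return list with `coords` (n x k), `loadings` (descriptor x component),
#'   `explained_variance` (fractions, all components), `dropped_columns`.
#' @export
pca_project <- function(X, scale. = TRUE, k = 2L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("pca_project: X has missing values; exclude flagged rows")
  dropped <- character(0)
  if (scale.) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      dropped <- colnames(X)[sds == 0]
      warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
      X <- X[, sds > 0, drop = FALSE]
    }
  }
  p <- stats::prcomp(X, center = TRUE, scale. = scale.)
  ev <- p$sdev^2 / sum(p$sdev^2)
  k <- min(k, ncol(p$x))
  list(coords = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation,
       explained_variance = ev,
       dropped_columns = dropped)
}

#' Butina sphere-exclusion clustering
#'
#' Leader clustering at a Tanimoto-distance cutoff: molecules are ranked by
#' neighbour count (ties by input index), the best-connected unassigned
#' molecule becomes a cluster centroid and claims its unassigned neighbours,
#' until every molecule is labeled. Deterministic and invariant to input row
#' order up to the stated tie rule.
#'
#' @param fingerprints logical fingerprint matrix.
#' @param cutoff Tanimoto-distance cutoff (default 0.5): neighbours are pairs
#'   with `1 - tanimoto <= cutoff`.
#' @param sims optional precomputed similarity matrix (overrides
#'   `fingerprints`).
#' @return list with `labels` (integer cluster ids, contiguous from 0, named
#'   by rownames), `centroids` (row indices) and `cutoff`.
#' @export
butina_cluster <- function(fingerprints, cutoff = 0.5, sims = NULL) {
  if (is.null(sims)) sims <- tanimoto_matrix(fingerprints)
  n <- nrow(sims)
  neigh <- (1 - sims) <= cutoff
  diag(neigh) <- FALSE
  counts <- rowSums(neigh)
  order_idx <- order(-counts, seq_len(n))
  labels <- rep(NA_integer_, n)
  centroids <- integer(0)
  cl <- -1L
  for (i in order_idx) {
    if (!is.na(labels[i])) next
    cl <- cl + 1L
    labels[i] <- cl
    centroids <- c(centroids, i)
    members <- which(neigh[i, ] & is.na(labels))
    labels[members] <- cl
  }
  names(labels) <- rownames(sims)
  list(labels = labels, centroids = centroids, cutoff = cutoff)
}

#' Rank-based trustworthiness of an embedding
#'
#' The standard neighbourhood-preservation score: for each point, the k
#' nearest neighbours in the embedding are checked against the ranks they
#' hold in the original space, and intruders are penalized by how far down
#' the original ranking they sit. 1 means every embedded neighbourhood is
#' trustworthy.
#'
#' @param d_original,d_embedded full distance matrices over the same points
#'   (use [tanimoto_matrix()] complements for fingerprint spaces).
#' @param k neighbourhood size; must satisfy `k < n / 2` for the standard
#'   normalization.
#' @return numeric scalar in `[0, 1]`.
#' @export
trustworthiness <- function(d_original, d_embedded, k = 5L) {
  n <- nrow(d_original)
  if (k >= n) stop("trustworthiness: k must be smaller than n")
  penalty <- 0
  for (i in seq_len(n)) {
    rank_orig <- order(d_original[i, -i])
    ranks <- integer(n - 1L)
    ranks[rank_orig] <- seq_len(n - 1L)
    nn_emb <- order(d_embedded[i, -i])[seq_len(k)]
    r <- ranks[nn_emb]
    penalty <- penalty + sum(pmax(r - k, 0L))
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * penalty
}

# Jaccard distance matrix of a logical fingerprint matrix.
jaccard_dist <- function(fingerprints) 1 - tanimoto_matrix(fingerprints)

#' UMAP embeddings over a parameter grid
#'
#' Computes 2-d UMAP embeddings of a binary fingerprint matrix for every
#' (n_neighbors, min_dist) grid cell in a single external `python` +
#' umap-learn run (Jaccard metric by default, fixed `random_state`). Cells
#' that fail to embed are returned as `NULL`.
#'
#' @param fingerprints logical fingerprint matrix.
#' @param n_neighbors,min_dist grid axes.
#' @param metric distance metric passed to umap-learn (default "jaccard").
#' @param seed random state.
#' @param python python executable (default "python").
#' @return list of cells; each has `n_neighbors`, `min_dist` and `coords`
#'   (n x 2 matrix) or `NULL` coords on failure.
#' @export
umap_embed_grid <- function(fingerprints,
                            n_neighbors = c(2L, 3L, 5L, 10L, 15L, 30L),
                            min_dist = c(0, 0.01, 0.1, 0.25, 0.5),
                            metric = "jaccard", seed = 42L,
                            python = "python") {
  script <- system.file("python", "umap_grid.py", package = "chemcov")
  td <- tempfile("umapgrid")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  xpath <- file.path(td, "X.csv")
  utils::write.table(matrix(as.integer(fingerprints),
                            nrow = nrow(fingerprints)),
                     xpath, sep = ",", row.names = FALSE, col.names = FALSE)
  grid <- expand.grid(n_neighbors = n_neighbors, min_dist = min_dist,
                      KEEP.OUT.ATTRS = FALSE)
  gpath <- file.path(td, "grid.csv")
  utils::write.table(grid, gpath, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  status <- system2(python, c(script, xpath, gpath, td, metric,
                              as.character(seed)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("umap grid run failed (python exit ", status, ")")
  lapply(seq_len(nrow(grid)), function(g) {
    f <- file.path(td, paste0("emb_", g - 1L, ".csv"))
    coords <- if (file.exists(f)) {
      as.matrix(utils::read.table(f, sep = ","))
    } else NULL
    if (!is.null(coords)) {
      dimnames(coords) <- list(rownames(fingerprints), c("x", "y"))
    }
    list(n_neighbors = grid$n_neighbors[g], min_dist = grid$min_dist[g],
         coords = coords)
  })
}

#' UMAP parameter grid search scored by trustworthiness
#'
#' Embeds every grid cell, scores each embedding by rank-based
#' trustworthiness, and returns the argmax cell (ties resolved toward
#' smaller n_neighbors, then smaller min_dist). Two scoring references are
#' supported: the fingerprint Jaccard space itself (default), or the medoid
#' space of a Butina cluster labeling (each point represented by the Jaccard
#' distance to its cluster centroid profile).
#'
#' @inheritParams umap_embed_grid
#' @param k trustworthiness neighbourhood size.
#' @param reference `"fingerprint"` (default) or a labeling from
#'   [butina_cluster()] for the cluster-anchored variant.
#' @return list with `best` (`n_neighbors`, `min_dist`, `score`, `coords`)
#'   and `scores` (data.frame over the evaluated grid).
#' @export
umap_grid_search <- function(fingerprints,
                             n_neighbors = c(2L, 3L, 5L, 10L, 15L, 30L),
                             min_dist = c(0, 0.01, 0.1, 0.25, 0.5),
                             k = 5L, metric = "jaccard", seed = 42L,
                             reference = "fingerprint",
                             python = "python") {
  d_ref <- if (identical(reference, "fingerprint")) {
    jaccard_dist(fingerprints)
  } else {
    .medoid_space_dist(fingerprints, reference)
  }
  cells <- umap_embed_grid(fingerprints, n_neighbors = n_neighbors,
                           min_dist = min_dist, metric = metric,
                           seed = seed, python = python)
  scores <- data.frame(n_neighbors = integer(0), min_dist = numeric(0),
                       score = numeric(0))
  best <- NULL
  for (cell in cells) {
    if (is.null(cell$coords)) {
      message("umap cell (", cell$n_neighbors, ", ", cell$min_dist,
              ") failed; excluded")
      next
    }
    d_emb <- as.matrix(stats::dist(cell$coords))
    s <- trustworthiness(d_ref, d_emb, k = k)
    scores <- rbind(scores, data.frame(n_neighbors = cell$n_neighbors,
                                       min_dist = cell$min_dist, score = s))
    better <- is.null(best) || s > best$score ||
      (s == best$score && (cell$n_neighbors < best$n_neighbors ||
                             (cell$n_neighbors == best$n_neighbors &&
                                cell$min_dist < best$min_dist)))
    if (better) {
      best <- list(n_neighbors = cell$n_neighbors, min_dist = cell$min_dist,
                   score = s, coords = cell$coords)
    }
  }
  if (is.null(best)) stop("umap_grid_search: every grid cell failed")
  list(best = best, scores = scores)
}

# Distance to each cluster-centroid fingerprint as an alternative reference
# space for trustworthiness scoring.
.medoid_space_dist <- function(fingerprints, labeling) {
  centroids <- fingerprints[labeling$centroids, , drop = FALSE]
  profile <- 1 - tanimoto_matrix(fingerprints, centroids)
  as.matrix(stats::dist(profile))
}
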