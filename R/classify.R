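#' Feature tables of flattened topological summaries
#'
#' One row per trajectory frame: trajectory id, frame index, class label, and
#' a flattened summary vector.  Matrices (GCCD) are flattened row-major over
#' epsilon then rho, and the flattening order is recorded.
#'
#' @param features numeric matrix, one row per item.
#' @param info data frame with columns `trajectory_id`, `frame_index`,
#'   `label`, aligned with `features` rows.
#' @param summary_kind `"gccd"`, `"gauss_betti_1d"`, or `"gauss_betti_012"`.
#' @return a `feature_table` object.
#' @export
feature_table <- function(features, info,
                          summary_kind = c("gccd", "gauss_betti_1d",
                                           "gauss_betti_012")) {
  summary_kind <- match.arg(summary_kind)
  features <- as.matrix(features)
  stopifnot(nrow(features) == nrow(info),
            all(c("trajectory_id", "frame_index", "label") %in% names(info)))
  structure(list(features = features, info = as.data.frame(info),
                 summary_kind = summary_kind,
                 flattening = "row-major over epsilon then rho"),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table (%s): %d items x %d features\n", x$summary_kind,
              nrow(x$features), ncol(x$features)))
  invisible(x)
}

# flatten a crocker/gccd matrix row-major over epsilon then rho
flatten_summary <- function(m) as.vector(t(unclass(m)))

#' Summarize labeled trajectories into per-sigma feature tables
#'
#' Barcodes are computed once per frame (they do not depend on sigma) and
#' vectorized at every requested sigma.
#'
#' @param frame_sets list of [trajectory_frames()] objects.
#' @param grid an [epsilon_grid()].
#' @param sigmas numeric vector of smoothing parameters.
#' @param summary_kind `"gccd"` (dimension-1 GCCD matrix),
#'   `"gauss_betti_1d"` (classical-Rips dimension-1 Gaussian Betti vector) or
#'   `"gauss_betti_012"` (normalized concatenated dimensions 0, 1, 2).
#' @param scheme a [residue_scheme()]; default from the first frame.
#' @param cutoff death cap; default `max(grid) + 0.001`.
#' @return named list (one element per sigma, names `as.character(sigmas)`)
#'   of [feature_table()] objects.
#' @export
summarize_frames <- function(frame_sets, grid, sigmas,
                             summary_kind = c("gccd", "gauss_betti_1d",
                                              "gauss_betti_012"),
                             scheme = NULL, cutoff = max(grid) + 0.001) {
  summary_kind <- match.arg(summary_kind)
  if (is.null(scheme)) scheme <- scheme_for_cloud(frame_sets[[1]]$frames[[1]])
  M <- choose_M(cutoff)
  rows <- list()
  info <- list()
  for (ts in frame_sets) {
    for (i in seq_along(ts$frames)) {
      cloud <- ts$frames[[i]]
      if (summary_kind == "gccd") {
        barcodes <- lapply(seq_len(scheme$inter_chain_value), function(rho) {
          D <- build_dissimilarity(cloud, rho, M, scheme)
          rips_barcode(D, dims = 1L, cutoff = cutoff)[["1"]]
        })
        per_sigma <- lapply(sigmas, function(sg) {
          cols <- vapply(barcodes, function(bc) {
            gaussian_betti_number(bc, as.numeric(grid), sg)
          }, numeric(length(grid)))
          if (ncol(cols) > 1L) {
            cols[, -1L] <- cols[, -1L, drop = FALSE] -
              cols[, -ncol(cols), drop = FALSE]
          }
          flatten_summary(cols)
        })
      } else if (summary_kind == "gauss_betti_1d") {
        de <- as.matrix(stats::dist(cloud_xyz(cloud)))
        bc <- rips_barcode(de, dims = 1L, cutoff = cutoff)[["1"]]
        per_sigma <- lapply(sigmas, function(sg) {
          gaussian_betti_number(bc, as.numeric(grid), sg)
        })
      } else {
        de <- as.matrix(stats::dist(cloud_xyz(cloud)))
        bcs <- rips_barcode(de, dims = 0:2, cutoff = cutoff)
        per_sigma <- lapply(sigmas, function(sg) {
          normalized_multidim_vector(bcs, grid, sg)
        })
      }
      rows[[length(rows) + 1L]] <- per_sigma
      info[[length(info) + 1L]] <- data.frame(
        trajectory_id = ts$trajectory_id,
        frame_index = ts$frame_indices[i],
        label = ts$label, stringsAsFactors = FALSE)
    }
  }
  info <- do.call(rbind, info)
  out <- lapply(seq_along(sigmas), function(si) {
    feature_table(do.call(rbind, lapply(rows, `[[`, si)), info, summary_kind)
  })
  names(out) <- as.character(sigmas)
  out
}

#' Pairwise Euclidean distances between summaries
#'
#' @param table a [feature_table()].
#' @return symmetric matrix of Euclidean distances with zero diagonal.
#' @export
pairwise_distances <- function(table) {
  stopifnot(inherits(table, "feature_table"), nrow(table$features) > 0)
  as.matrix(stats::dist(table$features))
}

#' k-nearest-neighbour label prediction
#'
#' Majority vote over the k nearest training summaries by Euclidean distance.
#' k must be odd (binary labels, no vote ties).  Distance ties are broken by
#' the stable training order (trajectory_id, then frame_index), so
#' predictions are reproducible.
#'
#' @param train,test [feature_table()] objects with equal feature length.
#' @param k odd neighbour count, `k <= nrow(train$features)`.
#' @param cross_dist optional precomputed test-by-train distance matrix.
#' @return character vector of predicted labels, one per test item.
#' @export
knn_predict <- function(train, test, k, cross_dist = NULL) {
  if (k %% 2 == 0) stop("k must be odd to avoid vote ties")
  if (k > nrow(train$features)) stop("k exceeds the training set size")
  if (is.null(cross_dist)) {
    if (ncol(train$features) != ncol(test$features)) {
      stop("train and test summaries have different lengths")
    }
    cross_dist <- .cross_distances(test$features, train$features)
  }
  ord_train <- order(train$info$trajectory_id, train$info$frame_index)
  labels <- train$info$label
  apply(cross_dist, 1L, function(dr) {
    nn <- order(dr[ord_train])[seq_len(k)]   # stable: ties keep sorted order
    votes <- labels[ord_train][nn]
    names(sort(table(votes), decreasing = TRUE))[1L]
  })
}

.cross_distances <- function(a, b) {
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(sq, 0))
}

#' Trajectory-level train/test and train/validation splits
#'
#' With four trajectories per class there are 16 train/test splits, each
#' holding out one (glycosylated, aglycosylated) trajectory pair; inside each
#' training set (3 + 3 trajectories) there are nine leave-one-pair-out
#' train/validation splits.  Test trajectories never enter hyperparameter
#' selection.
#'
#' @param glyco_ids,aglyco_ids trajectory ids of each class.
#' @return data frame of test pairs (`glyco`, `aglyco`).
#' @export
test_splits <- function(glyco_ids, aglyco_ids) {
  expand.grid(glyco = glyco_ids, aglyco = aglyco_ids,
              KEEP.OUT.ATTRS = FALSE)
}

#' Hyperparameter grid search over nine validation splits
#'
#' For every (sigma, k) pair, the mean validation accuracy over the nine
#' leave-one-pair-out splits of the training trajectories is computed; the
#' argmax is returned, ties broken toward the smallest sigma, then the
#' smallest k (least smoothing, fewest neighbours).
#'
#' @param tables_per_sigma named list of [feature_table()] objects, one per
#'   sigma, each covering all six training trajectories.
#' @param sigmas,ks hyperparameter grid; every k must be odd.
#' @return list with `sigma`, `k`, and the accuracy table
#'   (`data.frame(sigma, k, mean_accuracy)`).
#' @export
grid_search <- function(tables_per_sigma, sigmas, ks) {
  if (any(ks %% 2 == 0)) stop("all k values must be odd")
  missing_sig <- setdiff(as.character(sigmas), names(tables_per_sigma))
  if (length(missing_sig) > 0) {
    stop("missing summaries for sigma: ", paste(missing_sig, collapse = ", "))
  }
  info <- tables_per_sigma[[as.character(sigmas[1])]]$info
  glyco <- unique(info$trajectory_id[info$label == "glycosylated"])
  aglyco <- unique(info$trajectory_id[info$label == "aglycosylated"])
  val_pairs <- expand.grid(glyco = glyco, aglyco = aglyco,
                           KEEP.OUT.ATTRS = FALSE)
  results <- expand.grid(sigma = sigmas, k = ks, KEEP.OUT.ATTRS = FALSE)
  results$mean_accuracy <- NA_real_
  for (si in seq_along(sigmas)) {
    tab <- tables_per_sigma[[as.character(sigmas[si])]]
    accs <- matrix(NA_real_, nrow(val_pairs), length(ks))
    for (vi in seq_len(nrow(val_pairs))) {
      hold <- (tab$info$label == "glycosylated" &
                 tab$info$trajectory_id == val_pairs$glyco[vi]) |
        (tab$info$label == "aglycosylated" &
           tab$info$trajectory_id == val_pairs$aglyco[vi])
      tr <- .subset_table(tab, !hold)
      va <- .subset_table(tab, hold)
      cd <- .cross_distances(va$features, tr$features)
      for (ki in seq_along(ks)) {
        pred <- knn_predict(tr, va, ks[ki], cross_dist = cd)
        accs[vi, ki] <- mean(pred == va$info$label)
      }
    }
    for (ki in seq_along(ks)) {
      results$mean_accuracy[results$sigma == sigmas[si] &
                              results$k == ks[ki]] <- mean(accs[, ki])
    }
  }
  best <- results[order(-results$mean_accuracy, results$sigma, results$k), ]
  list(sigma = best$sigma[1L], k = best$k[1L], accuracies = results)
}

.subset_table <- function(tab, keep) {
  feature_table(tab$features[keep, , drop = FALSE],
                tab$info[keep, , drop = FALSE], tab$summary_kind)
}

#' Evaluate classification over all 16 train/test splits
#'
#' For each held-out (glycosylated, aglycosylated) trajectory pair, a grid
#' search over the remaining 3 + 3 trajectories selects (sigma, k); a k-NN
#' classifier trained on those six trajectories is then scored on the
#' held-out pair.  No test frame influences hyperparameter selection.
#'
#' @param tables_per_sigma named list of [feature_table()] objects, one per
#'   sigma, covering all 4 + 4 trajectories.
#' @param sigmas,ks hyperparameter grid.
#' @return list with `splits` (data frame: test ids, selected
#'   hyperparameters, accuracy per split) and `mean_accuracy` (grand mean
#'   over the 16 splits).
#' @export
evaluate_splits <- function(tables_per_sigma, sigmas, ks) {
  info <- tables_per_sigma[[1L]]$info
  glyco <- sort(unique(info$trajectory_id[info$label == "glycosylated"]))
  aglyco <- sort(unique(info$trajectory_id[info$label == "aglycosylated"]))
  if (length(glyco) < 2 || length(aglyco) < 2) {
    stop("need at least two trajectories per class to form train/test splits")
  }
  splits <- test_splits(glyco, aglyco)
  splits$sigma <- NA_real_
  splits$k <- NA_integer_
  splits$accuracy <- NA_real_
  for (si in seq_len(nrow(splits))) {
    is_test <- function(tab) {
      (tab$info$label == "glycosylated" &
         tab$info$trajectory_id == splits$glyco[si]) |
        (tab$info$label == "aglycosylated" &
           tab$info$trajectory_id == splits$aglyco[si])
    }
    train_tables <- lapply(tables_per_sigma, function(tab) {
      .subset_table(tab, !is_test(tab))
    })
    sel <- grid_search(train_tables, sigmas, ks)
    tab <- tables_per_sigma[[as.character(sel$sigma)]]
    tr <- .subset_table(tab, !is_test(tab))
    te <- .subset_table(tab, is_test(tab))
    pred <- knn_predict(tr, te, sel$k)
    splits$sigma[si] <- sel$sigma
    splits$k[si] <- sel$k
    splits$accuracy[si] <- mean(pred == te$info$label)
  }
  list(splits = splits, mean_accuracy = mean(splits$accuracy))
}

#' Low-dimensional embeddings of summary collections
#'
#' Metric multidimensional scaling (on the precomputed Euclidean distance
#' matrix, via classical scaling) or principal component analysis of the
#' flattened summaries.
#'
#' @param table a [feature_table()].
#' @param method `"mds"` or `"pca"`.
#' @param n_components number of output dimensions (default 2).
#' @return list with `coordinates` (items x n_components) and, for PCA,
#'   `explained_variance_ratio` of the leading components.
#' @export
embed_summaries <- function(table, method = c("mds", "pca"),
                            n_components = 2L) {
  method <- match.arg(method)
  n <- nrow(table$features)
  if (n < n_components + 1L) stop("too few items to embed")
  if (method == "mds") {
    co <- stats::cmdscale(pairwise_distances(table), k = n_components)
    list(coordinates = co)
  } else {
    pca <- stats::prcomp(table$features, center = TRUE, scale. = FALSE)
    ratio <- pca$sdev^2 / sum(pca$sdev^2)
    list(coordinates = pca$x[, seq_len(n_components), drop = FALSE],
         explained_variance_ratio = ratio[seq_len(n_components)])
  }
}
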