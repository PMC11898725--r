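#' @title K-means classification of cabbage morphology
#' @description Heads are clustered on length circumference, width
#'   circumference and weight.  Features are z-standardized before distance
#'   computation because the units are mixed (cm vs g) and weight would
#'   otherwise dominate.
#' @name morphology
NULL

.feature_cols <- c("length_circumference_cm", "width_circumference_cm", "weight_g")

.feature_matrix <- function(records) {
  if (is.matrix(records)) return(records)
  cols <- intersect(.feature_cols, names(records))
  if (length(cols) == 0) {
    cols <- names(records)[vapply(records, is.numeric, logical(1))]
    cols <- setdiff(cols, "id")
  }
  as.matrix(records[, cols, drop = FALSE])
}

.standardize <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  list(Z = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

# squared Euclidean distances from each row of Z to each row of centers
.sqdist <- function(Z, centers) {
  zz <- rowSums(Z^2)
  cc <- rowSums(centers^2)
  outer(zz, cc, "+") - 2 * Z %*% t(centers)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center
.kpp_init <- function(Z, k) {
  n <- nrow(Z)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- .sqdist(Z, Z[idx[1], , drop = FALSE])[, 1]
    for (j in 2:k) {
      p <- pmax(d2, 0)
      idx[j] <- if (sum(p) > 0) sample.int(n, 1L, prob = p) else sample.int(n, 1L)
      d2 <- pmin(d2, .sqdist(Z, Z[idx[j], , drop = FALSE])[, 1])
    }
  }
  Z[idx, , drop = FALSE]
}

# Lloyd iterations until the assignment is unchanged or the centroid shift
# drops below `tol`; empty clusters are reseeded at the farthest point.
.lloyd <- function(Z, centers, tol = 1e-8, max_iter = 200L) {
  k <- nrow(centers)
  labels <- integer(nrow(Z))
  for (it in seq_len(max_iter)) {
    D2 <- .sqdist(Z, centers)
    new_labels <- max.col(-D2, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- new_labels == j
      if (any(members)) {
        new_centers[j, ] <- colMeans(Z[members, , drop = FALSE])
      } else {
        far <- which.max(D2[cbind(seq_len(nrow(Z)), new_labels)])
        new_centers[j, ] <- Z[far, ]
        new_labels[far] <- j
      }
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    same <- identical(new_labels, labels)
    centers <- new_centers
    labels <- new_labels
    if (same || shift < tol) break
  }
  D2 <- .sqdist(Z, centers)
  sse <- sum(D2[cbind(seq_along(labels), labels)])
  list(centers = centers, labels = labels, sse = sse)
}

#' Fit K-means to morphology records
#'
#' Minimises the within-cluster sum of squared distances (Lloyd iterations,
#' k-means++ seeding, best of `n_restarts` restarts by SSE) on z-standardized
#' features.  Clusters are mapped to size classes 1..k by ascending centroid
#' weight, so class 1 is always the smallest heads.
#'
#' @param records Data frame with columns `length_circumference_cm`,
#'   `width_circumference_cm`, `weight_g` (or any numeric matrix).
#' @param k Number of clusters.
#' @param seed RNG seed for the restarts.
#' @param n_restarts Number of k-means++ restarts.
#' @return Object of class `cluster_model`: `k`, `centers` (standardized),
#'   `centers_raw` (destandardized), `labels` (cluster index per record),
#'   `classes` (size-class label per record), `sse`, `scaler`, `class_order`.
#' @export
kmeans_fit <- function(records, k, seed = 1, n_restarts = 10) {
  X <- .feature_matrix(records)
  if (nrow(X) == 0) stop("empty input", call. = FALSE)
  if (k < 1) stop("`k` must be at least 1", call. = FALSE)
  std <- .standardize(X)
  n_distinct <- nrow(unique(std$Z))
  if (k > n_distinct)
    stop("`k` exceeds the number of distinct points", call. = FALSE)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- .lloyd(std$Z, .kpp_init(std$Z, k))
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  centers_raw <- sweep(sweep(best$centers, 2, std$scale, "*"), 2, std$center, "+")
  wcol <- if ("weight_g" %in% colnames(centers_raw)) "weight_g" else ncol(centers_raw)
  class_order <- order(centers_raw[, wcol])      # cluster index in ascending weight
  class_of_cluster <- order(class_order)         # cluster -> class label
  structure(list(k = k, centers = best$centers, centers_raw = centers_raw,
                 labels = best$labels,
                 classes = class_of_cluster[best$labels],
                 sse = best$sse,
                 scaler = list(center = std$center, scale = std$scale),
                 class_order = class_of_cluster),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("K-means cluster model: k =", x$k, " SSE =", signif(x$sse, 6), "\n")
  cat("Cluster sizes (by class):",
      paste(tabulate(x$classes, x$k), collapse = " / "), "\n")
  cat("Class mean weights (g):",
      paste(signif(sort(x$centers_raw[, ncol(x$centers_raw)]), 6),
            collapse = ", "), "\n")
  invisible(x)
}

#' SSE versus number of clusters (elbow diagnostic)
#'
#' @inheritParams kmeans_fit
#' @param k_range Increasing vector of cluster counts.
#' @return Data frame with columns `k` and `sse`, SSE nonincreasing in k.
#' @export
sse_curve <- function(records, k_range, seed = 1, n_restarts = 10) {
  if (length(k_range) == 0 || any(diff(k_range) <= 0))
    stop("`k_range` must be nonempty and increasing", call. = FALSE)
  sse <- vapply(k_range, function(k)
    kmeans_fit(records, k, seed = seed, n_restarts = n_restarts)$sse, numeric(1))
  data.frame(k = k_range, sse = sse)
}

#' Mean silhouette coefficient of a labelled clustering
#'
#' Per record, s = (b - a) / max(a, b) with a the mean distance to the other
#' members of its own cluster and b the smallest mean distance to another
#' cluster.  Records in singleton clusters contribute s = 0.  Distances are
#' Euclidean on z-standardized features (set `standardize = FALSE` for raw
#' feature space).
#'
#' @inheritParams kmeans_fit
#' @param labels Integer cluster label per record.
#' @param standardize z-scale features before computing distances.
#' @return Mean silhouette, in \[-1, 1\].
#' @export
silhouette_mean <- function(records, labels, standardize = TRUE) {
  X <- .feature_matrix(records)
  n <- nrow(X)
  if (n < 2L) stop("at least two records are required", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("`labels` length mismatch", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("silhouette needs at least two clusters", call. = FALSE)
  if (standardize) X <- .standardize(X)$Z
  D <- as.matrix(dist(X))
  cl <- sort(unique(labels))
  sizes <- table(factor(labels, levels = cl))
  # mean distance from each point to each cluster (self excluded for own)
  M <- vapply(cl, function(j) rowSums(D[, labels == j, drop = FALSE]), numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- match(labels[i], cl)
    n_own <- sizes[[own]]
    if (n_own == 1L) { s[i] <- 0; next }
    a <- M[i, own] / (n_own - 1L)
    b <- min(M[i, -own] / as.numeric(sizes[-own]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the number of clusters by silhouette
#'
#' Fits K-means over `k_range`, picks the k with the highest mean
#' silhouette, and reports the SSE curve with its knee (maximum second
#' difference) as an elbow diagnostic.
#'
#' @inheritParams kmeans_fit
#' @param k_range Candidate cluster counts (each at least 2).
#' @return List with `k_opt`, `silhouette` (data frame k, silhouette),
#'   `sse` (data frame k, sse) and `knee_k` (NA when `k_range` is too short
#'   to form a second difference).
#' @export
select_k <- function(records, k_range = 2:5, seed = 1, n_restarts = 10) {
  if (any(k_range < 2)) stop("`k_range` must not go below 2", call. = FALSE)
  fits <- lapply(k_range, function(k)
    kmeans_fit(records, k, seed = seed, n_restarts = n_restarts))
  sil <- vapply(seq_along(fits), function(i)
    silhouette_mean(records, fits[[i]]$labels), numeric(1))
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  knee_k <- if (length(k_range) >= 3) {
    d2 <- diff(diff(sse))                       # curvature of the elbow plot
    k_range[which.max(d2) + 1L]
  } else NA_integer_
  list(k_opt = k_range[which.max(sil)],
       silhouette = data.frame(k = k_range, silhouette = sil),
       sse = data.frame(k = k_range, sse = sse),
       knee_k = knee_k)
}

#' Heat-balanced allocation of heads to baskets
#'
#' Each basket receives one head of each size class.  To balance metabolic
#' heat load, class-1 heads sorted by ascending weight are paired with
#' class-3 heads sorted descending, and class-2 heads are then assigned
#' descending against the ascending pair totals.
#'
#' @param model A [kmeans_fit()] model with k = 3.
#' @param records The records the model was fitted to (must carry `id`).
#' @return Data frame with columns `basket_id`, `id`, `class`, `weight_g`.
#' @export
allocate_baskets <- function(model, records) {
  stopifnot(inherits(model, "cluster_model"))
  if (model$k != 3) stop("basket allocation expects k = 3 classes", call. = FALSE)
  classes <- model$classes
  sizes <- tabulate(classes, 3)
  if (length(unique(sizes)) != 1L)
    stop("class counts must be equal for one-per-class baskets", call. = FALSE)
  n_baskets <- sizes[1]
  w <- .feature_matrix(records)[, "weight_g"]
  ids <- if (!is.null(records$id)) records$id else seq_along(classes)
  ord <- lapply(1:3, function(cl) {
    i <- which(classes == cl)
    i[order(w[i])]
  })
  i1 <- ord[[1]]                       # ascending
  i3 <- rev(ord[[3]])                  # descending
  pair_tot <- w[i1] + w[i3]
  # heaviest class-2 head joins the lightest 1+3 pair
  i2 <- rev(ord[[2]])[rank(pair_tot, ties.method = "first")]
  do.call(rbind, lapply(seq_len(n_baskets), function(b) {
    sel <- c(i1[b], i2[b], i3[b])
    data.frame(basket_id = b, id = ids[sel], class = classes[sel],
               weight_g = w[sel])
  }))
}
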