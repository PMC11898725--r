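test_that("k-means separates duplicated points exactly", {
  rec <- data.frame(length_circumference_cm = c(0, 0, 1, 1),
                    width_circumference_cm = c(0, 0, 1, 1),
                    weight_g = c(0, 0, 1, 1))
  fit <- kmeans_fit(rec, 2, seed = 1)
  expect_equal(fit$sse, 0)
  expect_equal(sort(tabulate(fit$labels, 2)), c(2, 2))
  # one-cluster SSE equals total standardized scatter, (n - 1) per feature
  expect_equal(sse_curve(rec, 1)$sse, 3 * (4 - 1))
  expect_error(kmeans_fit(rec[0, ], 2), "empty")
  expect_error(kmeans_fit(rec, 3), "distinct")
})

test_that("k-means attains the exhaustive-enumeration optimum on small sets", {
  # 1D two-group set: partition and SSE from brute force over all 2-partitions
  rec <- data.frame(weight_g = c(0, 0.1, 0.2, 10, 10.1, 10.2))
  fit <- kmeans_fit(rec, 2, seed = 1)
  expect_equal(length(unique(fit$labels[1:3])), 1)
  expect_equal(length(unique(fit$labels[4:6])), 1)
  Z <- scale(as.matrix(rec))
  expect_equal(fit$sse, brute_force_sse(Z, 2), tolerance = 1e-10)
  # random small configurations, k = 2
  for (s in 1:5) {
    set.seed(s)
    rec <- data.frame(length_circumference_cm = runif(7, 0, 10),
                      width_circumference_cm = runif(7, 0, 10),
                      weight_g = runif(7, 0, 10))
    fit <- kmeans_fit(rec, 2, seed = s, n_restarts = 10)
    Z <- scale(as.matrix(rec))
    expect_equal(fit$sse, brute_force_sse(Z, 2), tolerance = 1e-8)
  }
})

test_that("k-means agrees with the reference Lloyd implementation", {
  rec <- gen_morphology(54, seed = 1)
  fit <- kmeans_fit(rec, 3, seed = 1)
  Z <- scale(as.matrix(rec[, -1]))
  set.seed(1)
  ref <- kmeans(Z, 3, nstart = 25, algorithm = "Lloyd", iter.max = 100)
  expect_equal(fit$sse, ref$tot.withinss, tolerance = 1e-8)
})

test_that("fitted cluster means recover the class weight profile", {
  rec <- gen_morphology(54, seed = 1)
  fit <- kmeans_fit(rec, 3, seed = 1)
  w <- sort(fit$centers_raw[, "weight_g"])
  targets <- c(1503.20, 2132.48, 2826.37)
  se2 <- 2 * c(118.39, 127.16, 121.25) / sqrt(54)
  expect_true(all(abs(w - targets) < se2))
  # class labels follow ascending centroid weight
  expect_equal(as.numeric(tapply(rec$weight_g, fit$classes, mean)), w,
               tolerance = 1e-6)
})

test_that("SSE curve is nonincreasing with a sharp elbow at the true k", {
  blobs <- make_blobs(rbind(c(0, 0, 0), c(10, 10, 10), c(20, 0, 20)))
  cur <- sse_curve(blobs, 1:5, seed = 1)
  expect_true(all(diff(cur$sse) <= 1e-9))
  drops <- -diff(cur$sse)
  expect_gt(drops[2], 20 * drops[3])  # 2->3 collapse dwarfs 3->4
})

test_that("silhouette matches hand-computed values", {
  rec1 <- data.frame(weight_g = c(0, 0, 3, 3))
  expect_equal(silhouette_mean(rec1, c(1, 1, 2, 2)), 1)
  rec2 <- data.frame(weight_g = c(0, 1, 10, 11))
  hand <- ((10.5 - 1) / 10.5 + (9.5 - 1) / 9.5) / 2
  expect_equal(silhouette_mean(rec2, c(1, 1, 2, 2)), hand, tolerance = 1e-10)
  # singleton clusters contribute zero
  rec3 <- data.frame(weight_g = c(0, 1, 2))
  expect_equal(silhouette_mean(rec3, c(1, 2, 2)), (0 + 0 + 0.5) / 3)
  expect_error(silhouette_mean(rec2, c(1, 1, 1, 1)), "two clusters")
})

test_that("silhouette stays in [-1, 1] and agrees with cluster::silhouette", {
  for (s in 1:5) {
    set.seed(s)
    rec <- data.frame(length_circumference_cm = rnorm(30),
                      width_circumference_cm = rnorm(30),
                      weight_g = rnorm(30))
    labels <- sample(1:3, 30, replace = TRUE)
    ours <- silhouette_mean(rec, labels, standardize = FALSE)
    expect_gte(ours, -1); expect_lte(ours, 1)
    ref <- mean(cluster::silhouette(labels, dist(as.matrix(rec)))[, 3])
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("silhouette-based selection finds the constructed cluster count", {
  three <- make_blobs(rbind(c(0, 0, 0), c(10, 10, 10), c(20, 0, 20)))
  expect_equal(select_k(three, 2:5, seed = 1)$k_opt, 3)
  expect_equal(select_k(three, 2:5, seed = 1)$knee_k, 3)
  two <- make_blobs(rbind(c(0, 0, 0), c(12, 12, 12)), seed = 7)
  expect_equal(select_k(two, 2:4, seed = 1)$k_opt, 2)
})

test_that("selection returns three size classes on synthetic morphology", {
  hits <- vapply(1:5, function(s) {
    rec <- gen_morphology(54, seed = 100 + s)
    select_k(rec, 2:5, seed = s)$k_opt
  }, numeric(1))
  expect_true(all(hits == 3))
})

test_that("basket allocation mixes classes and balances weight", {
  rec <- gen_morphology(18, seed = 2)
  fit <- kmeans_fit(rec, 3, seed = 1)
  alloc <- allocate_baskets(fit, rec)
  expect_equal(length(unique(alloc$basket_id)), 18)
  by_basket <- split(alloc$class, alloc$basket_id)
  expect_true(all(vapply(by_basket, function(x) identical(sort(x), 1:3),
                         logical(1))))
  # greedy pairing is no worse than random allocation (100 shuffles)
  tot <- tapply(alloc$weight_g, alloc$basket_id, sum)
  set.seed(1)
  rand_ranges <- replicate(100, {
    picks <- lapply(1:3, function(cl) sample(rec$weight_g[fit$classes == cl]))
    diff(range(Reduce(`+`, picks)))
  })
  expect_lte(diff(range(tot)), min(rand_ranges))
  # minimal case: one head per class, a single basket
  tiny <- data.frame(id = 1:3, length_circumference_cm = c(70, 82, 90),
                     width_circumference_cm = c(45, 52, 58),
                     weight_g = c(1500, 2100, 2800))
  fit3 <- kmeans_fit(tiny, 3, seed = 1)
  expect_equal(unique(allocate_baskets(fit3, tiny)$basket_id), 1)
})
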