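# Streaming series-wide PCA: accumulation, finalization, projection.

test_that("accumulated statistics are additive and order-invariant", {
  img1 <- random_msi(10, 10, seed = 1)
  img2 <- random_msi(10, 10, seed = 2)
  m <- full_mask(10, 10)
  s1 <- pixel_stats(img1, m); s2 <- pixel_stats(img2, m)
  both <- merge_stats(s1, s2)
  expect_equal(both$n_pixels, 200L)
  expect_equal(both$crossprod, s1$crossprod + s2$crossprod)

  fwd <- accumulate_statistics(list(list(image = img1, mask = m),
                                    list(image = img2, mask = m)))
  rev <- accumulate_statistics(list(list(image = img2, mask = m),
                                    list(image = img1, mask = m)))
  expect_equal(fwd$sum_vector, rev$sum_vector, tolerance = 1e-10)
  expect_equal(fwd$crossprod, rev$crossprod, tolerance = 1e-10)

  # single image: crossprod equals the dense X'X
  X <- unfold_pixels(img1, m)
  expect_equal(s1$crossprod, crossprod(X))
  expect_error(accumulate_statistics(list()), "empty")
})

test_that("merging is associative over a partitioned series", {
  imgs <- lapply(1:4, function(s) random_msi(8, 8, seed = s))
  m <- full_mask(8, 8)
  parts <- lapply(imgs, pixel_stats, mask = m)
  all4 <- accumulate_statistics(parts)
  ab <- merge_stats(parts[[1]], parts[[2]])
  cd <- merge_stats(parts[[3]], parts[[4]])
  expect_equal(all4$crossprod, merge_stats(ab, cd)$crossprod,
               tolerance = 1e-10)
  expect_equal(all4$sum_vector, merge_stats(ab, cd)$sum_vector,
               tolerance = 1e-10)
})

test_that("rank-1 pixel clouds put all variance on component 1", {
  set.seed(3)
  v <- stats::runif(11)
  t_i <- stats::rnorm(500)
  X <- 50 + outer(t_i, v)
  cube <- array(0, dim = c(20, 25, 11))
  for (k in 1:11) cube[, , k] <- matrix(X[, k], 20, 25)
  img <- multispectral_image(cube)
  model <- finalize_pca(pixel_stats(img, full_mask(20, 25)))
  expect_equal(model$explained[1], 100, tolerance = 1e-6)
  expect_lt(max(model$eigenvalues[-1]) / model$eigenvalues[1], 1e-10)
})

test_that("streaming fit equals the dense PCA oracle", {
  imgs <- lapply(1:5, function(s) random_msi(25, 40, seed = s))
  m <- full_mask(25, 40)
  model <- finalize_pca(accumulate_statistics(
    lapply(imgs, function(im) list(image = im, mask = m))))

  Xall <- do.call(rbind, lapply(imgs, unfold_pixels, mask = m))
  pc <- stats::prcomp(Xall, center = TRUE, scale. = FALSE)

  expect_equal(model$mean, colMeans(Xall), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(model$eigenvalues, pc$sdev^2, tolerance = 1e-8)
  expect_equal(abs(model$loadings), abs(pc$rotation), tolerance = 1e-8,
               ignore_attr = TRUE)

  # variance conservation: eigenvalue sum equals the covariance trace
  expect_equal(sum(model$eigenvalues),
               sum(apply(Xall, 2, stats::var)), tolerance = 1e-10)

  # orthonormal loadings, explained summing to 100
  expect_equal(crossprod(model$loadings), diag(11), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(model$explained), 100, tolerance = 1e-6)
  expect_true(all(diff(model$eigenvalues) <= 1e-8))
})

test_that("isotropic pixels spread variance evenly across components", {
  set.seed(12)
  n <- 1e5
  cube <- array(stats::rnorm(n * 11), dim = c(250, 400, 11))
  model <- finalize_pca(pixel_stats(multispectral_image(cube),
                                    full_mask(250, 400)))
  # 0.51 pp = 3x the mean maximum deviation observed over 30 replicate
  # draws at this n (Monte-Carlo calibration)
  expect_lt(max(abs(model$explained - 100 / 11)), 0.51)
})

test_that("sign canonicalization makes each loading's largest element negative", {
  model <- finalize_pca(pixel_stats(random_msi(30, 30, seed = 7),
                                    full_mask(30, 30)))
  for (k in 1:11) {
    expect_lt(model$loadings[which.max(abs(model$loadings[, k])), k], 0)
  }
})

test_that("score projection is centered, variance-matching and uncorrelated", {
  imgs <- lapply(1:3, function(s) random_msi(20, 20, seed = s + 10))
  m <- full_mask(20, 20)
  model <- finalize_pca(accumulate_statistics(
    lapply(imgs, function(im) list(image = im, mask = m))))

  # a pixel equal to the global mean scores 0 on every component
  cube <- array(rep(model$mean, each = 1), dim = c(1, 1, 11))
  at_mean <- multispectral_image(cube)
  for (k in c(1, 5, 11)) {
    expect_equal(project_scores(at_mean, full_mask(1, 1), model, k)$values[1, 1],
                 0, tolerance = 1e-10)
  }

  S <- do.call(rbind, lapply(imgs, function(im) {
    project_score_values(im, m, model, 1:11)
  }))
  n <- nrow(S)
  expect_equal(apply(S, 2, function(s) sum(s^2) / (n - 1)),
               model$eigenvalues, tolerance = 1e-6)
  off <- crossprod(S) / (n - 1)
  expect_lt(max(abs(off[upper.tri(off)])) / model$eigenvalues[1], 1e-6)

  expect_error(project_scores(imgs[[1]], m, model, 12), "out of range")
})

test_that("8-bit score rendering uses common eigenvalue-derived bounds", {
  img <- random_msi(15, 15, seed = 20)
  m <- full_mask(15, 15)
  model <- finalize_pca(pixel_stats(img, m))
  sc <- project_scores(img, m, model, 1)

  b <- 3 * sqrt(model$eigenvalues[1])
  zero <- sc; zero$values[] <- 0
  expect_true(all(score_to_8bit(zero, model) == 128L))
  hi <- sc; hi$values[] <- b + 10
  expect_true(all(score_to_8bit(hi, model) == 255L))

  # identical bounds for different images of the same series
  img2 <- random_msi(15, 15, seed = 21)
  sc2 <- project_scores(img2, m, model, 1)
  expect_identical(attr(score_to_8bit(sc, model), "bounds"),
                   attr(score_to_8bit(sc2, model), "bounds"))
  expect_error(score_to_8bit(sc, model, spread = 0), "positive")
})

test_that("three contrasting endmembers are recovered in the top-3 subspace", {
  W <- endmember_matrix(default_endmembers())
  set.seed(31)
  n <- 20000
  A <- matrix(stats::runif(3 * n, 0, 1), ncol = 3)
  X <- A %*% W * 100
  X <- X + matrix(stats::rnorm(n * 11, 0, 0.02 * mean(X)), ncol = 11)
  cube <- array(0, dim = c(100, 200, 11))
  for (k in 1:11) cube[, , k] <- matrix(X[, k], 100, 200)
  model <- finalize_pca(pixel_stats(multispectral_image(cube),
                                    full_mask(100, 200)))
  L3 <- model$loadings[, 1:3]
  for (i in 1:2) for (j in (i + 1):3) {
    v <- W[i, ] - W[j, ]
    angle <- acos(min(1, sqrt(sum((crossprod(L3, v))^2)) / sqrt(sum(v^2))))
    expect_lt(angle * 180 / pi, 5)
  }
})

test_that("PCA model JSON round trip preserves the model", {
  model <- finalize_pca(pixel_stats(random_msi(10, 10, seed = 40),
                                    full_mask(10, 10)))
  f <- file.path(withr::local_tempdir(), "model.json")
  write_pca_json(model, f)
  back <- read_pca_json(f)
  expect_equal(back$mean, model$mean)
  expect_equal(back$eigenvalues, model$eigenvalues)
  expect_equal(back$loadings, model$loadings, ignore_attr = TRUE)
  expect_equal(back$explained, model$explained)
})
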