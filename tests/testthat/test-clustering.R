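test_that("two-point Ripley K steps from 0 to the region area", {
  tab <- loc_table(data.frame(x = c(0, 300), y = c(0, 400), frame = 0L),
                   region = c(0, 0, 1000, 1000))
  rc <- suppressWarnings(ripley(tab, radii = c(100, 499, 500, 520),
                                edge_correction = "none"))
  # pair distance is 500; below it K = 0, at and above it K = A = 1e6
  expect_equal(rc$K, c(0, 0, 1e6, 1e6))
  expect_equal(rc$L, sqrt(rc$K / pi))
  expect_equal(rc$H, rc$L - rc$r)
})

test_that("K is nonnegative and nondecreasing on random patterns", {
  radii <- seq(5, 400, by = 5)
  for (seed in 1:5) {
    p <- simulate_points(300, c(0, 0, 2000, 2000), "csr", seed = seed)
    rc <- ripley(cbind(p$x, p$y), radii, "translation",
                 region = c(0, 0, 2000, 2000))
    expect_true(all(rc$K >= 0))
    expect_true(all(diff(rc$K) >= 0))
  }
})

test_that("the H peak of clustered data sits at the Thomas-process optimum", {
  # independent oracle: for a Thomas process with cluster intensity kappa
  # and spread sigma_c, K(r) = pi r^2 + (1 - exp(-r^2/(4 sigma_c^2)))/kappa;
  # the H peak location follows by 1-D optimization.
  kappa <- 40 / 2000^2
  sigma_c <- 50
  h_theory <- function(r) {
    sqrt((pi * r^2 + (1 - exp(-r^2 / (4 * sigma_c^2))) / kappa) / pi) - r
  }
  r_star <- optimize(h_theory, c(10, 1000), maximum = TRUE)$maximum
  radii <- seq(10, 500, by = 10)
  peaks <- vapply(1:25, function(k) {
    p <- simulate_points(1000, c(0, 0, 2000, 2000), "gaussian_clusters",
                         n_clusters = 40, sigma_c = sigma_c, seed = 400 + k)
    rc <- ripley(cbind(p$x, p$y), radii, "translation",
                 region = c(0, 0, 2000, 2000))
    radii[which.max(rc$H)]
  }, numeric(1))
  expect_lt(abs(median(peaks) - r_star), 50)
  expect_true(all(peaks > 2 * sigma_c / 2 & peaks < 500))
})

test_that("dbscan handles the textbook micro-examples", {
  line <- cbind(c(0, 1, 2), 0)
  expect_equal(dbscan(line, eps = 1.5, min_pts = 2)$labels, c(0L, 0L, 0L))
  apart <- cbind(c(0, 10), 0)
  expect_equal(dbscan(apart, eps = 1, min_pts = 2)$labels, c(-1L, -1L))
  # border point: within eps of a core but not core itself
  pts <- cbind(c(0, 0.4, 0.8, 1.7), 0)
  res <- dbscan(pts, eps = 1, min_pts = 3)
  expect_equal(res$labels, c(0L, 0L, 0L, 0L))
  expect_equal(res$is_core, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("dbscan equals the brute-force core-graph oracle", {
  withr::with_seed(30, {
    for (rep in 1:40) {
      n <- sample(20:200, 1)
      xy <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
      eps <- runif(1, 30, 120)
      min_pts <- sample(2:6, 1)
      got <- dbscan(xy, eps, min_pts)
      want <- oracle_dbscan(xy, eps, min_pts)
      expect_true(same_partition(got$labels, want))
      # localization bookkeeping: clusters + noise = n
      expect_equal(sum(got$labels >= 0L) + sum(got$labels < 0L), n)
    }
  })
})

test_that("the OPTICS eps-cut reproduces dbscan partitions", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      n <- sample(30:200, 1)
      xy <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
      min_pts <- sample(2:6, 1)
      eps <- runif(1, 30, 120)
      op <- optics(xy, min_pts)
      ex <- extract_dbscan(op, eps)
      db <- dbscan(xy, eps, min_pts)
      expect_true(same_partition(ex$labels, db$labels))
    }
  })
})

test_that("OPTICS reachability shows one valley per well-separated blob", {
  withr::with_seed(32, {
    blob1 <- cbind(rnorm(60, 200, 20), rnorm(60, 200, 20))
    blob2 <- cbind(rnorm(60, 800, 20), rnorm(60, 800, 20))
  })
  op <- optics(rbind(blob1, blob2), min_pts = 5)
  reach_in_order <- op$reachability[op$order]
  # valleys = maximal runs of reachability below a fixed threshold
  low <- reach_in_order < 100
  low[is.na(low)] <- FALSE
  n_valleys <- sum(diff(c(FALSE, low)) == 1)
  expect_equal(n_valleys, 2L)
})

test_that("a single point yields a trivial ordering with infinite reach", {
  op <- optics(cbind(1, 1), min_pts = 2)
  expect_equal(op$order, 1L)
  expect_equal(op$reachability, Inf)
})

test_that("morphology closed forms: unit square and near-circular 64-gon", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  res <- dbscan(sq, eps = 2, min_pts = 2)
  shp <- cluster_morphology(sq, res)
  expect_equal(shp$area, 1)
  expect_equal(shp$perimeter, 4)
  expect_equal(shp$circularity, pi / 4, tolerance = 1e-12)
  expect_equal(shp$max_diameter, sqrt(2))
  expect_equal(c(shp$centroid_x, shp$centroid_y), c(0.5, 0.5))
  ang <- 2 * pi * (0:63) / 64
  gon <- cbind(100 * cos(ang), 100 * sin(ang))
  shp64 <- cluster_morphology(gon, dbscan(gon, eps = 50, min_pts = 2))
  expect_equal(shp64$circularity, 1, tolerance = 1e-3)
})

test_that("hull area and perimeter match the brute-force oracle", {
  withr::with_seed(33, {
    for (rep in 1:8) {
      n <- sample(5:50, 1)
      pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
      res <- structure(list(labels = rep.int(0L, n), n_clusters = 1L,
                            is_core = rep(TRUE, n),
                            params = list(eps = 1e3, min_pts = 1)),
                       class = "cluster_result")
      shp <- cluster_morphology(pts, res)
      want <- oracle_hull_metrics(pts)
      expect_equal(shp$area, want$area, tolerance = 1e-9)
      expect_equal(shp$perimeter, want$perimeter, tolerance = 1e-9)
      expect_lte(shp$circularity, 1 + 1e-9)
    }
  })
})

test_that("degenerate clusters are flagged with zero area", {
  collinear <- cbind(c(0, 1, 2), c(0, 1, 2))
  res <- dbscan(collinear, eps = 3, min_pts = 2)
  shp <- cluster_morphology(collinear, res)
  expect_true(shp$degenerate)
  expect_equal(shp$area, 0)
  expect_true(is.na(shp$circularity))
})

test_that("per-cluster localization counts partition the table", {
  p <- simulate_points(400, c(0, 0, 2000, 2000), "gaussian_clusters",
                       n_clusters = 8, sigma_c = 40, seed = 34)
  res <- dbscan(cbind(p$x, p$y), eps = 50, min_pts = 5)
  shp <- cluster_morphology(cbind(p$x, p$y), res)
  expect_equal(sum(shp$n_localizations) + sum(res$labels < 0L), 400L)
})
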