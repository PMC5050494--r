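test_that("pure translation and identity are recovered exactly", {
  withr::with_seed(10, {
    mov <- cbind(runif(8, 0, 2000), runif(8, 0, 2000))
  })
  fix <- sweep(mov, 2, c(50, -20), "+")
  ft <- estimate_transform(list(moving = mov, fixed = fix), "translation")
  expect_equal(ft$transform$offset, c(50, -20))
  expect_equal(ft$fre, 0, tolerance = 1e-9)
  for (model in c("translation", "similarity", "affine")) {
    ft <- estimate_transform(list(moving = mov, fixed = mov), model)
    expect_equal(ft$transform$matrix, diag(2), tolerance = 1e-9)
    expect_equal(ft$transform$offset, c(0, 0), tolerance = 1e-6)
    expect_equal(ft$fre, 0, tolerance = 1e-9)
  }
})

test_that("noise-free synthetic transforms are recovered for all models", {
  withr::with_seed(11, {
    mov <- cbind(runif(12, 0, 2000), runif(12, 0, 2000))
  })
  th <- 10 * pi / 180
  truth <- list(
    translation = affine2d(diag(2), c(30, 40), "translation"),
    similarity = affine2d(1.01 * matrix(c(cos(th), sin(th), -sin(th),
                                          cos(th)), 2, 2),
                          c(30, 40), "similarity"),
    affine = affine2d(matrix(c(1.02, 0.05, -0.03, 0.98), 2, 2), c(30, 40)))
  for (model in names(truth)) {
    fix <- transform_points(truth[[model]], mov)
    ft <- estimate_transform(list(moving = mov, fixed = fix), model)
    expect_equal(ft$transform$matrix, truth[[model]]$matrix,
                 tolerance = 1e-6)
    expect_equal(ft$transform$offset, truth[[model]]$offset,
                 tolerance = 1e-6)
    expect_lt(ft$fre, 1e-6)
  }
})

test_that("FRE is invariant under relabeling of the pair order", {
  withr::with_seed(12, {
    mov <- cbind(runif(15, 0, 2000), runif(15, 0, 2000))
    fix <- sweep(mov, 2, c(10, 5), "+") + matrix(rnorm(30, sd = 4), ncol = 2)
    perm <- sample(15)
  })
  f1 <- estimate_transform(list(moving = mov, fixed = fix), "similarity")
  f2 <- estimate_transform(list(moving = mov[perm, ], fixed = fix[perm, ]),
                           "similarity")
  expect_equal(f1$fre, f2$fre, tolerance = 1e-12)
})

test_that("noisy similarity fits match Monte-Carlo expectations", {
  # rotation 10 deg, scale 1.01, translation (30, 40); isotropic noise
  # sigma = 5 nm on the fixed channel; n = 20 fiducials, 300 replicates.
  th <- 10 * pi / 180
  s_true <- 1.01
  truth <- affine2d(s_true * matrix(c(cos(th), sin(th), -sin(th), cos(th)),
                                    2, 2), c(30, 40), "similarity")
  sigma <- 5
  n <- 20
  reps <- 300
  stats <- withr::with_seed(13, {
    t(replicate(reps, {
      mov <- cbind(runif(n, 0, 2000), runif(n, 0, 2000))
      fix <- transform_points(truth, mov) +
        matrix(rnorm(2 * n, sd = sigma), ncol = 2)
      ft <- estimate_transform(list(moving = mov, fixed = fix), "similarity")
      A <- ft$transform$matrix
      c(scale = sqrt(abs(det(A))), angle = atan2(A[2, 1], A[1, 1]),
        fre = ft$fre)
    }))
  })
  # parameter recovery: mean within 3 standard errors of the truth
  for (col in c("scale", "angle")) {
    tr <- if (col == "scale") s_true else th
    se <- sd(stats[, col]) / sqrt(reps)
    expect_lt(abs(mean(stats[, col]) - tr), 3 * se)
  }
  # FRE ~ sigma * sqrt(2) * sqrt(1 - k/(2n)) with k = 4 similarity dofs
  expected_fre <- sigma * sqrt(2) * sqrt(1 - 4 / (2 * n))
  expect_equal(mean(stats[, "fre"]), expected_fre, tolerance = 0.05)
})

test_that("apply_transform maps coordinates, leaves other fields, inverts", {
  tab <- random_table(25, seed = 14)
  ident <- affine2d()
  expect_equal(as.data.frame(apply_transform(tab, ident)),
               as.data.frame(tab))
  tr <- affine2d(diag(2), c(50, -20), "translation")
  fwd <- apply_transform(tab, tr)
  expect_equal(fwd$photons, tab$photons)
  expect_equal(fwd$frame, tab$frame)
  back <- apply_transform(fwd, invert_transform(tr))
  expect_equal(back$x, tab$x, tolerance = 1e-9)
  expect_equal(back$y, tab$y, tolerance = 1e-9)
  # 90 deg rotation about the origin maps (1, 0) to (0, 1) in the
  # top-left-origin, y-down convention (x, y) -> (-y, x)
  rot <- affine2d(matrix(c(0, 1, -1, 0), 2, 2))
  expect_equal(as.vector(transform_points(rot, cbind(1, 0))), c(0, 1))
})

test_that("mutual-nearest-neighbor matching equals the brute-force oracle", {
  withr::with_seed(15, {
    for (rep in 1:10) {
      a <- cbind(runif(30, 0, 5000), runif(30, 0, 5000))
      b <- rbind(a[sample(30, 20), ] + matrix(rnorm(40, sd = 30), ncol = 2),
                 cbind(runif(10, 0, 5000), runif(10, 0, 5000)))
      got <- match_fiducials(a, b, max_dist = 150)
      want <- oracle_mutual_nn(a, b, max_dist = 150)
      pair_key <- function(m, f) {
        sort(paste(signif(m[, 1], 12), signif(m[, 2], 12),
                   signif(f[, 1], 12), signif(f[, 2], 12)))
      }
      expect_equal(pair_key(got$moving, got$fixed),
                   pair_key(a[want[, 1], , drop = FALSE],
                            b[want[, 2], , drop = FALSE]))
    }
  })
})

test_that("matching enforces the distance threshold", {
  pts <- cbind(c(0, 500, 1000), c(0, 0, 0))
  got <- match_fiducials(pts, pts, max_dist = 1)
  expect_equal(nrow(got$moving), 3L)
  expect_error(match_fiducials(pts, sweep(pts, 2, c(100, 0), "+"),
                               max_dist = 50), "matching error")
})
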