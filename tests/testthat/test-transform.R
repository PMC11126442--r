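test_that("rigid transforms act on points as rotation about a centre plus shift", {
  tr <- rigid_transform(angles = c(0, 0, pi / 2), translation = c(1, 0, 0),
                        center = c(1, 1, 0))
  # brute-force recomputation for one point
  p <- c(2, 1, 5)
  rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  expected <- as.numeric(rz %*% (p - c(1, 1, 0))) + c(1, 1, 0) + c(1, 0, 0)
  expect_equal(as.numeric(transform_points(tr, p)), expected, tolerance = 1e-12)
})

test_that("non-orthonormal rotation matrices are rejected", {
  expect_error(rigid_transform(rotation = diag(3) * 1.001), "orthonormal")
  expect_error(rigid_transform(rotation = diag(c(1, 1, -1))), "orthonormal")
})

test_that("composition and inversion close over the group", {
  set.seed(42)
  for (i in 1:25) {
    t1 <- rigid_transform(angles = runif(3, -0.3, 0.3),
                          translation = runif(3, -5, 5),
                          center = runif(3, 0, 20))
    t2 <- rigid_transform(angles = runif(3, -0.3, 0.3),
                          translation = runif(3, -5, 5),
                          center = runif(3, 0, 20))
    pts <- matrix(runif(12, -10, 30), ncol = 3)
    # compose matches sequential application
    expect_equal(transform_points(compose_transforms(t2, t1), pts),
                 transform_points(t2, transform_points(t1, pts)),
                 tolerance = 1e-9)
    # T^-1 T = identity
    rt <- compose_transforms(invert_transform(t1), t1)
    expect_lt(max(abs(transform_points(rt, pts) - pts)), 1e-9)
  }
})

test_that("euler angles round-trip through the rotation matrix", {
  set.seed(7)
  for (i in 1:20) {
    a <- runif(3, -0.5, 0.5)
    tr <- rigid_transform(angles = a)
    expect_equal(rigid_transform(rotation = tr$rotation)$angles, a,
                 tolerance = 1e-9)
  }
})

test_that("target registration error matches direct point distances", {
  t1 <- rigid_transform(angles = c(0.1, -0.05, 0.2), translation = c(1, 2, 3))
  expect_equal(target_registration_error(t1, t1, matrix(1:9, 3)), 0)
  # composing a pure 1 mm translation gives exactly 1 mm for any points
  shift <- rigid_transform(translation = c(0, 0, 1))
  t2 <- compose_transforms(shift, t1)
  pts <- matrix(runif(30, -10, 10), ncol = 3)
  expect_equal(target_registration_error(t1, t2, pts), 1, tolerance = 1e-12)
  # generic perturbation equals brute-force mean distance
  t3 <- rigid_transform(angles = c(0.11, -0.04, 0.21), translation = c(1.2, 2, 2.9))
  d <- sqrt(rowSums((transform_points(t1, pts) - transform_points(t3, pts))^2))
  expect_equal(target_registration_error(t1, t3, pts), mean(d))
  expect_error(target_registration_error(t1, t2, matrix(numeric(0), ncol = 3)),
               "at least one")
})

test_that("transforms serialize to JSON and back", {
  tr <- rigid_transform(angles = c(0.02, -0.01, 0.03), translation = c(2, -1, 1.5),
                        center = c(10, 10, 5))
  f <- tempfile(fileext = ".json")
  write_transform_json(tr, f)
  tr2 <- read_transform_json(f)
  expect_equal(tr2$angles, tr$angles, tolerance = 1e-12)
  expect_equal(tr2$translation, tr$translation, tolerance = 1e-12)
  expect_equal(tr2$center, tr$center, tolerance = 1e-12)
  unlink(f)
})
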