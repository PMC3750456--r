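test_that("rigid transforms compose associatively and invert to identity", {
  set.seed(11)
  for (i in 1:20) {
    a <- random_rigid(); b <- random_rigid(); c_ <- random_rigid()
    p <- matrix(rnorm(30, sd = 10), 10, 3)
    lhs <- apply_transform(compose_transform(compose_transform(a, b), c_), p)
    rhs <- apply_transform(compose_transform(a, compose_transform(b, c_)), p)
    expect_lt(max(abs(lhs - rhs)), 1e-9)
    ident <- compose_transform(a, invert_transform(a))
    expect_lt(max(abs(ident$R - diag(3))), 1e-9)
    expect_lt(max(abs(ident$t)), 1e-9)
  }
})

test_that("improper or non-orthonormal rotations are rejected", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper")
  expect_error(rigid_transform(matrix(rnorm(9), 3, 3)), "orthonormal")
})

test_that("plane reflection is an involution and fixes on-plane points", {
  set.seed(12)
  for (i in 1:10) {
    pl <- plane3(rnorm(3), rnorm(3, sd = 5))
    p <- matrix(rnorm(60, sd = 20), 20, 3)
    expect_lt(max(abs(reflect_points(pl, reflect_points(pl, p)) - p)), 1e-9)
    expect_lt(max(abs(plane_signed_distance(pl, reflect_points(pl, p)) +
                      plane_signed_distance(pl, p))), 1e-9)
  }
  pl <- plane3(c(0, 1, 0), c(0, 40, 0))
  expect_equal(reflect_points(pl, c(3, 40, -2))[1, ], c(3, 40, -2))
})

test_that("plane construction rejects a zero normal", {
  expect_error(plane3(c(0, 0, 0), c(1, 2, 3)), "zero")
})

test_that("Kabsch alignment recovers random rigid transforms exactly", {
  set.seed(13)
  for (i in 1:20) {
    tr <- random_rigid()
    src <- matrix(rnorm(30, sd = 15), 10, 3)
    fit <- align_points(src, apply_transform(tr, src))
    expect_lt(max(abs(fit$R - tr$R)), 1e-9)
    expect_lt(max(abs(fit$t - tr$t)), 1e-9)
  }
})

test_that("rigid transforms preserve pairwise distances", {
  set.seed(14)
  p <- matrix(rnorm(60, sd = 10), 20, 3)
  for (i in 1:10) {
    q <- apply_transform(random_rigid(), p)
    expect_lt(max(abs(dist(q) - dist(p))), 1e-9)
  }
})

test_that("4x4 matrix round trip preserves the transform", {
  set.seed(15)
  tr <- random_rigid()
  tr2 <- transform_from_matrix(transform_matrix(tr))
  expect_equal(tr2$R, tr$R, tolerance = 1e-12)
  expect_equal(tr2$t, tr$t, tolerance = 1e-12)
})
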