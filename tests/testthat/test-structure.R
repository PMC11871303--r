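toy_xyz <- matrix(c(0, 0, 0,
                    3.8, 0, 0,
                    5.5, 3.1, 0,
                    7.0, 4.2, 2.9,
                    9.9, 2.0, 4.1), ncol = 3, byrow = TRUE)

test_that("C-alpha parsing keeps order, chain and first altloc", {
  path <- write_pdb_fixture(resno = c(5, 6, 7), models = toy_xyz[1:3, ])
  cs <- read_calpha(path)
  expect_equal(cs$resno, c(5L, 6L, 7L))
  expect_equal(cs$xyz, toy_xyz[1:3, ])
  # altloc: A line precedes B for residue 6; A must be retained
  xyzB <- rbind(toy_xyz[1, ], toy_xyz[2, ], toy_xyz[2, ] + 1, toy_xyz[3, ])
  pathB <- write_pdb_fixture(resno = c(5, 6, 6, 7), models = xyzB,
                             alt = c(" ", "A", "B", " "))
  csB <- read_calpha(pathB)
  expect_equal(nrow(csB$xyz), 3L)
  expect_equal(csB$xyz[2, ], toy_xyz[2, ])
})

test_that("model selection and chain errors behave as specified", {
  shifted <- toy_xyz[1:3, ] + 10
  path <- write_pdb_fixture(resno = 1:3, models = list(toy_xyz[1:3, ], shifted))
  m2 <- read_calpha(path, model = 2)
  expect_equal(m2$xyz, shifted)
  expect_error(read_calpha(path, model = 3), "model")
  expect_error(read_calpha(path, chain = "B"), "available")
})

test_that("common residues intersect by residue number", {
  a <- coord_set("a", 1:10, matrix(rnorm(30), 10, 3))
  b <- coord_set("b", 5:15, matrix(rnorm(33), 11, 3))
  pr <- common_residues(a, b)
  expect_equal(pr$resno, 5:10)
  expect_equal(pr$n_common, 6L)
  c_ <- coord_set("c", 20:25, matrix(rnorm(18), 6, 3))
  expect_error(common_residues(a, c_), "common")
  expect_error(coord_set("d", c(1, 1, 2), matrix(0, 3, 3)), "duplicate")
})

test_that("identical and rigidly transformed sets give zero RMSD", {
  fit0 <- kabsch_rmsd(toy_xyz, toy_xyz)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)  # 90 deg about z
  moved <- toy_xyz %*% t(Rz) + matrix(c(4, -2, 7), nrow(toy_xyz), 3, byrow = TRUE)
  expect_equal(kabsch_rmsd(toy_xyz, moved)$rmsd, 0, tolerance = 1e-10)
  set.seed(21)
  for (i in 1:5) {
    Q <- random_rotation()
    moved <- toy_xyz %*% t(Q) + matrix(rnorm(3), nrow(toy_xyz), 3, byrow = TRUE)
    expect_equal(kabsch_rmsd(toy_xyz, moved)$rmsd, 0, tolerance = 1e-9)
  }
})

test_that("reflections are never returned as rotations", {
  mirrored <- toy_xyz %*% diag(c(-1, 1, 1))
  fit <- kabsch_rmsd(toy_xyz, mirrored)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.1)
})

test_that("RMSD of a perturbed copy matches a rotation-grid oracle", {
  set.seed(22)
  pts <- toy_xyz[1:4, ]
  pert <- pts + matrix(rnorm(12, 0, 0.3), 4, 3)
  got <- kabsch_rmsd(pts, pert)$rmsd
  # oracle: coarse-to-fine search over Euler angles with optimal translation
  A <- sweep(pts, 2, colMeans(pts)); B <- sweep(pert, 2, colMeans(pert))
  rot <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  rmsd_at <- function(a, b, c) sqrt(mean(rowSums((A - B %*% t(rot(a, b, c)))^2)))
  centre <- c(0, 0, 0); width <- pi
  best <- Inf
  for (level in 1:6) {
    gr <- seq(-width, width, length.out = 13)
    for (a in centre[1] + gr) for (b in centre[2] + gr) for (c_ in centre[3] + gr) {
      val <- rmsd_at(a, b, c_)
      if (val < best) { best <- val; centre_new <- c(a, b, c_) }
    }
    centre <- centre_new
    width <- width / 5
  }
  expect_equal(got, best, tolerance = 1e-3)
  expect_lte(got, best + 1e-6)  # closed form is never worse than the search
})

test_that("kabsch agrees with an established superposition routine", {
  set.seed(23)
  a <- matrix(rnorm(45, sd = 5), 15, 3)
  b <- a %*% t(random_rotation()) + matrix(rnorm(45, 0, 0.4), 15, 3)
  ours <- kabsch_rmsd(a, b)$rmsd
  ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("degenerate and undersized inputs are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_rmsd(line, line + 0.1), "degenerate|collinear")
  expect_error(kabsch_rmsd(toy_xyz[1:2, ], toy_xyz[1:2, ]), ">= 3")
})

test_that("the pairwise matrix is symmetric, zero-diagonal and transform-invariant", {
  set.seed(24)
  base <- coord_set("s1", 1:12, matrix(rnorm(36, sd = 4), 12, 3))
  copies <- lapply(1:3, function(i) {
    Q <- random_rotation()
    coord_set(paste0("s", i + 1), 1:12,
              base$xyz %*% t(Q) + matrix(rnorm(3), 12, 3, byrow = TRUE))
  })
  m <- pairwise_rmsd_matrix(c(list(base), copies))
  expect_equal(m$rmsd, t(m$rmsd))
  expect_equal(unname(diag(m$rmsd)), rep(0, 4))
  expect_lt(max(m$rmsd), 1e-6)
  # perturbed copies obey the triangle-like bound through the original
  p1 <- coord_set("p1", 1:12, base$xyz + matrix(rnorm(36, 0, 0.2), 12, 3))
  p2 <- coord_set("p2", 1:12, base$xyz + matrix(rnorm(36, 0, 0.2), 12, 3))
  m2 <- pairwise_rmsd_matrix(list(base, p1, p2))$rmsd
  expect_lte(m2["p1", "p2"], m2["s1", "p1"] + m2["s1", "p2"] + 1e-9)
})
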