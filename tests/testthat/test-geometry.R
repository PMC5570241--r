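test_that("kabsch recovers exact rigid motions", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch(P, P)$rmsd, 0, tolerance = 1e-12)
  expect_equal(kabsch(P, P)$rotation, diag(3), tolerance = 1e-9)
  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  Q <- sweep(P %*% t(R), 2, c(1, -2, 3), "+")
  k <- kabsch(P, Q)
  expect_equal(k$rmsd, 0, tolerance = 1e-9)
  expect_equal(k$rotation, R, tolerance = 1e-9)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch matches the quaternion oracle on random clouds", {
  set.seed(7)
  for (i in 1:50) {
    P <- matrix(rnorm(30), 10, 3)
    Q <- matrix(rnorm(30), 10, 3)
    expect_equal(kabsch(P, Q)$rmsd, quaternion_rmsd(P, Q), tolerance = 1e-9)
  }
})

test_that("kabsch rejects fewer than 3 points", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "insufficient")
})

test_that("model contacts obey the distance threshold strictly", {
  target <- target_sequence("t", strrep("A", 20))
  co <- matrix(0, 3, 3)
  co[2, ] <- c(100, 0, 0)      # far from both others
  co[3, ] <- c(7.9, 0, 0)      # 7.9 A from residue 1
  m <- read_model(toy_pdb(rep("ALA", 3), c(1, 8, 11), co), target)
  mc <- model_contacts(m)
  expect_true(any(mc$i == 1 & mc$j == 11))   # 7.9 <= 8, separation 10
  co[3, ] <- c(8.01, 0, 0)
  m <- read_model(toy_pdb(rep("ALA", 3), c(1, 8, 11), co), target)
  expect_false(any(model_contacts(m)$j == 11))
})

test_that("model contacts equal a brute-force all-pairs scan", {
  ws <- ws_small()
  m <- ws$native
  mc <- model_contacts(m)
  xyz <- m$cb
  xyz[m$res_codes == "G", ] <- m$ca[m$res_codes == "G", ]
  pos <- m$target_positions
  brute <- list()
  for (i in seq_along(pos)) for (j in seq_along(pos)) {
    if (j <= i || abs(pos[i] - pos[j]) < 5) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 8) {
      brute[[length(brute) + 1]] <- c(pos[i], pos[j])
    }
  }
  brute <- do.call(rbind, brute)
  expect_equal(nrow(mc), nrow(brute))
  expect_setequal(paste(mc$i, mc$j), paste(brute[, 1], brute[, 2]))
})

test_that("TM-score of identical full-coverage models is exactly 1", {
  ws <- ws_small()
  sup <- tm_superpose(ws$native, ws$native, length(ws$target))
  expect_identical(sup$tm_score, 1)
  expect_true(all(sup$per_residue_d < 1e-9))
})

test_that("tm_superpose localizes a single displaced residue", {
  ws <- ws_small()
  m <- ws$native
  shifted <- m
  k <- 10L
  for (nm in c("ca", "cb", "n", "c", "o")) {
    shifted[[nm]][k, ] <- shifted[[nm]][k, ] + c(10, 0, 0)
  }
  sup <- tm_superpose(shifted, m, length(ws$target))
  d <- sup$per_residue_d
  expect_equal(unname(d[as.character(m$target_positions[k])]), 10,
               tolerance = 0.2)
  expect_lt(max(d[-k]), 0.5)
})

test_that("TM-score is invariant under rigid motion and symmetric", {
  ws <- ws_small()
  a <- ws$models[[5]]
  b <- ws$models[[8]]
  L <- length(ws$target)
  tm_ab <- tm_superpose(a, b, L)$tm_score
  for (seed in 1:3) {
    a2 <- rigid_transform_model(a, seed)
    expect_equal(tm_superpose(a2, b, L)$tm_score, tm_ab, tolerance = 1e-6)
  }
  expect_equal(tm_superpose(b, a, L)$tm_score, tm_ab, tolerance = 1e-6)
})

test_that("tm_superpose requires at least 5 shared positions", {
  target <- target_sequence("t", strrep("A", 20))
  co <- matrix(rnorm(9), 3, 3)
  a <- read_model(toy_pdb(rep("ALA", 3), 1:3, co), target)
  expect_error(tm_superpose(a, a, 20), "no-overlap")
})

test_that("local Q-score is 1 for identical models and has the closed form", {
  ws <- ws_small()
  m <- ws$native
  q <- local_qscore(m, m)
  expect_true(all(abs(q - 1) < 1e-12))
  # two collinear CA traces whose pairwise distances differ by |i-j| A
  target <- target_sequence("t", strrep("A", 6))
  co1 <- cbind(seq(0, 50, by = 10), 0, 0)[1:5, ]
  co2 <- cbind(seq(0, 55, by = 11), 0, 0)[1:5, ]
  a <- read_model(toy_pdb(rep("ALA", 5), 1:5, co1), target)
  b <- read_model(toy_pdb(rep("ALA", 5), 1:5, co2), target)
  # distances between i and j differ by |i-j| A; restrict to adjacent pairs
  q2 <- local_qscore(a, b)
  # neighbours differ by exactly 1 A; further pairs by 2,3,4 A
  expect_equal(unname(q2["1"]),
               mean(exp(-c(1, 2, 3, 4)^2)), tolerance = 1e-12)
})

test_that("local Q-score is invariant under rigid motion", {
  ws <- ws_small()
  a <- ws$models[[3]]
  b <- ws$native
  q <- local_qscore(a, b)
  a2 <- rigid_transform_model(a, 11)
  expect_equal(local_qscore(a2, b), q, tolerance = 1e-6)
})

test_that("geometry is invariant under rigid transforms of inputs", {
  ws <- ws_small()
  m <- ws$models[[6]]
  mc <- model_contacts(m)
  m2 <- rigid_transform_model(m, 3)
  mc2 <- model_contacts(m2)
  expect_equal(mc2$d, mc$d, tolerance = 1e-6)
  expect_identical(mc2[c("i", "j")], mc[c("i", "j")])
})
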