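test_that("difference matrices encode forward differences and null spaces", {
  expect_equal(as.matrix(difference_matrix(3, 1)),
               rbind(c(-1, 1, 0), c(0, -1, 1)), ignore_attr = TRUE)
  expect_equal(as.matrix(difference_matrix(4, 2)),
               rbind(c(1, -2, 1, 0), c(0, 1, -2, 1)), ignore_attr = TRUE)
  expect_equal(as.numeric(difference_matrix(6, 1) %*% rep(2, 6)), rep(0, 5))
  expect_equal(as.numeric(difference_matrix(6, 2) %*% (1:6)), rep(0, 4))
  expect_error(difference_matrix(2, 2), "too few coefficients")
})

test_that("penalty matrices equal D'D with the right rank and null space", {
  p <- penalty_matrix(3, 1)
  expect_equal(as.matrix(p$P),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)),
               ignore_attr = TRUE)
  for (k in 3:10) for (ord in 1:2) {
    if (k <= ord) next
    ps <- penalty_matrix(k, ord)
    expect_equal(rank_oracle(ps$P), k - ord)
    expect_lt(max(abs(as.matrix(ps$P) %*% ps$nullspace)), 1e-10)
    ev <- eigen(as.matrix(ps$P), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
  # RW precision is the same structure matrix
  expect_equal(as.matrix(rw_precision(3, 1)),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)),
               ignore_attr = TRUE)
})

test_that("spatial penalty assembles the Kronecker sum with correct rank", {
  p1 <- penalty_matrix(3, 1); p2 <- penalty_matrix(3, 1)
  sp <- spatial_penalty(p1, p2, lambda1 = 1)
  expect_equal(rank_oracle(sp$P_s), 9 - 1)
  ns <- rep(1, 9)
  expect_lt(max(abs(as.matrix(sp$P_s) %*% ns)), 1e-10)

  sp5 <- spatial_penalty(p1, p2, lambda1 = 0.5)
  expect_equal(as.matrix(sp5$P_s),
               as.matrix(0.5 * sp$K1 + sp$K2), ignore_attr = TRUE)

  q1 <- penalty_matrix(5, 2); q2 <- penalty_matrix(5, 2)
  expect_equal(rank_oracle(spatial_penalty(q1, q2, 1)$P_s), 25 - 4)

  expect_error(spatial_penalty(p1, p2, -1), "invalid smoothing parameter")
})

test_that("ICAR precision matches the graph Laplacian", {
  r2 <- study_region(c("A", "B"), cbind(1:2, 1:2), rbind(c("A", "B")))
  expect_equal(as.matrix(icar_precision(r2)),
               rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)
  expect_equal(as.matrix(icar_precision(path_region(3))),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)),
               ignore_attr = TRUE)
  two_edges <- study_region(LETTERS[1:4], cbind(1:4, 1:4),
                            rbind(c("A", "B"), c("C", "D")))
  expect_equal(rank_oracle(icar_precision(two_edges)), 2)
})

test_that("interaction structures have the published ranks", {
  expect_equal(as.matrix(interaction_structure("I", I = 2, T = 3)$M_struct),
               diag(6), ignore_attr = TRUE)

  s2 <- interaction_structure("II", I = 2, T = 3, rw_order = 1)
  expect_equal(s2$rank, 2 * (3 - 1))
  expect_equal(rank_oracle(s2$M_struct), 4)

  QI <- icar_precision(path_region(3))
  s4 <- interaction_structure("IV", Q_I = QI, I = 3, T = 3, rw_order = 1)
  expect_equal(s4$rank, (3 - 1) * (3 - 1))
  expect_equal(rank_oracle(s4$M_struct), 4)

  s3 <- interaction_structure("III", Q_I = QI, I = 3, T = 4)
  expect_equal(s3$rank, (3 - 1) * 4)
  expect_equal(rank_oracle(s3$M_struct), 8)
  expect_error(interaction_structure("III", I = 3, T = 4), "required")
})

test_that("interaction constraint rows remove exactly the null space", {
  QI <- icar_precision(path_region(3))
  for (type in c("II", "III", "IV")) for (ord in 1:2) {
    s <- interaction_structure(type, Q_I = QI, I = 3, T = 5, rw_order = ord)
    A <- s$constraint_rows
    defect <- 15 - s$rank
    expect_equal(nrow(A), defect)
    expect_equal(rank_oracle(A), defect)
    # constraint rows span the null space of the structure matrix
    N <- eigen(as.matrix(s$M_struct), symmetric = TRUE)
    null_vecs <- N$vectors[, N$values < 1e-8 * max(N$values), drop = FALSE]
    expect_equal(rank_oracle(rbind(A, t(null_vecs))), defect)
  }
  expect_equal(nrow(interaction_structure("I", I = 3, T = 5)$constraint_rows), 0)
})

test_that("Kronecker eigenvalue identities hold on small instances", {
  QI <- as.matrix(icar_precision(path_region(3)))
  QT <- as.matrix(rw_precision(4, 1))
  s <- interaction_structure("IV", Q_I = Matrix::Matrix(QI, sparse = TRUE),
                             I = 3, T = 4, rw_order = 1)
  got <- sort(eigen(as.matrix(s$M_struct), symmetric = TRUE, only.values = TRUE)$values)
  want <- sort(as.numeric(outer(eigen(QT, symmetric = TRUE, only.values = TRUE)$values,
                                eigen(QI, symmetric = TRUE, only.values = TRUE)$values)))
  expect_equal(got, want, tolerance = 1e-10)
})
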