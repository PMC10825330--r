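test_that("a zero-parameter network outputs the scaled midpoint everywhere", {
  p <- ann_params(matrix(0, 3, 2), rep(0, 3), matrix(0, 2, 3), rep(0, 2))
  sc <- ann_scaling(c(0, 0), c(1, 1), c(10, 100), c(20, 200))
  out <- ann_forward(p, sc, rbind(c(0.2, 0.8), c(1, 0)))
  # logsig(0) = 0.5 scaled = midpoint of each response range
  expect_equal(unname(out), rbind(c(15, 150), c(15, 150)))
})

test_that("a 1-1-1 identity-weight network composes two sigmoids", {
  p <- ann_params(matrix(1, 1, 1), 0, matrix(1, 1, 1), 0)
  s <- uaextract:::ann_forward_scaled(p, matrix(0, 1, 1))
  expect_equal(drop(s), 1 / (1 + exp(-0.5)), tolerance = 1e-6)  # 0.62246
})

test_that("scaled outputs are strictly inside (0, 1) for any input", {
  set.seed(11)
  for (rep in 1:5) {
    p <- random_net(4, 6, 4, scale = 5)
    Xs <- matrix(runif(40, -3, 3), 10, 4)
    s <- uaextract:::ann_forward_scaled(p, Xs)
    expect_true(all(s > 0 & s < 1))
  }
})

test_that("input dimension mismatches are rejected", {
  p <- random_net(4, 3, 2)
  sc <- ann_scaling(rep(0, 4), rep(1, 4), rep(0, 2), rep(1, 2))
  expect_error(ann_forward(p, sc, c(1, 2, 3)), "dimension")
  expect_error(ann_params(matrix(0, 3, 2), rep(0, 2), matrix(0, 2, 3),
                          rep(0, 2)), "u rows")
})

test_that("connection-weights influence of a single path is the weight product", {
  p <- ann_params(matrix(2, 1, 1), 0, matrix(3, 1, 1), 0)
  ri <- relative_influence(p, "olden")
  expect_equal(drop(ri), 6, ignore_attr = TRUE)
})

test_that("connection-weights influence is linear in the output weights", {
  set.seed(3)
  p <- random_net(4, 5, 3)
  p2 <- ann_params(p$u, p$Th, 2 * p$w, p$To)
  expect_equal(relative_influence(p2), 2 * relative_influence(p),
               ignore_attr = TRUE)
})

test_that("influence signs match brute-force input sensitivities", {
  # oracle: mean central-difference d y_o / d x_i over 100 random inputs
  set.seed(21)
  checked <- 0
  for (rep in 1:6) {
    p <- random_net(4, 3, 2, scale = 0.8)
    ri <- relative_influence(p, "olden")
    X <- matrix(runif(400, 0.05, 0.95), 100, 4)
    h <- 1e-5
    for (i in 1:4) for (o in 1:2) {
      if (abs(ri[i, o]) < 0.5 * max(abs(ri))) next  # only well-determined ones
      Xp <- X; Xp[, i] <- Xp[, i] + h
      Xm <- X; Xm[, i] <- Xm[, i] - h
      sens <- mean((uaextract:::ann_forward_scaled(p, Xp)[, o] -
                      uaextract:::ann_forward_scaled(p, Xm)[, o]) / (2 * h))
      expect_equal(sign(sens), sign(ri[i, o]))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
})

test_that("Garson influences are nonnegative and sum to one per output", {
  set.seed(5)
  p <- random_net(4, 12, 4)
  g <- relative_influence(p, "garson")
  expect_true(all(g >= 0))
  expect_equal(unname(colSums(g)), rep(1, 4))
  expect_error(relative_influence(p, "unknown"))
})

test_that("the published weight table loads as a structurally valid 4-12-4 net", {
  v <- read_fixture("table2_ann_weights")$value
  expect_length(v, 112)
  expect_equal(v[1], 8.11)
  p <- load_published_ann()
  expect_equal(dim(p$u), c(12, 4))
  expect_length(p$Th, 12)
  expect_equal(dim(p$w), c(4, 12))
  expect_length(p$To, 4)
  s <- uaextract:::ann_forward_scaled(p, matrix(runif(20, 0.05, 0.95), 5, 4))
  expect_true(all(is.finite(s) & s > 0 & s < 1))
  expect_error(load_published_ann("other-layout"))
})

test_that("the published influence table carries the prose-quoted values", {
  t3 <- read_fixture("table3_influence")
  expect_equal(t3$dYP[t3$notation == "XP"], 0.412)
  expect_equal(t3$dYA[t3$notation == "XT"], 0.504)
  expect_equal(t3$dYF[t3$notation == "XP"], 0.968)
  # power has a positive influence on every response
  expect_true(all(t3[t3$notation == "XP", c("dYP", "dYA", "dYB", "dYF")] > 0))
})
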