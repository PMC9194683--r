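test_that("rotation encoder handles the degenerate and identity cases", {
  v <- c(0.3, -1.2, 0.5, 2)
  # single node: empty relation product, vector returned unchanged
  expect_equal(encode_instance_rotate(list(v), list()), v)
  # identity relations collapse the recursion to the arithmetic mean
  set.seed(1)
  for (i in 1:100) {
    n <- sample(2:5, 1); d <- 2 * sample(1:6, 1)
    vecs <- lapply(seq_len(n), function(i) rnorm(d))
    rels <- rep(list(rep(1 + 0i, d / 2)), n - 1)
    expect_equal(encode_instance_rotate(vecs, rels),
                 encode_instance_mean(vecs), tolerance = 1e-6)
  }
})

test_that("rotation encoder matches direct complex arithmetic", {
  # 3-node instance with hand-chosen phases, checked coordinate-wise
  v1 <- c(1, 0, 0, 1); v2 <- c(0, 1, 1, 0); v3 <- c(2, -1, 0.5, 0.5)
  th1 <- c(pi / 2, pi / 4); th2 <- c(-pi / 3, pi)
  got <- encode_instance_rotate(
    list(v1, v2, v3),
    list(complex(argument = th1), complex(argument = th2)))
  want <- oracle_encode(list(v1, v2, v3), list(th1, th2))
  expect_equal(got, want, tolerance = 1e-12)

  set.seed(2)
  for (i in 1:20) {
    n <- sample(2:5, 1); d <- 6
    vecs <- lapply(seq_len(n), function(i) rnorm(d))
    phs <- lapply(seq_len(n - 1), function(i) runif(d / 2, -pi, pi))
    expect_equal(
      encode_instance_rotate(vecs, lapply(phs, function(p)
        complex(argument = p))),
      oracle_encode(vecs, phs), tolerance = 1e-10)
  }
})

test_that("rotation encoder rejects invalid inputs", {
  expect_error(encode_instance_rotate(list(c(1, 2, 3)), list()), "even")
  expect_error(
    encode_instance_rotate(list(c(1, 0), c(0, 1)), list(2 + 0i)),
    "modulus")
  expect_error(encode_instance_mean(list()), "at least one")
})

test_that("mean encoder averages coordinate-wise", {
  v <- c(1, -2, 3)
  expect_equal(encode_instance_mean(list(v)), v)
  expect_equal(encode_instance_mean(list(v, -v)), c(0, 0, 0))
})

test_that("intra-metapath attention normalises and aggregates per head", {
  d <- 4; K <- 3
  set.seed(3)
  delta <- matrix(rnorm(2 * d * K), 2 * d, K)
  h <- rnorm(d)
  # a single instance takes all the attention
  enc1 <- matrix(rnorm(d), 1)
  r1 <- intra_aggregate(h, enc1, delta)
  expect_equal(unname(r1$alpha), matrix(1, 1, K))
  expect_equal(r1$embedding, rep(oracle_elu(enc1[1, ]), K),
               tolerance = 1e-12, ignore_attr = TRUE)
  # two identical encodings split the attention evenly
  enc2 <- rbind(enc1, enc1)
  r2 <- intra_aggregate(h, enc2, delta)
  expect_equal(unname(r2$alpha), matrix(0.5, 2, K))
  # attention sums to one per head on random inputs
  enc5 <- matrix(rnorm(5 * d), 5)
  r5 <- intra_aggregate(h, enc5, delta)
  expect_equal(unname(colSums(r5$alpha)), rep(1, K), tolerance = 1e-6)
})

test_that("intra-metapath attention matches a straight-line oracle", {
  d <- 4; K <- 2
  set.seed(4)
  delta <- matrix(rnorm(2 * d * K), 2 * d, K)
  h <- rnorm(d)
  encs <- matrix(rnorm(5 * d), 5)
  got <- intra_aggregate(h, encs, delta)
  for (k in 1:K) {
    e <- apply(encs, 1, function(enc)
      oracle_lrelu(sum(delta[, k] * c(h, enc)), 0.01))
    a <- oracle_softmax(e)
    expect_equal(got$alpha[, k], a, tolerance = 1e-12)
    expect_equal(got$embedding[((k - 1) * d + 1):(k * d)],
                 oracle_elu(colSums(a * encs)), tolerance = 1e-12)
  }
})

test_that("metapath summaries stay in (-1,1) and match the formula", {
  A <- 3; d <- 4
  W <- diag(1, A, d); b <- numeric(A)
  expect_equal(metapath_summary(matrix(0, 1, d), W, b), numeric(A))
  h <- c(0.5, -1, 2, 0)
  same <- rbind(h, h, h)
  expect_equal(metapath_summary(same, W, b),
               tanh((W %*% h)[, 1]), tolerance = 1e-12)
  set.seed(5)
  W2 <- matrix(rnorm(A * d), A); b2 <- rnorm(A)
  E <- matrix(rnorm(6 * d), 6)
  s <- metapath_summary(E, W2, b2)
  expect_true(all(abs(s) < 1))
  expect_equal(s, colMeans(tanh(E %*% t(W2) +
                                  matrix(b2, 6, A, byrow = TRUE))),
               tolerance = 1e-12)
})

test_that("inter-metapath attention weights metapaths by their summaries", {
  d <- 4; A <- 3
  E1 <- matrix(rnorm(8), 2); E2 <- matrix(rnorm(8), 2)
  c_att <- rnorm(A)
  # a single metapath gets weight one
  r1 <- inter_aggregate(list(E1), list(rnorm(A)), c_att)
  expect_equal(r1$beta, 1)
  expect_equal(r1$embedding, E1)
  # equal summaries share the weight equally
  s <- rnorm(A)
  r2 <- inter_aggregate(list(E1, E2), list(s, s), c_att)
  expect_equal(unname(r2$beta), c(0.5, 0.5))
  # three metapaths: match the straight-line computation
  set.seed(6)
  Es <- replicate(3, matrix(rnorm(8), 2), simplify = FALSE)
  ss <- replicate(3, rnorm(A), simplify = FALSE)
  r3 <- inter_aggregate(Es, ss, c_att)
  e <- vapply(ss, function(si) sum(c_att * si), 0)
  beta <- oracle_softmax(e)
  expect_equal(r3$beta, beta, tolerance = 1e-12)
  expect_equal(r3$embedding, beta[1] * Es[[1]] + beta[2] * Es[[2]] +
                 beta[3] * Es[[3]], tolerance = 1e-12)
  expect_equal(sum(r3$beta), 1, tolerance = 1e-6)
  expect_error(inter_aggregate(list(E1, E2[, 1:3]), list(s, s), c_att),
               "mismatch")
})

test_that("pair scores are symmetric, monotone, and sigmoid-valued", {
  expect_equal(predict_score(c(1, 0), c(0, 1)), 0.5)
  expect_equal(predict_score(c(1, 2), c(3, -1)), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  h <- c(0.4, -0.3, 1.1)
  g <- c(0.2, 0.9, -0.5)
  expect_identical(predict_score(h, g), predict_score(g, h))
  # score approaches 1 as the aligned norm grows
  expect_gt(predict_score(10 * h, 10 * h), 0.999999)
  # strictly increasing in the inner product
  ips <- seq(-3, 3, by = 0.5)
  scores <- vapply(ips, function(z) predict_score(c(z, 0), c(1, 0)), 0)
  expect_true(all(diff(scores) > 0))
  expect_error(predict_score(c(1, 2), c(1, 2, 3)), "mismatch")
})

test_that("cross-entropy loss has its closed-form values", {
  # perfect scores give (numerically) zero loss
  expect_lt(bce_loss(rep(1 - 1e-15, 3), rep(1e-15, 3)), 1e-8)
  # indifferent scores: n_pos = n_neg = n at 0.5 sums to 2n log 2
  n <- 7
  expect_equal(bce_loss(rep(0.5, n), rep(0.5, n)), 2 * n * log(2),
               tolerance = 1e-12)
  expect_equal(bce_loss(0.8, numeric(0)), -log(0.8), tolerance = 1e-12)
  expect_equal(bce_loss(rep(0.5, 2), rep(0.5, 2), reduction = "mean"),
               log(2), tolerance = 1e-12)
  # boundary scores are clamped, not infinite
  expect_message(val <- bce_loss(c(0, 0.5), 0.5), "clamped")
  expect_true(is.finite(val))
})
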