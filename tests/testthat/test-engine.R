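# The vectorised engine against naive straight-line computation, plus
# analytic gradients against finite differences.

small_config <- function(...) {
  training_config(hidden_dim = 4, heads = 2, attention_dim = 3,
                  layers = 1, dropout = 0, epochs = 1, neighbors = Inf,
                  ...)
}

test_that("one engine layer matches the straight-line oracle", {
  for (seed in 1:4) {
    net <- random_network(seed, n_m = 4, n_c = 3, n_d = 3, p = 0.5)
    cfg <- small_config(seed = seed)
    params <- init_params(net, cfg, seed + 100)
    got <- layer_forward(net, params, cfg)
    want <- oracle_layer(net, params, cfg, params$theta$emb)
    for (ty in names(want))
      expect_equal(got[[ty]], want[[ty]], tolerance = 1e-10,
                   info = paste("type", ty, "seed", seed))
  }
})

test_that("layer output is finite on the toy network and zero maps to zero", {
  net <- fixture_small()
  cfg <- small_config(seed = 1)
  params <- init_params(net, cfg, 2)
  H <- layer_forward(net, params, cfg)
  expect_true(all(vapply(H, function(M) all(is.finite(M)), TRUE)))
  # zeroing the output weights collapses every embedding to elu(0) = 0
  for (ty in names(params$theta$layers[[1]]))
    params$theta$layers[[1]][[ty]]$W_o[] <- 0
  H0 <- layer_forward(net, params, cfg)
  for (ty in names(H0))
    expect_equal(H0[[ty]], matrix(0, nrow(H0[[ty]]), ncol(H0[[ty]])))
})

test_that("embeddings are invariant to edge-list input order", {
  e_md <- rbind(c("m2", "d1"), c("m1", "d2"), c("m3", "d1"))
  e_mc <- rbind(c("m1", "c1"), c("m2", "c2"), c("m3", "c1"))
  e_dc <- rbind(c("d1", "c1"), c("d2", "c2"))
  net1 <- build_network(md = e_md, mc = e_mc, dc = e_dc)
  net2 <- build_network(md = e_md[3:1, ], mc = e_mc[c(2, 3, 1), ],
                        dc = e_dc[2:1, ])
  cfg <- small_config(seed = 5)
  params <- init_params(net1, cfg, 9)
  expect_equal(layer_forward(net1, params, cfg),
               layer_forward(net2, params, cfg), tolerance = 1e-12)
})

test_that("stacked layers equal repeated single-layer application", {
  net <- fixture_small()
  cfg2 <- training_config(hidden_dim = 4, heads = 2, attention_dim = 3,
                          layers = 2, dropout = 0, neighbors = Inf,
                          seed = 1)
  params <- init_params(net, cfg2, 3)
  engine <- mdpath:::build_engine(net, cfg2)
  einst <- mdpath:::cap_instances(engine, 1)
  full <- mdpath:::magnn_forward(engine, params, einst)$H
  H1 <- layer_forward(net, params, cfg2, layer = 1)
  H2 <- layer_forward(net, params, cfg2, H = H1, layer = 2)
  expect_equal(full, H2, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  sim <- generate_synthetic(synthetic_spec(n_m = 10, n_c = 4, n_d = 7,
                                           n_blocks = 2, p_in = 0.5,
                                           p_out = 0.1, seed = 9))
  net <- sim$network
  for (variant in c("full", "nb", "avg")) {
    cfg <- training_config(hidden_dim = 4, heads = 2, attention_dim = 3,
                           layers = 2, dropout = 0, neighbors = Inf,
                           seed = 5, variant = variant)
    engine <- mdpath:::build_engine(net, cfg)
    params <- init_params(net, cfg, 7)
    einst <- mdpath:::cap_instances(engine, 11)
    mi <- match(net$md[, 1], net$microbes)
    dj <- match(net$md[, 2], net$diseases)
    mi <- c(mi, rev(mi)); dj <- c(dj, dj)
    y <- rep(c(1L, 0L), each = length(mi) / 2)
    loss_at <- function(theta) {
      params$theta <- theta
      H <- mdpath:::magnn_forward(engine, params, einst)$H
      mdpath:::pair_loss(
        mdpath:::pair_scores(H$microbe, H$disease, mi, dj), y)
    }
    fwd <- mdpath:::magnn_forward(engine, params, einst,
                                  keep_cache = TRUE)
    s <- mdpath:::pair_scores(fwd$H$microbe, fwd$H$disease, mi, dj)
    dz <- (s - y) / length(s)
    d <- cfg$hidden_dim
    g_final <- list(
      microbe = mdpath:::add_rows(
        matrix(0, nrow(fwd$H$microbe), d), mi,
        dz * fwd$H$disease[dj, , drop = FALSE]),
      disease = mdpath:::add_rows(
        matrix(0, nrow(fwd$H$disease), d), dj,
        dz * fwd$H$microbe[mi, , drop = FALSE]))
    grads <- mdpath:::magnn_backward(engine, params, einst, fwd$caches,
                                     g_final)
    eps <- 1e-6
    check_leaf <- function(get, set, idx, label) {
      v <- get(params$theta)
      vp <- v; vp[idx] <- v[idx] + eps
      vm <- v; vm[idx] <- v[idx] - eps
      num <- (loss_at(set(params$theta, vp)) -
                loss_at(set(params$theta, vm))) / (2 * eps)
      ana <- get(grads)[idx]
      expect_equal(ana, num, tolerance = 1e-4,
                   info = paste(variant, label))
    }
    check_leaf(function(t) t$emb$microbe,
               function(t, v) { t$emb$microbe[] <- v; t }, 3,
               "microbe embedding")
    check_leaf(function(t) t$emb$drug,
               function(t, v) { t$emb$drug[] <- v; t }, 5,
               "drug embedding")
    if (variant != "avg") {
      check_leaf(function(t) t$phases[["disease|microbe"]],
                 function(t, v) { t$phases[["disease|microbe"]] <- v; t },
                 1, "md phase")
      check_leaf(function(t) t$phases[["drug|microbe"]],
                 function(t, v) { t$phases[["drug|microbe"]] <- v; t },
                 2, "mc phase")
    }
    for (l in 1:2) {
      check_leaf(function(t) t$layers[[l]]$microbe$delta[[1]],
                 function(t, v) { t$layers[[l]]$microbe$delta[[1]][] <- v; t },
                 4, paste("delta layer", l))
      check_leaf(function(t) t$layers[[l]]$disease$W_att,
                 function(t, v) { t$layers[[l]]$disease$W_att[] <- v; t },
                 2, paste("W_att layer", l))
      check_leaf(function(t) t$layers[[l]]$disease$c_att,
                 function(t, v) { t$layers[[l]]$disease$c_att <- v; t },
                 1, paste("c_att layer", l))
      check_leaf(function(t) t$layers[[l]]$microbe$W_o,
                 function(t, v) { t$layers[[l]]$microbe$W_o[] <- v; t },
                 6, paste("W_o layer", l))
    }
  }
})

test_that("nodes without any metapath instance fall back to themselves", {
  # m3 has a drug but no disease, so m-d-m has no instance for it
  net <- build_network(md = rbind(c("m1", "d1"), c("m2", "d1")),
                       mc = rbind(c("m1", "c1"), c("m3", "c1")),
                       dc = cbind("d1", "c1"))
  cfg <- small_config(seed = 2,
                      metapaths = list(microbe = "m-d-m",
                                       drug = "c-m-c",
                                       disease = "d-m-d"))
  params <- init_params(net, cfg, 4)
  H <- layer_forward(net, params, cfg)
  expect_true(all(is.finite(H$microbe)))
  # the fallback node agrees with the oracle, whose fallback is the
  # node's own vector as the sole instance encoding
  i3 <- match("m3", net$microbes)
  want <- oracle_layer(net, params, cfg, params$theta$emb)
  expect_equal(H$microbe[i3, ], want$microbe[i3, ], tolerance = 1e-10)
})

test_that("two training runs with one seed are identical", {
  sim <- generate_synthetic(synthetic_spec(n_m = 20, n_c = 8, n_d = 12,
                                           seed = 4))
  cfg <- training_config(hidden_dim = 8, heads = 2, attention_dim = 4,
                         epochs = 4, seed = 17)
  f1 <- train_model(sim$network, cfg)
  f2 <- train_model(sim$network, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$embeddings, f2$embeddings)
})
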