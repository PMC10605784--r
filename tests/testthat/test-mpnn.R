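# Graph encoder tests run at reduced width/depth: the architecture is
# identical to the full-size configuration and every property under test is
# size-independent.

small_graph_cfg <- function(family, ...) {
  model_config(family, hidden_size = 16, ffn_hidden = 8, batch_size = 64,
               ...)
}

test_that("molecular graphs carry directed bonds and ring structure", {
  g <- molecular_graphs(c("CCO", "C", "c1ccccc1"))
  expect_equal(nrow(g[[1]]$bonds), 4)  # 2 undirected bonds -> 4 directed
  expect_equal(g[[1]]$bonds$rev[g[[1]]$bonds$rev], 1:4)  # reverse is an involution
  expect_equal(nrow(g[[2]]$bonds), 0)  # methane: bondless heavy-atom graph
  expect_true(all(g[[3]]$ring_atom))
  expect_equal(ncol(g[[1]]$atom_features), 17)
})

test_that("latent encodings are invariant to atom ordering and sized by config", {
  ds <- synth_ds(30, seed = 41)
  p <- cross_merge(ds[1:8, ])
  m <- train_delta_graph(p, small_graph_cfg("graph_delta", epochs = 1, seed = 2))
  # same molecule written two ways encodes identically (sum readout is
  # permutation invariant; OpenBabel canonicalization happens upstream)
  z <- encode_molecule(m, c("c1ccccc1CCO", "OCCc1ccccc1", "C"))
  expect_equal(z[1, ], z[2, ], tolerance = 1e-6)
  expect_equal(ncol(z), 16)
  expect_true(all(is.finite(z[3, ])))  # bondless molecule encodes finitely
})

test_that("graph model training is seed-deterministic and self pairs are near zero", {
  ds <- synth_ds(30, seed = 41)
  p <- cross_merge(ds[1:10, ])
  m1 <- train_delta_graph(p, small_graph_cfg("graph_delta", epochs = 2, seed = 5))
  m2 <- train_delta_graph(p, small_graph_cfg("graph_delta", epochs = 2, seed = 5))
  expect_identical(predict_delta(m1, p), predict_delta(m2, p))
  # no architectural antisymmetry: self-pair predictions are generally not
  # exactly zero, just small after training on data that includes self pairs
  selfp <- p[p$first == p$second, , drop = FALSE]
  ps <- predict_delta(m1, selfp)
  expect_true(all(is.finite(ps)))
  expect_true(any(ps != 0))
  expect_error(model_config("graph_delta", epochs = 0), "epochs")
})

test_that("default epochs are 5 for the delta and 50 for the traditional graph model", {
  expect_equal(model_config("graph_delta")$epochs, 5L)
  expect_equal(model_config("graph_traditional")$epochs, 50L)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- model_config("graph_delta", hidden_size = 6, depth = 3, ffn_hidden = 4,
                      seed = 3)
  bat <- deltamol:::mpnn_batch(molecular_graphs(c("CCO", "c1ccccc1", "CC(=O)O")))
  set.seed(3)
  params <- list(enc1 = deltamol:::mpnn_init_encoder(cfg),
                 head = deltamol:::mpnn_init_head(cfg, 12))
  params$enc2 <- deltamol:::mpnn_init_encoder(cfg)
  i1 <- c(1, 2, 3, 1); i2 <- c(2, 3, 1, 1); y <- c(0.4, -1, 0.6, 0)
  loss <- function(pp) {
    c1 <- deltamol:::encoder_forward(pp$enc1, bat, cfg)
    c2 <- deltamol:::encoder_forward(pp$enc2, bat, cfg)
    U <- cbind(c1$G[i1, , drop = FALSE], c2$G[i2, , drop = FALSE])
    mean((deltamol:::head_forward(pp$head, U)$yhat - y)^2)
  }
  c1 <- deltamol:::encoder_forward(params$enc1, bat, cfg)
  c2 <- deltamol:::encoder_forward(params$enc2, bat, cfg)
  U <- cbind(c1$G[i1, , drop = FALSE], c2$G[i2, , drop = FALSE])
  hf <- deltamol:::head_forward(params$head, U)
  hb <- deltamol:::head_backward(params$head, U, hf, 2 * (hf$yhat - y) / length(y))
  dG1 <- deltamol:::scatter_rows(hb$dU[, 1:6, drop = FALSE], i1, 3)
  dG2 <- deltamol:::scatter_rows(hb$dU[, 7:12, drop = FALSE], i2, 3)
  grads <- list(enc1 = deltamol:::encoder_backward(params$enc1, bat, c1, dG1, cfg),
                enc2 = deltamol:::encoder_backward(params$enc2, bat, c2, dG2, cfg),
                head = hb$grads)
  eps <- 1e-6
  set.seed(9)
  for (top in names(params)) for (leaf in names(params[[top]])) {
    P <- params[[top]][[leaf]]
    for (ix in sample(length(P), min(4, length(P)))) {
      pp <- params; pp[[top]][[leaf]][ix] <- pp[[top]][[leaf]][ix] + eps
      pm <- params; pm[[top]][[leaf]][ix] <- pm[[top]][[leaf]][ix] - eps
      num <- (loss(pp) - loss(pm)) / (2 * eps)
      ana <- as.matrix(grads[[top]][[leaf]])[ix]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
})

test_that("encoder sharing halves the parameter sets and still trains", {
  ds <- synth_ds(30, seed = 41)
  p <- cross_merge(ds[1:8, ])
  m <- train_delta_graph(p, small_graph_cfg("graph_delta", epochs = 1, seed = 4,
                                            encoder_sharing = TRUE))
  expect_equal(m$fit$n_enc, 1L)
  expect_null(m$fit$params$enc2)
  expect_length(predict_delta(m, p), nrow(p))
})

test_that("the traditional graph model learns absolute values", {
  ds <- synth_ds(40, noise = 0.05, seed = 51)
  # small batches so 50 epochs of 40 molecules give enough gradient steps
  m <- train_traditional(ds, model_config("graph_traditional",
                                          hidden_size = 16, ffn_hidden = 8,
                                          batch_size = 16, epochs = 50,
                                          lr = 3e-3, seed = 6))
  v <- predict_value(m, ds$smiles)
  expect_true(all(is.finite(v)))
  # in-sample fit should at least correlate with truth after 30 epochs
  expect_gt(cor(v, ds$value), 0.5)
})
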