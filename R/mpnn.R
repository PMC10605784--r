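# Directed message passing neural network (D-MPNN) encoder with a
# feed-forward regression head, written directly on matrix primitives with
# hand-derived backpropagation and Adam updates.
#
# Encoder: each directed bond b = (u -> v) carries a hidden state. The state
# is initialised from [atom features of u ; bond features], then refined for
# `depth - 1` steps by summing the states of bonds incoming to u excluding
# the reverse bond (v -> u), a linear map, a skip connection to the initial
# state and a ReLU. Atom states are read out by summing incoming bond states
# through one more linear layer; the molecule latent is the sum (or mean)
# over atom states. Sum aggregation makes the latent invariant to atom
# ordering.
#
# Delta mode encodes the two molecules of a pair separately (separate
# weights unless `encoder_sharing`), concatenates the latents and regresses
# the difference; traditional mode encodes one molecule and regresses the
# absolute value.

relu <- function(x) pmax(x, 0)

# stack molecule graphs into one block-diagonal batch with index matrices:
# A (bond x bond) message aggregation, B (atom x bond) readout incidence,
# S (molecule x atom) latent pooling
mpnn_batch <- function(graphs) {
  natoms <- vapply(graphs, function(g) nrow(g$atom_features), integer(1))
  nbonds <- vapply(graphs, function(g) nrow(g$bonds), integer(1))
  atom_off <- cumsum(c(0L, natoms[-length(natoms)]))
  bond_off <- cumsum(c(0L, nbonds[-length(nbonds)]))
  X <- do.call(rbind, lapply(graphs, `[[`, "atom_features"))
  E <- do.call(rbind, lapply(graphs, `[[`, "bond_features"))
  src <- unlist(lapply(seq_along(graphs), function(i)
    graphs[[i]]$bonds$src + atom_off[i]))
  dst <- unlist(lapply(seq_along(graphs), function(i)
    graphs[[i]]$bonds$dst + atom_off[i]))
  rev <- unlist(lapply(seq_along(graphs), function(i)
    graphs[[i]]$bonds$rev + bond_off[i]))
  nb <- length(src); na <- nrow(X); nm <- length(graphs)
  Z <- cbind(X[src, , drop = FALSE], E)
  # A[b, b'] = 1 iff b' flows into the source atom of b and is not b's reverse
  ii <- integer(0); jj <- integer(0)
  if (nb > 0) {
    in_by_atom <- split(seq_len(nb), dst)
    for (b in seq_len(nb)) {
      inc <- in_by_atom[[as.character(src[b])]]
      inc <- inc[inc != rev[b]]
      if (length(inc)) { ii <- c(ii, rep.int(b, length(inc))); jj <- c(jj, inc) }
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nb, nb))
  B <- Matrix::sparseMatrix(i = dst, j = seq_len(nb), x = 1, dims = c(na, nb))
  S <- Matrix::sparseMatrix(
    i = rep(seq_len(nm), natoms), j = seq_len(na), x = 1, dims = c(nm, na))
  list(X = X, E = E, Z = Z, A = A, B = B, S = S,
       natoms = natoms, n_mol = nm)
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

mpnn_init_encoder <- function(config) {
  Fa <- atom_feature_dim(); Fb <- bond_feature_dim(); H <- config$hidden_size
  list(Wi = glorot(Fa + Fb, H), Wh = glorot(H, H), Wo = glorot(Fa + H, H))
}

mpnn_init_head <- function(config, latent_dim) {
  Fh <- config$ffn_hidden
  list(W1 = glorot(latent_dim, Fh), b1 = rep(0, Fh),
       w2 = glorot(Fh, 1), b2 = 0)
}

encoder_forward <- function(p, bat, config) {
  depth <- config$depth
  Zi <- bat$Z %*% p$Wi
  H0 <- relu(Zi)
  Hs <- vector("list", depth); Ms <- vector("list", depth)
  Hs[[1]] <- H0
  if (depth > 1) for (t in seq_len(depth - 1)) {
    M <- as.matrix(bat$A %*% Hs[[t]])
    Ms[[t]] <- M
    Hs[[t + 1]] <- relu(H0 + M %*% p$Wh)
  }
  Hf <- Hs[[depth]]
  Matom <- as.matrix(bat$B %*% Hf)
  AX <- cbind(bat$X, Matom)
  Ha <- relu(AX %*% p$Wo)
  G <- as.matrix(bat$S %*% Ha)
  if (config$aggregation == "mean") G <- G / bat$natoms
  list(G = G, H0 = H0, Hs = Hs, Ms = Ms, AX = AX, Ha = Ha)
}

encoder_backward <- function(p, bat, cache, dG, config) {
  depth <- config$depth
  if (config$aggregation == "mean") dG <- dG / bat$natoms
  dHa <- as.matrix(Matrix::crossprod(bat$S, dG)) * (cache$Ha > 0)
  dWo <- crossprod(cache$AX, dHa)
  dAX <- dHa %*% t(p$Wo)
  Fa <- ncol(bat$X)
  dHf <- as.matrix(Matrix::crossprod(bat$B, dAX[, (Fa + 1):ncol(dAX), drop = FALSE]))
  dH <- dHf
  dH0 <- 0; dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  if (depth > 1) for (t in rev(seq_len(depth - 1))) {
    dP <- dH * (cache$Hs[[t + 1]] > 0)
    dH0 <- dH0 + dP
    dWh <- dWh + crossprod(cache$Ms[[t]], dP)
    dH <- as.matrix(Matrix::crossprod(bat$A, dP %*% t(p$Wh)))
  }
  dH0 <- dH0 + dH
  dZi <- dH0 * (cache$H0 > 0)
  dWi <- as.matrix(Matrix::crossprod(bat$Z, dZi))
  list(Wi = dWi, Wh = dWh, Wo = dWo)
}

head_forward <- function(p, U) {
  A1 <- sweep(U %*% p$W1, 2, p$b1, "+")
  Hd <- relu(A1)
  yhat <- drop(Hd %*% p$w2) + p$b2
  list(yhat = yhat, A1 = A1, Hd = Hd)
}

head_backward <- function(p, U, cache, dy) {
  dy <- matrix(dy, ncol = 1)
  dw2 <- crossprod(cache$Hd, dy)
  db2 <- sum(dy)
  dA1 <- (dy %*% t(p$w2)) * (cache$A1 > 0)
  dW1 <- crossprod(U, dA1)
  db1 <- colSums(dA1)
  dU <- dA1 %*% t(p$W1)
  list(grads = list(W1 = dW1, b1 = db1, w2 = dw2, b2 = db2), dU = dU)
}

adam_init <- function(params) {
  flat <- unlist(params, recursive = FALSE)
  list(m = lapply(flat, function(x) x * 0), v = lapply(flat, function(x) x * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  flat_p <- unlist(params, recursive = FALSE)
  flat_g <- unlist(grads, recursive = FALSE)
  for (k in names(flat_p)) {
    g <- flat_g[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    flat_p[[k]] <- flat_p[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  # restore nesting
  out <- params
  for (top in names(params)) for (leaf in names(params[[top]]))
    out[[top]][[leaf]] <- flat_p[[paste(top, leaf, sep = ".")]]
  list(params = out, state = state)
}

# scatter pair-latent gradients back onto molecule latents
scatter_rows <- function(d, idx, n_mol) {
  P <- Matrix::sparseMatrix(i = seq_along(idx), j = idx, x = 1,
                            dims = c(length(idx), n_mol))
  as.matrix(Matrix::crossprod(P, d))
}

# shared trainer for graph_delta (pairs) and graph_traditional (records)
mpnn_train <- function(records, pairs, config) {
  delta_mode <- is.null(records)
  if (delta_mode) {
    smiles <- unique(c(pairs$smiles_1, pairs$smiles_2))
    y <- pairs$delta
    i1 <- match(pairs$smiles_1, smiles)
    i2 <- match(pairs$smiles_2, smiles)
  } else {
    smiles <- records$smiles
    y <- records$value
  }
  graphs <- molecular_graphs(smiles)
  bat <- mpnn_batch(graphs)
  H <- config$hidden_size
  y_mean <- mean(y); y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  ys <- (y - y_mean) / y_sd
  n_enc <- if (delta_mode && !config$encoder_sharing) 2L else 1L
  latent_dim <- if (delta_mode) 2L * H else H
  with_seed(config$seed, {
    params <- list()
    for (e in seq_len(n_enc)) params[[paste0("enc", e)]] <- mpnn_init_encoder(config)
    params$head <- mpnn_init_head(config, latent_dim)
    opt <- adam_init(params)
    n_obs <- length(ys)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_obs)
      starts <- seq(1, n_obs, by = config$batch_size)
      for (s in starts) {
        sel <- ord[s:min(s + config$batch_size - 1, n_obs)]
        caches <- lapply(seq_len(n_enc), function(e)
          encoder_forward(params[[paste0("enc", e)]], bat, config))
        if (delta_mode) {
          G1 <- caches[[1]]$G
          G2 <- caches[[min(2, n_enc)]]$G
          U <- cbind(G1[i1[sel], , drop = FALSE], G2[i2[sel], , drop = FALSE])
        } else {
          U <- caches[[1]]$G[sel, , drop = FALSE]
        }
        hf <- head_forward(params$head, U)
        resid <- hf$yhat - ys[sel]
        dy <- 2 * resid / length(sel)
        hb <- head_backward(params$head, U, hf, dy)
        grads <- list()
        if (delta_mode) {
          dG1 <- scatter_rows(hb$dU[, 1:H, drop = FALSE], i1[sel], bat$n_mol)
          dG2 <- scatter_rows(hb$dU[, (H + 1):(2 * H), drop = FALSE], i2[sel],
                              bat$n_mol)
          if (n_enc == 2) {
            grads$enc1 <- encoder_backward(params$enc1, bat, caches[[1]], dG1, config)
            grads$enc2 <- encoder_backward(params$enc2, bat, caches[[2]], dG2, config)
          } else {
            grads$enc1 <- encoder_backward(params$enc1, bat, caches[[1]],
                                           dG1 + dG2, config)
          }
        } else {
          dG <- scatter_rows(hb$dU, sel, bat$n_mol)
          grads$enc1 <- encoder_backward(params$enc1, bat, caches[[1]], dG, config)
        }
        grads$head <- hb$grads
        upd <- adam_step(params, grads, opt, config$lr)
        params <- upd$params
        opt <- upd$state
      }
    }
    new_delta_model(config, if (delta_mode) "delta" else "traditional",
                    fit = list(params = params, n_enc = n_enc,
                               y_mean = y_mean, y_sd = y_sd))
  })
}

#' Encode molecules to latent vectors
#'
#' Runs the fitted message-passing encoder (the first encoder, for a
#' two-encoder delta model) on a set of molecules.
#'
#' @param model a graph-family `delta_model`.
#' @param smiles character vector of SMILES.
#' @return matrix (molecules x hidden_size) of latent representations.
#' @export
encode_molecule <- function(model, smiles) {
  stopifnot(inherits(model, "delta_model"),
            model$family %in% c("graph_delta", "graph_traditional"))
  bat <- mpnn_batch(molecular_graphs(smiles))
  encoder_forward(model$fit$params$enc1, bat, model$config)$G
}

mpnn_predict_values <- function(model, smiles) {
  bat <- mpnn_batch(molecular_graphs(smiles))
  G <- encoder_forward(model$fit$params$enc1, bat, model$config)$G
  hf <- head_forward(model$fit$params$head, G)
  hf$yhat * model$fit$y_sd + model$fit$y_mean
}

mpnn_predict_deltas <- function(model, pairs) {
  smiles <- unique(c(pairs$smiles_1, pairs$smiles_2))
  bat <- mpnn_batch(molecular_graphs(smiles))
  p <- model$fit$params
  G1 <- encoder_forward(p$enc1, bat, model$config)$G
  G2 <- if (model$fit$n_enc == 2)
    encoder_forward(p$enc2, bat, model$config)$G else G1
  U <- cbind(G1[match(pairs$smiles_1, smiles), , drop = FALSE],
             G2[match(pairs$smiles_2, smiles), , drop = FALSE])
  hf <- head_forward(p$head, U)
  hf$yhat * model$fit$y_sd + model$fit$y_mean
}
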