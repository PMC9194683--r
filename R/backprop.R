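# Reverse-mode gradients of the full forward pass, mirroring
# model-engine.R stage by stage. Gradients are accumulated into a tree
# with the same shape as params$theta, which the Adam step walks.

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

# M[rows named by idx] += column-wise sums of G grouped by idx
add_rows <- function(M, idx, G) {
  rs <- rowsum(G, idx)
  r <- as.integer(rownames(rs))
  M[r, ] <- M[r, , drop = FALSE] + rs
  M
}

# gradient of one metapath's instance encoding w.r.t. node embeddings
# and relation phases; mutates the accumulator environment `acc`
encoder_backward <- function(acc, H, theta, inst, mp, steps, variant,
                             g_enc) {
  len <- length(mp$types)
  if (variant == "avg") {
    g <- g_enc / len
    for (t in seq_len(len))
      acc$g_H[[mp$types[t]]] <- add_rows(acc$g_H[[mp$types[t]]],
                                         inst[, t], g)
    return(invisible(NULL))
  }
  d2 <- ncol(g_enc) / 2
  odd <- seq(1, 2 * d2, by = 2); even <- seq(2, 2 * d2, by = 2)
  if (variant == "nb" && len > 2) {
    th <- Reduce(`+`, lapply(steps, function(s) s$sign * theta[[s$key]]))
    rot1 <- rotate_rows(H[[mp$types[1]]][inst[, 1], , drop = FALSE], th)
    g <- g_enc / 2
    acc$g_H[[mp$types[len]]] <- add_rows(acc$g_H[[mp$types[len]]],
                                         inst[, len], g)
    gth <- colSums(-rot1[, even, drop = FALSE] * g[, odd, drop = FALSE] +
                     rot1[, odd, drop = FALSE] * g[, even, drop = FALSE])
    for (s in steps)
      acc$g_phases[[s$key]] <- acc$g_phases[[s$key]] + s$sign * gth
    g1 <- rotate_rows(g, -th)
    acc$g_H[[mp$types[1]]] <- add_rows(acc$g_H[[mp$types[1]]],
                                       inst[, 1], g1)
    return(invisible(NULL))
  }
  # full rotation encoder: recompute the per-step rotated accumulators
  enc <- encode_instances(H, theta, inst, mp, steps, "full",
                          keep_steps = TRUE)
  g <- g_enc / len
  for (t in len:2) {
    acc$g_H[[mp$types[t]]] <- add_rows(acc$g_H[[mp$types[t]]],
                                       inst[, t], g)
    s <- steps[[t - 1]]
    r <- enc$rots[[t]]
    gth <- colSums(-r[, even, drop = FALSE] * g[, odd, drop = FALSE] +
                     r[, odd, drop = FALSE] * g[, even, drop = FALSE])
    acc$g_phases[[s$key]] <- acc$g_phases[[s$key]] + s$sign * gth
    g <- rotate_rows(g, -s$sign * theta[[s$key]])
  }
  acc$g_H[[mp$types[1]]] <- add_rows(acc$g_H[[mp$types[1]]], inst[, 1], g)
  invisible(NULL)
}

# Full backward pass. g_Hfinal: named list of gradients w.r.t. the final
# embeddings (types may be omitted; missing types get zero gradient).
# Returns a gradient tree mirroring params$theta.
magnn_backward <- function(engine, params, einst, caches, g_Hfinal) {
  cfg <- engine$config
  d <- params$meta$d; K <- params$meta$K; L <- params$meta$L
  slope <- cfg$leaky_slope
  grads <- list(emb = NULL, phases = zero_like(params$theta$phases),
                layers = vector("list", L))
  acc <- new.env(parent = emptyenv())
  acc$g_phases <- grads$phases
  g_H <- list()
  for (ty in names(engine$catalog)) {
    n_ty <- engine$idx$n[[ty]]
    g_H[[ty]] <- if (!is.null(g_Hfinal[[ty]])) g_Hfinal[[ty]] else
      matrix(0, n_ty, d)
  }
  for (l in L:1) {
    cache <- caches[[l]]
    lpar <- params$theta$layers[[l]]
    g_lpar <- zero_like(lpar)
    acc$g_H <- lapply(cache$H, function(M) matrix(0, nrow(M), ncol(M)))
    for (ty in names(engine$catalog)) {
      tc <- cache[[ty]]
      g_out_pre <- g_H[[ty]] * elu_grad_out(tc$Hout)
      g_lpar[[ty]]$W_o <- g_lpar[[ty]]$W_o + t(g_out_pre) %*% tc$Fm
      g_F <- g_out_pre %*% lpar[[ty]]$W_o
      S <- length(tc$hM)
      g_beta <- vapply(seq_len(S), function(p) sum(g_F * tc$hM[[p]]), 0)
      g_hM <- lapply(seq_len(S), function(p) tc$beta[p] * g_F)
      g_e <- tc$beta * (g_beta - sum(tc$beta * g_beta))
      n_ty <- nrow(tc$Hout)
      for (p in seq_len(S)) {
        g_lpar[[ty]]$c_att <- g_lpar[[ty]]$c_att + g_e[p] * tc$s[[p]]
        g_T <- matrix(g_e[p] * lpar[[ty]]$c_att, n_ty,
                      params$meta$attn_dim, byrow = TRUE) / n_ty
        g_pre <- g_T * (1 - tc$Tn[[p]]^2)
        g_lpar[[ty]]$W_att <- g_lpar[[ty]]$W_att +
          t(g_pre) %*% tc$hM[[p]]
        g_lpar[[ty]]$b_att <- g_lpar[[ty]]$b_att + colSums(g_pre)
        g_hM[[p]] <- g_hM[[p]] + g_pre %*% lpar[[ty]]$W_att
      }
      for (p in seq_len(S)) {
        mc <- tc$mcache[[p]]
        g_hMp_pre <- g_hM[[p]] * elu_grad_out(mc$hM)
        if (isTRUE(mc$empty)) {
          for (k in seq_len(K)) {
            cols <- ((k - 1) * d + 1):(k * d)
            acc$g_H[[ty]] <- acc$g_H[[ty]] +
              g_hMp_pre[, cols, drop = FALSE]
          }
          next
        }
        ei <- mc$ei
        mp <- mc$mp
        if (length(ei$missing) > 0L) {
          for (k in seq_len(K)) {
            cols <- ((k - 1) * d + 1):(k * d)
            acc$g_H[[ty]][ei$missing, ] <-
              acc$g_H[[ty]][ei$missing, , drop = FALSE] +
              g_hMp_pre[ei$missing, cols, drop = FALSE]
          }
        }
        n_i <- nrow(mc$enc)
        g_enc <- matrix(0, n_i, d)
        g_alpha <- matrix(0, n_i, K)
        for (k in seq_len(K)) {
          cols <- ((k - 1) * d + 1):(k * d)
          Gk <- g_hMp_pre[ei$ugroups, cols,
                          drop = FALSE][ei$gidx, , drop = FALSE]
          g_enc <- g_enc + mc$alpha[, k] * Gk
          g_alpha[, k] <- rowSums(Gk * mc$enc)
        }
        if (!is.null(mc$amask))
          g_alpha <- g_alpha * mc$amask / (1 - cache$p_drop)
        t1 <- mc$alpha_raw * g_alpha
        gsum <- rowsum(t1, ei$group)[ei$gidx, , drop = FALSE]
        g_E <- t1 - mc$alpha_raw * gsum
        g_Epre <- g_E * ifelse(mc$Epre_sign, 1, slope)
        U <- cbind(cache$H[[ty]][ei$group, , drop = FALSE], mc$enc)
        delta <- lpar[[ty]]$delta[[mp$name]]
        g_lpar[[ty]]$delta[[mp$name]] <-
          g_lpar[[ty]]$delta[[mp$name]] + t(U) %*% g_Epre
        g_U <- g_Epre %*% t(delta)
        acc$g_H[[ty]] <- add_rows(acc$g_H[[ty]], ei$group,
                                  g_U[, 1:d, drop = FALSE])
        g_enc <- g_enc + g_U[, (d + 1):(2 * d), drop = FALSE]
        encoder_backward(acc, cache$H, params$theta$phases, ei$inst, mp,
                         engine$steps[[ty]][[p]], engine$variant, g_enc)
      }
    }
    grads$layers[[l]] <- g_lpar
    if (cache$p_drop > 0) {
      for (ty in names(acc$g_H))
        acc$g_H[[ty]] <- acc$g_H[[ty]] * cache$masks[[ty]] /
          (1 - cache$p_drop)
    }
    g_H <- acc$g_H
  }
  grads$emb <- g_H
  grads$phases <- acc$g_phases
  grads
}

# One Adam update over the parameter/gradient trees. `state` carries the
# first/second-moment trees and the step counter; weight decay is classic
# L2 added to the gradient of every leaf except the relation phases.
adam_init <- function(theta) {
  list(m = zero_like(theta), v = zero_like(theta), t = 0L)
}

adam_step <- function(theta, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(th, g, m, v, decay) {
    if (is.list(th)) {
      out_th <- th; out_m <- m; out_v <- v
      nms <- names(th)
      for (i in seq_along(th)) {
        dec <- decay && !identical(nms[i], "phases")
        r <- upd(th[[i]], g[[i]], m[[i]], v[[i]], dec)
        out_th[[i]] <- r$th; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      return(list(th = out_th, m = out_m, v = out_v))
    }
    if (decay && weight_decay > 0) g <- g + weight_decay * th
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    th <- th - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(th = th, m = m, v = v)
  }
  r <- upd(theta, grads, state$m, state$v, TRUE)
  list(theta = r$th,
       state = list(m = r$m, v = r$v, t = state$t))
}
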