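# Vectorised forward pass of the metapath-aggregated attention network.
# All instances of a metapath are processed as one integer index matrix;
# attention heads are computed in a single matrix product and normalised
# group-wise (per target node) with rowsum().

canonical_rel <- function(ta, tb) paste(sort(c(ta, tb)), collapse = "|")
rel_sign <- function(ta, tb) if (ta == sort(c(ta, tb))[1]) 1 else -1

# rotate the d/2 complex coordinates of every row of X by angles theta
# (interleaved real/imaginary layout)
rotate_rows <- function(X, theta) {
  n <- nrow(X)
  d2 <- length(theta)
  re <- X[, seq(1, 2 * d2, by = 2), drop = FALSE]
  im <- X[, seq(2, 2 * d2, by = 2), drop = FALSE]
  co <- rep(cos(theta), each = n)
  si <- rep(sin(theta), each = n)
  out <- X
  out[, seq(1, 2 * d2, by = 2)] <- re * co - im * si
  out[, seq(2, 2 * d2, by = 2)] <- re * si + im * co
  out
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise model parameters
#'
#' Creates every learnable quantity of the model for a given network
#' size, configuration and metapath catalog: one embedding matrix per
#' node type (the linear map applied to one-hot initial features), one
#' phase vector per relation (relation vectors are unit-modulus complex
#' numbers stored as phase angles, so unit modulus is structural), and
#' per layer and node type the per-metapath, per-head instance-attention
#' vectors, the semantic-attention map, and the output weights.
#'
#' @param net A [tripartite_network][build_network] (only node counts are
#'   used).
#' @param config A [training_config()].
#' @param seed Integer seed for the random initialisation (Glorot uniform
#'   for matrices, uniform phases in (-pi, pi)).
#' @return An object of class `md_params` with elements `meta` (sizes)
#'   and `theta` (nested list of numeric arrays).
#' @export
init_params <- function(net, config, seed = config$seed) {
  d <- config$hidden_dim; K <- config$heads; A <- config$attention_dim
  L <- config$layers
  counts <- node_counts(net)
  catalog <- active_catalog(config$metapaths, counts)
  with_seed(seed, {
    emb <- list()
    nmap <- c(microbe = counts[["n_m"]], drug = counts[["n_c"]],
              disease = counts[["n_d"]])
    for (ty in names(catalog)) emb[[ty]] <- glorot(nmap[[ty]], d)
    phases <- list()
    for (key in c("disease|microbe", "drug|microbe", "disease|drug"))
      phases[[key]] <- stats::runif(d / 2, -pi, pi)
    layers <- vector("list", L)
    for (l in seq_len(L)) {
      lay <- list()
      for (ty in names(catalog)) {
        mp_names <- vapply(catalog[[ty]], function(m) m$name, "")
        delta <- stats::setNames(
          lapply(mp_names, function(nm) glorot(2 * d, K)), mp_names)
        lay[[ty]] <- list(delta = delta,
                          W_att = glorot(A, K * d),
                          b_att = numeric(A),
                          c_att = glorot(A, 1)[, 1],
                          W_o = glorot(d, K * d))
      }
      layers[[l]] <- lay
    }
    structure(list(meta = list(d = d, K = K, attn_dim = A, L = L,
                               counts = nmap,
                               types = names(catalog)),
                   theta = list(emb = emb, phases = phases,
                                layers = layers)),
              class = "md_params")
  })
}

# parse the catalog and drop node types that are absent from the network
active_catalog <- function(metapaths, counts) {
  nmap <- c(microbe = counts[["n_m"]], drug = counts[["n_c"]],
            disease = counts[["n_d"]])
  out <- list()
  for (ty in c("microbe", "drug", "disease")) {
    if (nmap[[ty]] == 0L) next
    specs <- metapaths[[ty]]
    if (is.null(specs) || length(specs) == 0L)
      stop("metapath catalog has no entry for type '", ty, "'")
    out[[ty]] <- lapply(specs, parse_metapath)
  }
  out
}

# Precompute everything about a (network, config) pair that does not
# change across epochs: the adjacency index, the full enumeration of
# every metapath's instances, and the relation key/sign of every step.
build_engine <- function(net, config) {
  idx <- network_index(net)
  catalog <- active_catalog(config$metapaths, node_counts(net))
  # a metapath is usable only if every relation along it has edges
  inst_full <- list(); steps <- list()
  for (ty in names(catalog)) {
    inst_full[[ty]] <- list(); steps[[ty]] <- list()
    for (p in seq_along(catalog[[ty]])) {
      mp <- catalog[[ty]][[p]]
      inst_full[[ty]][[p]] <- enumerate_instances(idx, mp)
      steps[[ty]][[p]] <- lapply(seq_len(length(mp$types) - 1), function(t)
        list(key = canonical_rel(mp$types[t], mp$types[t + 1]),
             sign = rel_sign(mp$types[t], mp$types[t + 1])))
    }
  }
  list(idx = idx, catalog = catalog, inst_full = inst_full, steps = steps,
       config = config, variant = config$variant)
}

# Per-epoch instance subsample: cap each target node at k instances,
# uniformly without replacement, and precompute the group bookkeeping
# the softmax needs.
cap_instances <- function(engine, seed) {
  k <- engine$config$neighbors
  with_seed(seed, {
    out <- list()
    for (ty in names(engine$catalog)) {
      out[[ty]] <- list()
      n_ty <- engine$idx$n[[ty]]
      for (p in seq_along(engine$catalog[[ty]])) {
        full <- engine$inst_full[[ty]][[p]]
        if (nrow(full) > 0L) {
          rows <- split(seq_len(nrow(full)), full[, 1])
          over <- vapply(rows, length, 0L) > k
          if (any(over))
            rows[over] <- lapply(rows[over], function(r)
              sort(sample(r, k)))
          inst <- full[unlist(rows, use.names = FALSE), , drop = FALSE]
        } else {
          inst <- full
        }
        group <- inst[, 1]
        ugroups <- sort(unique(group))
        out[[ty]][[p]] <- list(
          inst = inst, group = group, ugroups = ugroups,
          gidx = match(group, ugroups),
          sp = split(seq_len(nrow(inst)), group),
          missing = setdiff(seq_len(n_ty), ugroups))
      }
    }
    out
  })
}

# group-wise column softmax: E is instances x K, sp splits row indices
# by target node, gidx maps each row to its group's position
group_softmax <- function(E, sp, gidx, group) {
  gmax <- matrix(0, length(sp), ncol(E))
  for (k in seq_len(ncol(E)))
    gmax[, k] <- vapply(sp, function(r) max(E[r, k]), 0)
  ex <- exp(E - gmax[gidx, , drop = FALSE])
  denom <- rowsum(ex, group)
  ex / denom[gidx, , drop = FALSE]
}

# encode all instances of one metapath; returns the encoding matrix and,
# when keep_steps, the per-step accumulators needed for gradients
encode_instances <- function(H, theta, inst, mp, steps, variant,
                             keep_steps = FALSE) {
  len <- length(mp$types)
  n <- nrow(inst)
  if (variant == "avg") {
    acc <- H[[mp$types[1]]][inst[, 1], , drop = FALSE]
    for (t in 2:len)
      acc <- acc + H[[mp$types[t]]][inst[, t], , drop = FALSE]
    return(list(enc = acc / len))
  }
  if (variant == "nb" && len > 2) {
    th <- Reduce(`+`, lapply(steps, function(s) s$sign * theta[[s$key]]))
    rot1 <- rotate_rows(H[[mp$types[1]]][inst[, 1], , drop = FALSE], th)
    enc <- (H[[mp$types[len]]][inst[, len], , drop = FALSE] + rot1) / 2
    return(list(enc = enc, theta_comp = th, rot1 = rot1))
  }
  acc <- H[[mp$types[1]]][inst[, 1], , drop = FALSE]
  rots <- if (keep_steps) vector("list", len) else NULL
  for (t in 2:len) {
    s <- steps[[t - 1]]
    r <- rotate_rows(acc, s$sign * theta[[s$key]])
    if (keep_steps) rots[[t]] <- r
    acc <- H[[mp$types[t]]][inst[, t], , drop = FALSE] + r
  }
  list(enc = acc / len, rots = rots)
}

# Forward pass of one layer for every node type. Returns the new H and
# (when keep_cache) everything the backward pass reuses.
forward_layer <- function(engine, params, lpar, Hraw, einst, train,
                          keep_cache = FALSE) {
  cfg <- engine$config
  d <- params$meta$d; K <- params$meta$K
  p_drop <- if (train) cfg$dropout else 0
  H <- Hraw; masks <- list()
  if (p_drop > 0) {
    for (ty in names(H)) {
      m <- matrix(stats::runif(length(H[[ty]])) >= p_drop,
                  nrow(H[[ty]]), d)
      masks[[ty]] <- m
      H[[ty]] <- H[[ty]] * m / (1 - p_drop)
    }
  }
  Hnew <- list(); cache <- list(H = H, masks = masks, p_drop = p_drop)
  for (ty in names(engine$catalog)) {
    n_ty <- engine$idx$n[[ty]]
    S <- length(engine$catalog[[ty]])
    hM <- vector("list", S); mcache <- vector("list", S)
    for (p in seq_len(S)) {
      mp <- engine$catalog[[ty]][[p]]
      ei <- einst[[ty]][[p]]
      delta <- lpar[[ty]]$delta[[mp$name]]
      if (nrow(ei$inst) == 0L) {
        # no instances anywhere: every node falls back to itself
        hMp <- elu(do.call(cbind, rep(list(H[[ty]]), K)))
        hM[[p]] <- hMp
        mcache[[p]] <- list(ei = ei, hM = hMp, empty = TRUE)
        next
      }
      encs <- encode_instances(H, params$theta$phases, ei$inst, mp,
                               engine$steps[[ty]][[p]], engine$variant,
                               keep_steps = FALSE)
      enc <- encs$enc
      U <- cbind(H[[ty]][ei$group, , drop = FALSE], enc)
      Epre <- U %*% delta
      E <- leaky_relu(Epre, cfg$leaky_slope)
      alpha_raw <- group_softmax(E, ei$sp, ei$gidx, ei$group)
      if (p_drop > 0) {
        amask <- matrix(stats::runif(length(alpha_raw)) >= p_drop,
                        nrow(alpha_raw), K)
        alpha <- alpha_raw * amask / (1 - p_drop)
      } else {
        amask <- NULL
        alpha <- alpha_raw
      }
      pre <- matrix(0, n_ty, K * d)
      for (k in seq_len(K)) {
        Sk <- rowsum(enc * alpha[, k], ei$group)
        pre[ei$ugroups, ((k - 1) * d + 1):(k * d)] <- Sk
      }
      if (length(ei$missing) > 0L) {
        fb <- H[[ty]][ei$missing, , drop = FALSE]
        for (k in seq_len(K))
          pre[ei$missing, ((k - 1) * d + 1):(k * d)] <- fb
      }
      hMp <- elu(pre)
      hM[[p]] <- hMp
      mcache[[p]] <- list(ei = ei, enc = enc, E = E, Epre_sign = Epre > 0,
                          alpha_raw = alpha_raw, amask = amask,
                          alpha = alpha, hM = hMp, mp = mp)
    }
    # semantic attention across the S metapaths
    W_att <- lpar[[ty]]$W_att; b_att <- lpar[[ty]]$b_att
    c_att <- lpar[[ty]]$c_att; W_o <- lpar[[ty]]$W_o
    Tn <- lapply(hM, function(M)
      tanh(M %*% t(W_att) +
             matrix(b_att, nrow(M), length(b_att), byrow = TRUE)))
    s <- lapply(Tn, colMeans)
    e <- vapply(s, function(si) sum(c_att * si), 0)
    beta <- softmax(e)
    Fm <- Reduce(`+`, Map(function(b, M) b * M, beta, hM))
    Hout <- elu(Fm %*% t(W_o))
    Hnew[[ty]] <- Hout
    if (keep_cache)
      cache[[ty]] <- list(mcache = mcache, hM = hM, Tn = Tn, s = s,
                          beta = beta, Fm = Fm, Hout = Hout)
  }
  list(H = Hnew, cache = if (keep_cache) cache else NULL)
}

# Full forward pass through all layers. Returns per-layer caches (for
# backprop) and the final embeddings.
magnn_forward <- function(engine, params, einst, train = FALSE,
                          keep_cache = FALSE) {
  H <- params$theta$emb
  caches <- if (keep_cache) vector("list", params$meta$L) else NULL
  for (l in seq_len(params$meta$L)) {
    res <- forward_layer(engine, params, params$theta$layers[[l]], H,
                         einst, train, keep_cache)
    if (keep_cache) caches[[l]] <- res$cache
    H <- res$H
  }
  list(H = H, caches = caches)
}

#' Run one aggregation layer over a network
#'
#' Computes one full layer of the model for every node type: metapath
#' instances are enumerated (optionally capped at `neighbors` per node),
#' encoded, aggregated within each metapath by multi-head attention, and
#' fused across metapaths by semantic attention, followed by the layer's
#' linear map and activation. Deterministic (no dropout). Intended for
#' inspection and testing; training uses the same code path internally.
#'
#' @param net A [tripartite_network][build_network].
#' @param params [init_params()] output.
#' @param config The [training_config()] the parameters were built for.
#' @param H Optional named list of input embedding matrices per node
#'   type; defaults to the layer-0 one-hot projection (the embedding
#'   matrices in `params`).
#' @param layer Which layer's parameters to apply.
#' @param sample_seed Seed for the instance cap (irrelevant when
#'   `neighbors` exceeds every instance count).
#' @return Named list of updated embedding matrices per node type.
#' @export
layer_forward <- function(net, params, config, H = NULL, layer = 1,
                          sample_seed = 1) {
  stopifnot(inherits(params, "md_params"), layer >= 1,
            layer <= params$meta$L)
  engine <- build_engine(net, config)
  einst <- cap_instances(engine, sample_seed)
  if (is.null(H)) H <- params$theta$emb
  forward_layer(engine, params, params$theta$layers[[layer]], H, einst,
                train = FALSE)$H
}

#' Final node embeddings of a trained model
#'
#' The last layer's output for every node type, as computed with the
#' best-validation parameters at the end of training.
#'
#' @param model An [md_model][train_model] object.
#' @return Named list of embedding matrices (rows named by node id).
#' @export
final_embeddings <- function(model) {
  stopifnot(inherits(model, "md_model"))
  model$embeddings
}
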