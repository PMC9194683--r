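# Independent straight-line oracles used to pin down the vectorised
# implementation. Everything here is deliberately naive: explicit DFS,
# R complex arithmetic, per-node loops.

# all node sequences following a type pattern, by depth-first search
oracle_instances <- function(net, types, start_id) {
  ids <- list(microbe = net$microbes, drug = net$drugs,
              disease = net$diseases)
  edge_ok <- function(a, ta, b, tb) {
    has <- function(m, x, y) any(m[, 1] == x & m[, 2] == y)
    if (ta == "microbe" && tb == "disease") has(net$md, a, b)
    else if (ta == "disease" && tb == "microbe") has(net$md, b, a)
    else if (ta == "microbe" && tb == "drug") has(net$mc, a, b)
    else if (ta == "drug" && tb == "microbe") has(net$mc, b, a)
    else if (ta == "disease" && tb == "drug") has(net$dc, a, b)
    else if (ta == "drug" && tb == "disease") has(net$dc, b, a)
    else FALSE
  }
  out <- list()
  grow <- function(path) {
    t <- length(path)
    if (t == length(types)) {
      out[[length(out) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (nxt in ids[[types[t + 1]]]) {
      if (edge_ok(path[t], types[t], nxt, types[t + 1]))
        grow(c(path, nxt))
    }
  }
  grow(start_id)
  out
}

# complex-arithmetic rotation encoder, one instance at a time
oracle_encode <- function(vectors, phase_list) {
  tocplx <- function(v) complex(real = v[c(TRUE, FALSE)],
                                imaginary = v[c(FALSE, TRUE)])
  fromcplx <- function(z) as.vector(rbind(Re(z), Im(z)))
  acc <- tocplx(vectors[[1]])
  for (t in seq_along(phase_list))
    acc <- tocplx(vectors[[t + 1]]) + acc * exp(1i * phase_list[[t]])
  fromcplx(acc / length(vectors))
}

oracle_softmax <- function(x) exp(x - max(x)) / sum(exp(x - max(x)))
oracle_lrelu <- function(x, s) ifelse(x > 0, x, s * x)
oracle_elu <- function(x) ifelse(x > 0, x, exp(x) - 1)

# One full layer, computed node by node with loops: enumerate instances
# by DFS, encode by complex arithmetic, per-head attention, semantic
# attention, output projection. Mirrors the model contract, not its code.
oracle_layer <- function(net, params, config, H) {
  ids <- list(microbe = net$microbes, drug = net$drugs,
              disease = net$diseases)
  catalog <- config$metapaths
  d <- params$meta$d; K <- params$meta$K
  phase_of <- function(ta, tb) {
    key <- paste(sort(c(ta, tb)), collapse = "|")
    s <- if (ta == sort(c(ta, tb))[1]) 1 else -1
    s * params$theta$phases[[key]]
  }
  lpar <- params$theta$layers[[1]]
  Hnew <- list()
  for (ty in names(catalog)) {
    if (length(ids[[ty]]) == 0) next
    hM <- list()
    for (spec in catalog[[ty]]) {
      mp <- parse_metapath(spec)
      delta <- lpar[[ty]]$delta[[mp$name]]
      rows <- matrix(0, length(ids[[ty]]), K * d)
      for (ni in seq_along(ids[[ty]])) {
        node <- ids[[ty]][ni]
        insts <- oracle_instances(net, mp$types, node)
        if (length(insts) == 0) {
          # fallback: the node alone is its own instance
          encs <- matrix(H[[ty]][ni, ], 1)
        } else {
          encs <- t(vapply(insts, function(p) {
            vecs <- lapply(seq_along(p), function(t)
              H[[mp$types[t]]][match(p[t], ids[[mp$types[t]]]), ])
            phs <- lapply(seq_len(length(p) - 1), function(t)
              phase_of(mp$types[t], mp$types[t + 1]))
            oracle_encode(vecs, phs)
          }, numeric(d)))
        }
        for (k in seq_len(K)) {
          e <- apply(encs, 1, function(enc)
            oracle_lrelu(sum(delta[, k] * c(H[[ty]][ni, ], enc)),
                         config$leaky_slope))
          a <- oracle_softmax(e)
          rows[ni, ((k - 1) * d + 1):(k * d)] <-
            oracle_elu(colSums(a * encs))
        }
      }
      hM[[mp$name]] <- rows
    }
    s <- lapply(hM, function(M)
      colMeans(tanh(M %*% t(lpar[[ty]]$W_att) +
                      matrix(lpar[[ty]]$b_att, nrow(M),
                             length(lpar[[ty]]$b_att), byrow = TRUE))))
    e <- vapply(s, function(si) sum(lpar[[ty]]$c_att * si), 0)
    beta <- oracle_softmax(e)
    Fm <- Reduce(`+`, Map(`*`, beta, hM))
    Hnew[[ty]] <- oracle_elu(Fm %*% t(lpar[[ty]]$W_o))
  }
  Hnew
}

# brute-force AUC: all positive-negative pairs, ties worth 1/2
oracle_auc <- function(labels, scores) {
  p <- scores[labels == 1]; n <- scores[labels == 0]
  tot <- 0
  for (x in p) tot <- tot + sum(x > n) + 0.5 * sum(x == n)
  tot / (length(p) * length(n))
}

# brute-force AUPR: sweep every distinct score as a threshold
oracle_aupr <- function(labels, scores) {
  np <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / np
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# small random tripartite network for property tests
random_network <- function(seed, n_m = 8, n_c = 4, n_d = 6, p = 0.35) {
  set.seed(seed)
  rand_edges <- function(a, b, prefix_a, prefix_b) {
    g <- which(matrix(runif(a * b) < p, a), arr.ind = TRUE)
    if (nrow(g) == 0) g <- cbind(1, 1)
    cbind(paste0(prefix_a, g[, 1]), paste0(prefix_b, g[, 2]))
  }
  build_network(md = rand_edges(n_m, n_d, "m", "d"),
                mc = rand_edges(n_m, n_c, "m", "c"),
                dc = rand_edges(n_d, n_c, "d", "c"))
}
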