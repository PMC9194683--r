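#' Sample negative microbe-disease pairs
#'
#' Draws unobserved (microbe, disease) cells of the association matrix
#' uniformly without replacement, disjoint from the known positives.
#' Negative sampling is done once, up front, so train/validation/test
#' negatives are fixed alongside the positives.
#'
#' @param net A [tripartite_network][build_network].
#' @param positives Two-column character matrix of known pairs
#'   (defaults to the network's microbe-disease edges).
#' @param ratio Negatives per positive.
#' @param seed Integer seed.
#' @return Two-column character matrix (`microbe`, `disease`) of
#'   `round(ratio * nrow(positives))` pairs.
#' @export
negative_sample <- function(net, positives = net$md, ratio = 1, seed = 1) {
  stopifnot(ratio > 0)
  n_m <- length(net$microbes); n_d <- length(net$diseases)
  need <- round(ratio * nrow(positives))
  i <- match(positives[, 1], net$microbes)
  j <- match(positives[, 2], net$diseases)
  pos_key <- (i - 1) * n_d + j
  total <- n_m * n_d
  if (total - length(unique(pos_key)) < need)
    stop("not enough unobserved microbe-disease cells: need ", need,
         ", have ", total - length(unique(pos_key)))
  keys <- with_seed(seed, {
    if (total <= 2e6) {
      avail <- setdiff(seq_len(total), pos_key)
      sample(avail, need)
    } else {
      got <- integer(0)
      while (length(got) < need) {
        cand <- sample.int(total, min(2 * need, total))
        cand <- setdiff(cand, pos_key)
        got <- unique(c(got, cand))
      }
      got[seq_len(need)]
    }
  })
  cbind(microbe = net$microbes[(keys - 1) %/% n_d + 1],
        disease = net$diseases[(keys - 1) %% n_d + 1])
}

#' Stratified train/validation/test split of labelled pairs
#'
#' Splits positive and negative pairs independently (so the label ratio
#' is preserved in every partition) into disjoint train, validation and
#' test sets at the given fractions. Partition sizes are
#' `round(fraction * n)` for validation and test, with the remainder
#' going to train.
#'
#' @param pos,neg Two-column character matrices of positive/negative
#'   pairs.
#' @param fractions Numeric length-3 vector (train, validation, test)
#'   summing to 1.
#' @param seed Integer seed for the random assignment.
#' @return A data frame with columns `microbe`, `disease`, `label`
#'   (1/0), `partition` (`"train"`, `"val"`, `"test"`).
#' @export
split_pairs <- function(pos, neg, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot(length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  k <- sum(fractions > 0)
  if (nrow(pos) < k || nrow(neg) < k)
    stop("need at least ", k, " pairs per label to fill ", k,
         " partitions")
  assign_one <- function(m, label, s) {
    n <- nrow(m)
    n_val <- round(fractions[2] * n)
    n_test <- round(fractions[3] * n)
    ord <- with_seed(s, sample.int(n))
    part <- rep("train", n)
    if (n_val > 0) part[ord[seq_len(n_val)]] <- "val"
    if (n_test > 0) part[ord[n_val + seq_len(n_test)]] <- "test"
    data.frame(microbe = m[, 1], disease = m[, 2], label = label,
               partition = part, stringsAsFactors = FALSE)
  }
  rbind(assign_one(pos, 1L, seed), assign_one(neg, 0L, seed + 1L))
}

pair_scores <- function(Hm, Hd, mi, dj) {
  sigmoid(rowSums(Hm[mi, , drop = FALSE] * Hd[dj, , drop = FALSE]))
}

pair_loss <- function(scores, y, eps = 1e-12) {
  p <- pmin(pmax(ifelse(y == 1, scores, 1 - scores), eps), 1)
  -mean(log(p))
}

#' Train the metapath-aggregation model
#'
#' End-to-end training on a tripartite network: samples negatives at
#' `neg_ratio`, makes a stratified train/validation/test split, removes held-out positive edges from the
#' message-passing graph (unless `mask_eval_edges = FALSE`), and runs
#' mini-batch-free full-graph gradient descent with Adam, dropout, and
#' early stopping on validation AUC. The parameters of the best
#' validation epoch are kept and used to compute the final embeddings.
#'
#' @param net A [tripartite_network][build_network].
#' @param config A [training_config()].
#' @return An object of class `md_model`: parameters, configuration,
#'   labelled pairs with partitions, per-epoch `history` (train loss,
#'   validation loss, validation AUC), `best_epoch`, and the final
#'   `embeddings` per node type.
#' @examples
#' \donttest{
#' sim <- generate_synthetic(synthetic_spec(n_m = 40, n_c = 12, n_d = 20,
#'                                          seed = 3))
#' cfg <- training_config(hidden_dim = 8, heads = 2, attention_dim = 8,
#'                        epochs = 3, seed = 3)
#' fit <- train_model(sim$network, cfg)
#' fit$history
#' }
#' @export
train_model <- function(net, config = training_config()) {
  stopifnot(inherits(net, "tripartite_network"),
            inherits(config, "training_config"))
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1, 5))
  neg <- negative_sample(net, net$md, config$neg_ratio, seeds[1])
  pairs <- split_pairs(net$md, neg, config$split, seeds[2])
  net_train <- net
  if (config$mask_eval_edges) {
    keep <- pairs$partition == "train" & pairs$label == 1L
    net_train$md <- cbind(microbe = pairs$microbe[keep],
                          disease = pairs$disease[keep])
  }
  engine <- build_engine(net_train, config)
  params <- init_params(net, config, seeds[3])
  mi <- match(pairs$microbe, net$microbes)
  dj <- match(pairs$disease, net$diseases)
  is_tr <- pairs$partition == "train"
  is_va <- pairs$partition == "val"
  epoch_seeds <- with_seed(seeds[4],
                           sample.int(.Machine$integer.max - 1,
                                      config$epochs + 1))
  adam <- adam_init(params$theta)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_auc = numeric(0))
  best <- list(auc = -Inf, theta = params$theta, epoch = 0L)
  drop_stream <- seeds[5]
  einst <- cap_instances(engine, epoch_seeds[1])
  for (epoch in seq_len(config$epochs)) {
    if (!config$freeze_sampling && epoch > 1)
      einst <- cap_instances(engine, epoch_seeds[epoch])
    fwd <- with_seed(drop_stream + epoch, {
      magnn_forward(engine, params, einst, train = TRUE,
                    keep_cache = TRUE)
    })
    Hm <- fwd$H$microbe; Hd <- fwd$H$disease
    s_tr <- pair_scores(Hm, Hd, mi[is_tr], dj[is_tr])
    y_tr <- pairs$label[is_tr]
    train_loss <- pair_loss(s_tr, y_tr)
    if (!is.finite(train_loss))
      stop("training diverged (non-finite loss) at epoch ", epoch,
           "; lower the learning rate")
    # chain through the sigmoid: d loss / d logit = (sigma(z) - y) / n
    dz <- (s_tr - y_tr) / length(s_tr)
    g_final <- list(
      microbe = add_rows(matrix(0, nrow(Hm), ncol(Hm)), mi[is_tr],
                         dz * Hd[dj[is_tr], , drop = FALSE]),
      disease = add_rows(matrix(0, nrow(Hd), ncol(Hd)), dj[is_tr],
                         dz * Hm[mi[is_tr], , drop = FALSE]))
    grads <- magnn_backward(engine, params, einst, fwd$caches, g_final)
    step <- adam_step(params$theta, grads, adam, config$lr,
                      config$weight_decay)
    params$theta <- step$theta
    adam <- step$state
    # deterministic evaluation pass (no dropout) for monitoring
    ev <- magnn_forward(engine, params, einst, train = FALSE)
    s_va <- pair_scores(ev$H$microbe, ev$H$disease, mi[is_va], dj[is_va])
    val_loss <- pair_loss(s_va, pairs$label[is_va])
    val_auc <- if (length(unique(pairs$label[is_va])) == 2)
      auc_score(pairs$label[is_va], s_va) else NA_real_
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = train_loss,
                                val_loss = val_loss, val_auc = val_auc))
    if (config$verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  val AUC %s",
                      epoch, train_loss, val_loss,
                      ifelse(is.na(val_auc), "NA",
                             sprintf("%.4f", val_auc))))
    crit <- if (is.na(val_auc)) -val_loss else val_auc
    if (crit > best$auc) {
      best <- list(auc = crit, theta = params$theta, epoch = epoch)
    } else if (epoch - best$epoch > config$patience) {
      break
    }
  }
  params$theta <- best$theta
  final_inst <- cap_instances(engine, epoch_seeds[1])
  emb <- magnn_forward(engine, params, final_inst, train = FALSE)$H
  for (ty in names(emb)) rownames(emb[[ty]]) <- engine$idx$ids[[ty]]
  structure(list(params = params, config = config, net = net,
                 net_train = net_train, pairs = pairs, history = history,
                 best_epoch = best$epoch,
                 best_val_auc = if (is.finite(best$auc)) best$auc else NA,
                 embeddings = emb),
            class = "md_model")
}

#' @export
print.md_model <- function(x, ...) {
  cat("Metapath-aggregation association model (variant:",
      x$config$variant, ")\n")
  cat(sprintf("  %d layer(s), hidden dim %d, %d heads\n",
              x$config$layers, x$config$hidden_dim, x$config$heads))
  cat(sprintf("  trained %d epoch(s); best validation epoch %d (AUC %.4f)\n",
              nrow(x$history), x$best_epoch, x$best_val_auc))
  invisible(x)
}

#' Score microbe-disease pairs with a trained model
#'
#' @param model An [md_model][train_model].
#' @param microbes,diseases Equal-length id vectors of the pairs to
#'   score.
#' @return Numeric vector of association scores in (0, 1).
#' @export
score_pairs <- function(model, microbes, diseases) {
  stopifnot(inherits(model, "md_model"),
            length(microbes) == length(diseases))
  mi <- match(microbes, model$net$microbes)
  dj <- match(diseases, model$net$diseases)
  if (anyNA(mi)) stop("unknown microbe id: ", microbes[which(is.na(mi))[1]])
  if (anyNA(dj)) stop("unknown disease id: ", diseases[which(is.na(dj))[1]])
  unname(pair_scores(model$embeddings$microbe, model$embeddings$disease,
                     mi, dj))
}

#' Full score matrix of a trained model
#'
#' Reconstructs the microbe-disease association matrix as
#' `sigmoid(H_m %*% t(H_d))`.
#'
#' @param model An [md_model][train_model].
#' @return Dense numeric matrix (microbes by diseases) of scores.
#' @export
predict_matrix <- function(model) {
  stopifnot(inherits(model, "md_model"))
  sigmoid(model$embeddings$microbe %*% t(model$embeddings$disease))
}

#' Train and evaluate one model variant
#'
#' Runs one of the four model variants on a network and reports held-out
#' test performance. `"full"` is the complete model; `"nb"` drops the
#' intermediate nodes of every metapath instance (the encoder sees only
#' target and endpoint, rotated by the composite relation); `"avg"`
#' replaces the rotation encoder with the order-insensitive mean encoder;
#' `"sm"` restricts the catalog to a single metapath per node type,
#' choosing the singleton catalog with the best validation AUC.
#'
#' @param variant One of `"full"`, `"nb"`, `"sm"`, `"avg"`.
#' @param net A [tripartite_network][build_network].
#' @param config A [training_config()]; its `variant` field is
#'   overridden.
#' @return An [md_eval][evaluate_model] report on the test partition,
#'   with the fitted model in `$model`.
#' @export
run_variant <- function(variant, net, config = training_config()) {
  variant <- match.arg(variant, c("full", "nb", "sm", "avg"))
  if (variant == "sm") {
    counts <- node_counts(net)
    cat0 <- validate_catalog(config$metapaths)
    n_cand <- max(lengths(cat0))
    fits <- vector("list", n_cand)
    for (p in seq_len(n_cand)) {
      cfg <- config
      cfg$variant <- "full"
      cfg$metapaths <- lapply(cat0, function(v) v[min(p, length(v))])
      fits[[p]] <- train_model(net, cfg)
    }
    vaucs <- vapply(fits, function(f) f$best_val_auc, 0)
    fit <- fits[[which.max(vaucs)]]
  } else {
    cfg <- config
    cfg$variant <- variant
    fit <- train_model(net, cfg)
  }
  rep <- evaluate_model(fit, "test")
  rep$variant <- variant
  rep$model <- fit
  rep
}

#' Run all four ablation variants
#'
#' Trains and evaluates the full model and its three ablations on the
#' same network and configuration, returning a comparison table.
#'
#' @param net A [tripartite_network][build_network].
#' @param config A [training_config()].
#' @return A data frame with one row per variant (test AUC and AUPR) and
#'   the per-variant reports in `attr(, "reports")`.
#' @export
ablate <- function(net, config = training_config()) {
  variants <- c("full", "nb", "sm", "avg")
  reports <- lapply(variants, run_variant, net = net, config = config)
  out <- data.frame(variant = variants,
                    auc = vapply(reports, function(r) r$auc, 0),
                    aupr = vapply(reports, function(r) r$aupr, 0))
  attr(out, "reports") <- stats::setNames(reports, variants)
  out
}
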