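# Reference implementations of the model's elementary operations on
# single nodes/instances. The training engine (model-engine.R) computes
# the same quantities vectorised over all instances; the test suite holds
# the two routes together.

# complex <-> interleaved-real layout: coordinate 2t-1 is Re(z_t),
# coordinate 2t is Im(z_t)
as_complex_vec <- function(v) {
  d <- length(v)
  if (d %% 2 != 0) stop("vector dimension must be even, got ", d)
  complex(real = v[seq(1, d, by = 2)], imaginary = v[seq(2, d, by = 2)])
}

as_real_vec <- function(z) {
  out <- numeric(2 * length(z))
  out[seq(1, length(out), by = 2)] <- Re(z)
  out[seq(2, length(out), by = 2)] <- Im(z)
  out
}

#' Encode a metapath instance by relational rotation
#'
#' Runs the relational-rotation recursion along a metapath instance: the
#' accumulator starts at the target node's vector and, at every step, is
#' rotated in complex space by the step's relation vector (elementwise
#' Hadamard product with a unit-modulus complex vector) before the next
#' node's vector is added. The final accumulator is divided by the number
#' of nodes, giving a sequence-aware average of the instance.
#'
#' Node vectors of even dimension d are read as d/2 complex coordinates
#' (interleaved layout: odd positions real parts, even positions
#' imaginary parts).
#'
#' @param node_vectors List of numeric vectors (or a matrix with one row
#'   per node) of common even dimension d, ordered along the instance.
#' @param relations List of complex vectors of length d/2, one per
#'   consecutive node pair; every coordinate must have modulus 1.
#' @return Numeric vector of dimension d.
#' @examples
#' v <- list(c(1, 0, 0, 1), c(0, 1, 1, 0))
#' r <- list(complex(argument = c(pi / 2, pi)))
#' encode_instance_rotate(v, r)
#' @export
encode_instance_rotate <- function(node_vectors, relations) {
  if (is.matrix(node_vectors))
    node_vectors <- asplit(node_vectors, 1)
  n <- length(node_vectors)
  if (n < 1L) stop("need at least one node vector")
  if (length(relations) != n - 1L)
    stop("need exactly ", n - 1L, " relation vectors, got ",
         length(relations))
  z <- lapply(node_vectors, as_complex_vec)
  for (r in relations) {
    if (any(abs(Mod(r) - 1) > 1e-8))
      stop("relation vector has modulus != 1")
  }
  acc <- z[[1]]
  if (n > 1L) {
    for (t in 2:n) acc <- z[[t]] + acc * relations[[t - 1]]
  }
  as_real_vec(acc / n)
}

#' Encode a metapath instance by its coordinate-wise mean
#'
#' The order-insensitive baseline encoder used by the `avg` model
#' variant: the instance is treated as a set and represented by the mean
#' of its node vectors. With identity relations (all phases zero) the
#' rotation encoder reduces exactly to this.
#'
#' @param node_vectors List of numeric vectors (or a matrix with one row
#'   per node) of common dimension.
#' @return Numeric vector, the coordinate-wise mean.
#' @export
encode_instance_mean <- function(node_vectors) {
  if (is.matrix(node_vectors))
    node_vectors <- asplit(node_vectors, 1)
  if (length(node_vectors) < 1L) stop("need at least one node vector")
  Reduce(`+`, lapply(node_vectors, as.numeric)) / length(node_vectors)
}

leaky_relu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
elu <- function(x) ifelse(x > 0, x, expm1(x))
# ELU'(x) expressed through the output: 1 where y > 0, y + 1 otherwise
elu_grad_out <- function(y) ifelse(y > 0, 1, y + 1)
sigmoid <- function(x) 1 / (1 + exp(-x))
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Attention aggregation of metapath instances for one target node
#'
#' Multi-head graph attention over the encoded instances of a single
#' metapath: each head scores every instance with
#' `LeakyReLU(delta_k' [h_i || h_inst])`, normalises the scores with a
#' softmax, aggregates the instance encodings with those weights, applies
#' the ELU activation, and the K head outputs are concatenated.
#'
#' @param target_vec The target node's current embedding (length d).
#' @param encodings Matrix of encoded instances (one row each, d
#'   columns), or a list of vectors.
#' @param delta Attention parameter matrix, 2d rows by K (heads) columns.
#' @param leaky_slope Negative slope of the LeakyReLU.
#' @return List with `embedding` (length K*d, heads concatenated) and
#'   `alpha` (instances-by-heads matrix of attention coefficients; every
#'   column sums to 1).
#' @export
intra_aggregate <- function(target_vec, encodings, delta,
                            leaky_slope = 0.01) {
  if (is.list(encodings)) encodings <- do.call(rbind, encodings)
  stopifnot(is.matrix(encodings), nrow(encodings) >= 1)
  d <- length(target_vec)
  if (nrow(delta) != 2 * d)
    stop("delta must have ", 2 * d, " rows (got ", nrow(delta), ")")
  K <- ncol(delta)
  U <- cbind(matrix(target_vec, nrow(encodings), d, byrow = TRUE),
             encodings)
  E <- leaky_relu(U %*% delta, leaky_slope)      # instances x K
  alpha <- apply(E, 2, softmax)
  if (!is.matrix(alpha)) alpha <- matrix(alpha, nrow = 1)
  heads <- lapply(seq_len(K), function(k)
    elu(colSums(encodings * alpha[, k])))
  list(embedding = unlist(heads, use.names = FALSE), alpha = alpha)
}

#' Type-level summary of a metapath's embeddings
#'
#' The feature vector of a metapath for semantic attention: every node's
#' metapath-specific embedding is passed through a learned affine map and
#' tanh, and the results are averaged over all nodes of the type. Each
#' coordinate therefore lies in (-1, 1).
#'
#' @param embeddings Matrix of metapath-specific node embeddings, one row
#'   per node of the type.
#' @param W Weight matrix (summary dimension by embedding dimension).
#' @param b Bias vector (summary dimension).
#' @return Numeric summary vector.
#' @export
metapath_summary <- function(embeddings, W, b) {
  if (is.list(embeddings)) embeddings <- do.call(rbind, embeddings)
  stopifnot(is.matrix(embeddings))
  if (nrow(embeddings) == 0L) stop("no nodes of this type")
  colMeans(tanh(embeddings %*% t(W) +
                  matrix(b, nrow(embeddings), length(b), byrow = TRUE)))
}

#' Semantic attention across metapaths
#'
#' Fuses a node type's per-metapath embeddings: each metapath's summary
#' vector is scored against the semantic attention vector, scores are
#' softmax-normalised into weights beta (shared by all nodes of the type,
#' because the summary is type-level), and every node's fused embedding
#' is the beta-weighted sum of its per-metapath embeddings.
#'
#' @param embeddings List (one element per metapath) of node-by-dimension
#'   matrices, all the same shape.
#' @param summaries List of summary vectors from [metapath_summary()].
#' @param c_att Semantic attention vector, same length as the summaries.
#' @return List with `embedding` (fused node matrix) and `beta` (metapath
#'   weights, summing to 1).
#' @export
inter_aggregate <- function(embeddings, summaries, c_att) {
  S <- length(embeddings)
  stopifnot(S >= 1, length(summaries) == S)
  dims <- vapply(embeddings, ncol, 0L)
  if (length(unique(dims)) != 1L)
    stop("per-metapath embeddings have mismatched dimensions")
  e <- vapply(summaries, function(s) {
    if (length(s) != length(c_att))
      stop("summary/attention-vector dimension mismatch")
    sum(c_att * s)
  }, 0)
  beta <- softmax(e)
  fused <- Reduce(`+`, Map(function(b, M) b * M, beta, embeddings))
  list(embedding = fused, beta = beta)
}

#' Association score of a microbe-disease pair
#'
#' The reconstruction head: the sigmoid of the inner product of the two
#' final embeddings, a probability-like score in (0, 1). Symmetric in its
#' arguments.
#'
#' @param h_m,h_d Final embedding vectors of a microbe and a disease
#'   (equal length).
#' @return Score in (0, 1).
#' @examples
#' predict_score(c(1, 2), c(3, -1)) # sigmoid(1)
#' @export
predict_score <- function(h_m, h_d) {
  if (length(h_m) != length(h_d))
    stop("embedding dimension mismatch: ", length(h_m), " vs ",
         length(h_d))
  sigmoid(sum(h_m * h_d))
}

#' Binary cross-entropy over positive and negative pair scores
#'
#' The link-prediction loss: `-sum(log(s_pos)) - sum(log(1 - s_neg))`,
#' optionally averaged over all pairs. Scores numerically equal to 0 or 1
#' are clamped away from the boundary by a small epsilon (with a
#' message), keeping the loss finite.
#'
#' @param pos_scores,neg_scores Scores in (0, 1) of positive and negative
#'   pairs.
#' @param reduction `"sum"` (default) or `"mean"` over all pairs.
#' @param eps Clamping epsilon.
#' @return Non-negative scalar.
#' @examples
#' bce_loss(0.8, numeric(0)) # -log(0.8)
#' @export
bce_loss <- function(pos_scores, neg_scores, reduction = c("sum", "mean"),
                     eps = 1e-12) {
  reduction <- match.arg(reduction)
  clamped <- sum(pos_scores < eps) + sum(neg_scores > 1 - eps)
  if (clamped > 0)
    message("bce_loss: clamped ", clamped, " boundary score(s)")
  p <- pmax(pos_scores, eps)
  q <- pmax(1 - neg_scores, eps)
  total <- -sum(log(p)) - sum(log(q))
  if (reduction == "mean")
    total <- total / (length(pos_scores) + length(neg_scores))
  total
}
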