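#' Training and model configuration
#'
#' Collects every tunable quantity of the model and its training loop,
#' with defaults matching the reference protocol: hidden dimension 32,
#' 6 attention heads, semantic-attention vector dimension 64, at most 150
#' sampled metapath instances per node, dropout 0.5, Adam with learning
#' rate 0.005 and weight decay 0.001, a 1:1 positive:negative ratio, an
#' 8:1:1 train/validation/test split, and at most 100 epochs with early
#' stopping on validation AUC (patience 5).
#'
#' @param hidden_dim Embedding dimension d (must be even: coordinates are
#'   paired into complex numbers by the rotation encoder).
#' @param heads Number of attention heads K.
#' @param attention_dim Dimension of the inter-metapath attention vector.
#' @param neighbors Maximum number of metapath instances sampled per
#'   target node.
#' @param layers Number of stacked aggregation layers L.
#' @param dropout Dropout rate applied to attention coefficients and
#'   layer inputs during training.
#' @param leaky_slope Negative slope of the LeakyReLU in the instance
#'   attention scores.
#' @param lr,weight_decay Adam learning rate and L2 weight decay.
#' @param epochs Maximum number of training epochs.
#' @param patience Early-stopping patience in epochs (0 = stop right
#'   after the first epoch without improvement).
#' @param neg_ratio Negatives sampled per positive.
#' @param split Train/validation/test fractions (length 3, sums to 1).
#' @param seed Master seed; all sampling, initialisation and dropout
#'   streams derive from it.
#' @param variant Model variant: `"full"` (rotation encoder, all
#'   metapaths), `"nb"` (target and endpoint only, intermediate nodes
#'   dropped), `"sm"` (single best metapath per type), `"avg"` (mean
#'   encoder).
#' @param metapaths Metapath catalog, a named list of schema strings per
#'   node type (see [default_metapaths()]).
#' @param freeze_sampling If `TRUE`, metapath instances are sampled once
#'   and reused every epoch; otherwise resampled each epoch.
#' @param mask_eval_edges If `TRUE` (default), validation and test
#'   positive edges are removed from the graph used for metapath
#'   aggregation during training, so held-out links never leak into
#'   message passing.
#' @param verbose Print a progress line per epoch.
#' @return An object of class `training_config`.
#' @export
training_config <- function(hidden_dim = 32, heads = 6, attention_dim = 64,
                            neighbors = 150, layers = 2, dropout = 0.5,
                            leaky_slope = 0.01, lr = 0.005,
                            weight_decay = 0.001, epochs = 100,
                            patience = 5, neg_ratio = 1,
                            split = c(0.8, 0.1, 0.1), seed = 1,
                            variant = c("full", "nb", "sm", "avg"),
                            metapaths = default_metapaths(),
                            freeze_sampling = FALSE,
                            mask_eval_edges = TRUE, verbose = FALSE) {
  variant <- match.arg(variant)
  stopifnot(hidden_dim >= 2, hidden_dim %% 2 == 0, heads >= 1,
            attention_dim >= 1, neighbors >= 1, layers >= 1,
            dropout >= 0, dropout < 1, epochs >= 1, patience >= 0,
            neg_ratio > 0, length(split) == 3, all(split >= 0))
  if (abs(sum(split) - 1) > 1e-8)
    stop("split fractions must sum to 1")
  metapaths <- validate_catalog(metapaths)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 heads = as.integer(heads),
                 attention_dim = as.integer(attention_dim),
                 neighbors = neighbors, layers = as.integer(layers),
                 dropout = dropout, leaky_slope = leaky_slope, lr = lr,
                 weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 patience = as.integer(patience), neg_ratio = neg_ratio,
                 split = split, seed = as.integer(seed), variant = variant,
                 metapaths = metapaths,
                 freeze_sampling = isTRUE(freeze_sampling),
                 mask_eval_edges = isTRUE(mask_eval_edges),
                 verbose = isTRUE(verbose)),
            class = "training_config")
}

#' Load a configuration from a YAML file
#'
#' Reads a flat YAML mapping of [training_config()] fields; fields not
#' present keep their defaults, and `overrides` (a named list, e.g. from
#' command-line flags) take precedence over the file.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @param overrides Named list of field overrides.
#' @return A [training_config()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(training_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(training_config, vals)
}

#' Write a configuration snapshot
#'
#' Serialises a [training_config()] to YAML so a run directory can be
#' re-created exactly.
#'
#' @param config A [training_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "training_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
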