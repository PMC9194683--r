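#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a uniformly chosen positive
#' outranks a uniformly chosen negative, with ties counted one half
#' (midrank convention). Requires both classes to be present.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)) # 0.75
#' @export
auc_score <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop("AUC needs both a positive and a negative example")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Non-interpolated AUPR: scores are swept from the highest distinct
#' value down, and the step curve's area is accumulated as
#' `sum((recall_t - recall_(t-1)) * precision_t)` over thresholds. Tied
#' scores enter the curve as one block. Requires at least one positive.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores, higher = more positive.
#' @return AUPR in `(0, 1]`.
#' @export
aupr_score <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  np <- sum(labels == 1L)
  if (np == 0L) stop("AUPR needs at least one positive example")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  # collapse tied scores into single thresholds
  last_of_block <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- cumsum(lab)[last_of_block]
  n_pred <- seq_along(lab)[last_of_block]
  precision <- tp / n_pred
  recall <- tp / np
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate a trained model on one partition
#'
#' Scores the labelled pairs of the requested partition with the model's
#' final embeddings and computes AUC and AUPR.
#'
#' @param model An [md_model][train_model].
#' @param partition `"test"` (default), `"val"`, or `"train"`.
#' @return An object of class `md_eval`: `auc`, `aupr`, `partition`, and
#'   `scored_pairs` (data frame with microbe, disease, label, score).
#' @export
evaluate_model <- function(model, partition = c("test", "val", "train")) {
  stopifnot(inherits(model, "md_model"))
  partition <- match.arg(partition)
  sub <- model$pairs[model$pairs$partition == partition, ]
  if (nrow(sub) == 0L) stop("no pairs in partition '", partition, "'")
  sub$score <- score_pairs(model, sub$microbe, sub$disease)
  structure(list(auc = auc_score(sub$label, sub$score),
                 aupr = aupr_score(sub$label, sub$score),
                 partition = partition,
                 scored_pairs = sub[, c("microbe", "disease", "label",
                                        "score")]),
            class = "md_eval")
}

#' @export
print.md_eval <- function(x, ...) {
  cat(sprintf("Evaluation on %s partition (%d pairs)\n", x$partition,
              nrow(x$scored_pairs)))
  cat(sprintf("  AUC  %.4f\n  AUPR %.4f\n", x$auc, x$aupr))
  if (!is.null(x$variant)) cat("  variant:", x$variant, "\n")
  invisible(x)
}

#' Rank candidate microbes for a disease
#'
#' Case-study mode: microbes already known to be associated with the
#' disease are removed, the remaining candidates are sorted by predicted
#' score in descending order (ties broken lexicographically by microbe
#' id, so rankings are deterministic), and the top of the list is
#' returned.
#'
#' @param model An [md_model][train_model].
#' @param disease Disease id.
#' @param top Number of rows to return (default 10); fewer if fewer
#'   candidates exist.
#' @param known Optional two-column matrix of known associations used
#'   for the removal step; defaults to the full network's
#'   microbe-disease edges.
#' @return Data frame with columns `rank`, `microbe`, `score`.
#' @export
rank_candidates <- function(model, disease, top = 10, known = NULL) {
  stopifnot(inherits(model, "md_model"))
  if (!disease %in% model$net$diseases)
    stop("unknown disease id: ", disease)
  if (is.null(known)) known <- model$net$md
  known_microbes <- known[known[, 2] == disease, 1]
  candidates <- setdiff(model$net$microbes, known_microbes)
  if (length(candidates) == 0L)
    return(data.frame(rank = integer(0), microbe = character(0),
                      score = numeric(0)))
  sc <- score_pairs(model, candidates, rep(disease, length(candidates)))
  ord <- order(-sc, candidates)
  n <- min(top, length(candidates))
  data.frame(rank = seq_len(n), microbe = candidates[ord][seq_len(n)],
             score = sc[ord][seq_len(n)])
}
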