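#' Specification for a planted-block synthetic network
#'
#' Describes a seed-reproducible tripartite network with planted community
#' structure. Nodes of every type are assigned to `n_blocks` communities;
#' each cross-type pair is linked independently with probability `p_in`
#' when the two nodes share a block and `p_out` otherwise. Because the
#' same blocks drive all three relations, microbe-disease links correlate
#' with shared drug neighbourhoods — the transitive signal that
#' metapath aggregation is designed to exploit.
#'
#' Defaults give a sparse network of 150 microbes, 40 drugs and 60
#' diseases in 3 blocks with a strong in-block/out-of-block contrast
#' (0.3 vs 0.02), the standard fixture used throughout the test suite.
#'
#' @param n_m,n_c,n_d Numbers of microbes, drugs, diseases.
#' @param n_blocks Number of planted communities.
#' @param p_in,p_out Within-/between-block link probabilities, applied to
#'   all three relations; requires `0 <= p_out < p_in <= 1` unless the two
#'   are equal (degenerate Erdos-Renyi case).
#' @param seed Integer seed for reproducibility.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_m = 150, n_c = 40, n_d = 60, n_blocks = 3,
                           p_in = 0.3, p_out = 0.02, seed = 1) {
  stopifnot(n_m >= n_blocks, n_c >= n_blocks, n_d >= n_blocks,
            n_blocks >= 1)
  if (!(p_out <= p_in && p_in <= 1 && p_out >= 0))
    stop("require 0 <= p_out <= p_in <= 1")
  structure(list(n_m = n_m, n_c = n_c, n_d = n_d, n_blocks = n_blocks,
                 p_in = p_in, p_out = p_out, seed = as.integer(seed)),
            class = "synthetic_spec")
}

pad_ids <- function(prefix, n) {
  if (n == 0L) return(character(0))
  sprintf("%s%0*d", prefix, max(3L, nchar(as.character(n))), seq_len(n))
}

block_assign <- function(n, n_blocks) {
  # contiguous, near-equal blocks; remainder spread over the first blocks
  sort(rep_len(seq_len(n_blocks), n))
}

sample_block_edges <- function(ids_a, blocks_a, ids_b, blocks_b,
                               p_in, p_out) {
  same <- outer(blocks_a, blocks_b, `==`)
  p <- ifelse(same, p_in, p_out)
  hit <- which(matrix(stats::runif(length(p)) < p, nrow = length(ids_a)),
               arr.ind = TRUE)
  cbind(ids_a[hit[, 1]], ids_b[hit[, 2]])
}

#' Generate a planted-block tripartite network
#'
#' Draws a random tripartite network under a [synthetic_spec()]: every
#' cross-type pair is linked with `p_in` if the two nodes share a planted
#' block and `p_out` otherwise. Reproducible from the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `network` (a [tripartite_network][build_network])
#'   and `blocks`, a named integer vector giving each node's block.
#' @examples
#' sim <- generate_synthetic(synthetic_spec(n_m = 20, n_c = 6, n_d = 10,
#'                                          seed = 7))
#' sim$network
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ids_m <- pad_ids("m", spec$n_m)
  ids_c <- pad_ids("c", spec$n_c)
  ids_d <- pad_ids("d", spec$n_d)
  bm <- block_assign(spec$n_m, spec$n_blocks)
  bc <- block_assign(spec$n_c, spec$n_blocks)
  bd <- block_assign(spec$n_d, spec$n_blocks)
  edges <- with_seed(spec$seed, {
    list(
      md = sample_block_edges(ids_m, bm, ids_d, bd, spec$p_in, spec$p_out),
      mc = sample_block_edges(ids_m, bm, ids_c, bc, spec$p_in, spec$p_out),
      dc = sample_block_edges(ids_d, bd, ids_c, bc, spec$p_in, spec$p_out)
    )
  })
  catalog <- data.frame(
    id = c(ids_m, ids_c, ids_d),
    type = rep(c("microbe", "drug", "disease"),
               c(spec$n_m, spec$n_c, spec$n_d)))
  net <- build_network(md = edges$md, mc = edges$mc, dc = edges$dc,
                       catalog = catalog)
  blocks <- c(stats::setNames(bm, ids_m), stats::setNames(bc, ids_c),
              stats::setNames(bd, ids_d))
  list(network = net, blocks = blocks)
}

#' Hard-coded 8-node toy network
#'
#' A fixed miniature network (3 microbes, 2 drugs, 3 diseases) used in
#' unit tests and examples. It contains at least one instance of each of
#' the default metapaths and is identical on every call.
#'
#' @return A [tripartite_network][build_network].
#' @export
fixture_small <- function() {
  build_network(
    md = rbind(c("m1", "d1"), c("m1", "d2"), c("m2", "d1"), c("m3", "d3")),
    mc = rbind(c("m1", "c1"), c("m2", "c1"), c("m3", "c2")),
    dc = rbind(c("d1", "c1"), c("d2", "c2"), c("d3", "c2"))
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
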