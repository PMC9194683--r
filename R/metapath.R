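TYPE_TOKENS <- c(m = "microbe", c = "drug", d = "disease")

#' Parse a metapath schema string
#'
#' A metapath is an alternating sequence of node types, written with the
#' single-letter tokens `m` (microbe), `c` (drug), `d` (disease), either
#' dash-separated (`"m-c-m"`) or concatenated (`"mcm"`). Consecutive
#' types must differ because the network has no within-type relation.
#'
#' @param spec Schema string.
#' @return An object of class `metapath`: list with `name` (canonical
#'   dashed form), `tokens` (letter vector) and `types` (full type names).
#' @examples
#' parse_metapath("m-c-m")
#' parse_metapath("dmd")
#' @export
parse_metapath <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  toks <- if (grepl("-", spec, fixed = TRUE)) {
    strsplit(spec, "-", fixed = TRUE)[[1]]
  } else {
    strsplit(spec, "", fixed = TRUE)[[1]]
  }
  toks <- tolower(trimws(toks))
  if (length(toks) < 2L)
    stop("metapath must have at least 2 node types: '", spec, "'")
  if (length(toks) > 5L)
    stop("metapaths longer than 5 node types are not supported: '",
         spec, "'")
  bad <- setdiff(toks, names(TYPE_TOKENS))
  if (length(bad) > 0L)
    stop("unknown node-type token '", bad[1], "' in metapath '", spec, "'")
  if (any(toks[-1] == toks[-length(toks)]))
    stop("consecutive identical node types in metapath '", spec, "'")
  structure(list(name = paste(toks, collapse = "-"), tokens = toks,
                 types = unname(TYPE_TOKENS[toks])),
            class = "metapath")
}

#' @export
print.metapath <- function(x, ...) {
  cat("Metapath", x$name, ":", paste(x$types, collapse = " -> "), "\n")
  invisible(x)
}

#' Default metapath catalog
#'
#' The metapaths used for embedding each node type: microbes use
#' microbe-drug-microbe and microbe-disease-microbe, diseases use
#' disease-microbe-disease and disease-drug-disease. Drugs, which appear
#' as intermediate nodes, are given the symmetric drug-centred metapaths
#' so that their representations are also refreshed between layers of a
#' multi-layer model.
#'
#' @return Named list (`microbe`, `drug`, `disease`) of schema strings.
#' @export
default_metapaths <- function() {
  list(microbe = c("m-c-m", "m-d-m"),
       drug    = c("c-m-c", "c-d-c"),
       disease = c("d-m-d", "d-c-d"))
}

validate_catalog <- function(catalog) {
  stopifnot(is.list(catalog))
  catalog <- catalog[intersect(c("microbe", "drug", "disease"),
                               names(catalog))]
  for (ty in names(catalog)) {
    for (s in catalog[[ty]]) {
      mp <- parse_metapath(s)
      if (mp$types[1] != ty || mp$types[length(mp$types)] != ty)
        stop("metapath '", s, "' does not start and end at type '",
             ty, "'")
    }
  }
  catalog
}

# Adjacency index: per-type id vectors plus integer neighbour lists for
# each ordered type pair that has a relation.
network_index <- function(net) {
  ids <- list(microbe = net$microbes, drug = net$drugs,
              disease = net$diseases)
  n <- lengths(ids)
  adj_of <- function(edges, ta, tb) {
    ia <- match(edges[, 1], ids[[ta]])
    ib <- match(edges[, 2], ids[[tb]])
    fwd <- split(ib, factor(ia, levels = seq_len(n[[ta]])))
    rev <- split(ia, factor(ib, levels = seq_len(n[[tb]])))
    list(fwd = unname(fwd), rev = unname(rev))
  }
  adj <- list()
  md <- adj_of(net$md, "microbe", "disease")
  mc <- adj_of(net$mc, "microbe", "drug")
  dc <- adj_of(net$dc, "disease", "drug")
  adj[["microbe|disease"]] <- md$fwd
  adj[["disease|microbe"]] <- md$rev
  adj[["microbe|drug"]]    <- mc$fwd
  adj[["drug|microbe"]]    <- mc$rev
  adj[["disease|drug"]]    <- dc$fwd
  adj[["drug|disease"]]    <- dc$rev
  list(ids = ids, n = n, adj = adj)
}

# Enumerate every instance of `mp` as an integer matrix (one row per
# instance, one column per position; values index into ids[[type]] of
# that position). `start` restricts to instances whose target node has
# the given integer index/indices.
enumerate_instances <- function(idx, mp, start = NULL) {
  types <- mp$types
  len <- length(types)
  first <- if (is.null(start)) seq_len(idx$n[[types[1]]]) else
    as.integer(start)
  paths <- matrix(first, ncol = 1)
  for (t in 2:len) {
    key <- paste(types[t - 1], types[t], sep = "|")
    nbr <- idx$adj[[key]]
    if (is.null(nbr))
      stop("no relation between types ", types[t - 1], " and ", types[t])
    last <- paths[, t - 1]
    cnt <- lengths(nbr)[last]
    if (sum(cnt) == 0L)
      return(matrix(integer(0), ncol = len))
    keep <- rep.int(seq_len(nrow(paths)), cnt)
    paths <- cbind(paths[keep, 1:(t - 1), drop = FALSE],
                   unlist(nbr[last], use.names = FALSE))
  }
  dimnames(paths) <- NULL
  paths
}

#' Sample metapath instances for a target node
#'
#' Enumerates all instances of metapath `mp` that start at node `node`
#' and, when more than `k` exist, draws a uniform sample of `k` of them
#' without replacement. For a symmetric metapath the degenerate instance
#' that returns to the target node itself is eligible like any other.
#' A node with no instances yields an empty list, not an error.
#'
#' @param net A [tripartite_network][build_network].
#' @param mp A [metapath][parse_metapath] or schema string.
#' @param node Node id with the metapath's start type.
#' @param k Maximum number of instances (default `Inf` = full
#'   enumeration).
#' @param seed Integer seed making the subsample reproducible.
#' @return List of character vectors, each a node-id sequence conforming
#'   to `mp` and starting at `node`.
#' @examples
#' net <- fixture_small()
#' sample_instances(net, "m-c-m", "m1")
#' @export
sample_instances <- function(net, mp, node, k = Inf, seed = 1) {
  if (is.character(mp)) mp <- parse_metapath(mp)
  stopifnot(inherits(mp, "metapath"), k >= 1)
  idx <- network_index(net)
  ty <- mp$types[1]
  pos <- match(node, idx$ids[[ty]])
  if (is.na(pos))
    stop("node '", node, "' is not a ", ty,
         " (metapath ", mp$name, " starts at type ", ty, ")")
  inst <- enumerate_instances(idx, mp, start = pos)
  if (nrow(inst) == 0L) return(list())
  if (nrow(inst) > k) {
    pick <- with_seed(seed, sample.int(nrow(inst), k))
    inst <- inst[sort(pick), , drop = FALSE]
  }
  lapply(seq_len(nrow(inst)), function(r) {
    vapply(seq_along(mp$types),
           function(t) idx$ids[[mp$types[t]]][inst[r, t]], "")
  })
}

#' Intermediate nodes of a metapath instance
#'
#' The context set of an instance: every node of the sequence except the
#' target (first) and endpoint (last) occurrences. For the symmetric
#' degenerate instance whose endpoint equals the target, the shared node
#' is still excluded.
#'
#' @param inst Character vector of node ids (a metapath instance), as
#'   returned by [sample_instances()].
#' @return Character vector of the distinct intermediate node ids
#'   (possibly empty).
#' @examples
#' intermediate_nodes(c("m1", "c1", "m2"))
#' @export
intermediate_nodes <- function(inst) {
  stopifnot(is.character(inst), length(inst) >= 2L)
  mid <- inst[-c(1L, length(inst))]
  setdiff(unique(mid), c(inst[1L], inst[length(inst)]))
}
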