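#' Read an undirected edge list from a delimited text file
#'
#' Reads a two-column edge list (one edge per row) describing links between
#' two node types of the tripartite microbe-drug-disease network. The
#' delimiter (comma or tab) is auto-detected unless given, and an optional
#' header row is recognised by common column names. Duplicate rows are
#' dropped with a message; a row joining an identifier to itself is an
#' error, because no relation of the network connects a node to itself.
#'
#' @param path Path to the edge-list file.
#' @param type_pair Character vector of length 2 naming the node types of
#'   the two columns, each one of `"microbe"`, `"drug"`, `"disease"`.
#' @param delim Field delimiter; `NULL` (default) auto-detects among
#'   comma and tab.
#' @param header `NA` (default) auto-detects a header row; otherwise
#'   logical.
#' @return A two-column character matrix of deduplicated pairs with
#'   `colnames` equal to `type_pair`. Zero rows for an empty file.
#' @examples
#' f <- tempfile()
#' writeLines(c("m1,d1", "m2,d1", "m1,d1"), f)
#' read_edge_list(f, c("microbe", "disease"))
#' @export
read_edge_list <- function(path, type_pair, delim = NULL, header = NA) {
  stopifnot(length(type_pair) == 2)
  type_pair <- match.arg(type_pair, c("microbe", "drug", "disease"),
                         several.ok = TRUE)
  if (type_pair[1] == type_pair[2])
    stop("type_pair must name two distinct node types")
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- matrix(character(0), ncol = 2,
                  dimnames = list(NULL, type_pair))
    return(out)
  }
  if (is.null(delim)) {
    delim <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  }
  parts <- strsplit(lines, delim, fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L)
  if (length(bad) > 0L)
    stop("malformed row (fewer than 2 fields) at line ", bad[1],
         " of ", path)
  a <- trimws(vapply(parts, `[[`, "", 1L))
  b <- trimws(vapply(parts, `[[`, "", 2L))
  if (is.na(header)) {
    header_words <- c("from", "to", "source", "target", "id", "node",
                      "microbe", "drug", "disease", "m", "c", "d")
    header <- tolower(a[1]) %in% header_words &&
      tolower(b[1]) %in% header_words
  }
  if (isTRUE(header) && length(a) >= 1L) {
    a <- a[-1]; b <- b[-1]
  }
  self <- which(a == b)
  if (length(self) > 0L)
    stop("edge joins an identifier to itself at data row ", self[1],
         ": '", a[self[1]], "'")
  pairs <- cbind(a, b)
  dup <- duplicated(pairs)
  if (any(dup))
    message("read_edge_list: dropped ", sum(dup), " duplicate edge(s) from ",
            basename(path))
  out <- pairs[!dup, , drop = FALSE]
  dimnames(out) <- list(NULL, type_pair)
  out
}

NODE_TYPES <- c("microbe", "drug", "disease")

canonical_pairs <- function(x, types) {
  # orient a 2-column pair matrix so columns follow `types`
  if (is.null(x) || NROW(x) == 0L)
    return(matrix(character(0), ncol = 2, dimnames = list(NULL, types)))
  x <- as.matrix(x)
  storage.mode(x) <- "character"
  cn <- colnames(x)
  if (!is.null(cn) && identical(sort(cn), sort(types)) &&
      !identical(cn, types)) {
    x <- x[, types, drop = FALSE]
  }
  colnames(x) <- types
  x[!duplicated(x), , drop = FALSE]
}

#' Build a tripartite microbe-drug-disease network
#'
#' Assembles the heterogeneous network from its three undirected,
#' unweighted relations: microbe-disease associations, microbe-drug
#' interactions, and disease-drug interactions. The node catalog is the
#' union of all identifiers seen, sorted lexicographically within each
#' type so that downstream matrix indices are reproducible regardless of
#' input order. Identifiers are opaque strings; no ontology mapping is
#' attempted, but near-duplicates differing only by case or surrounding
#' whitespace trigger a warning.
#'
#' @param md,mc,dc Two-column character matrices (or data frames) of
#'   microbe-disease, microbe-drug and disease-drug pairs, as returned by
#'   [read_edge_list()]. Any may be empty or `NULL`.
#' @param catalog Optional data frame with columns `id` and `type` adding
#'   isolated nodes not present in any edge.
#' @return An object of class `tripartite_network`: a list with elements
#'   `microbes`, `drugs`, `diseases` (sorted id vectors) and `md`, `mc`,
#'   `dc` (canonical edge matrices).
#' @examples
#' net <- build_network(md = cbind("m1", "d1"),
#'                      mc = cbind("m1", "c1"),
#'                      dc = cbind("d1", "c1"))
#' net
#' @export
build_network <- function(md = NULL, mc = NULL, dc = NULL, catalog = NULL) {
  md <- canonical_pairs(md, c("microbe", "disease"))
  mc <- canonical_pairs(mc, c("microbe", "drug"))
  dc <- canonical_pairs(dc, c("disease", "drug"))
  ids <- list(
    microbe = c(md[, "microbe"], mc[, "microbe"]),
    drug    = c(mc[, "drug"], dc[, "drug"]),
    disease = c(md[, "disease"], dc[, "disease"])
  )
  if (!is.null(catalog)) {
    stopifnot(all(c("id", "type") %in% names(catalog)))
    for (ty in NODE_TYPES)
      ids[[ty]] <- c(ids[[ty]], as.character(catalog$id[catalog$type == ty]))
  }
  ids <- lapply(ids, function(v) sort(unique(v)))
  # an id may belong to exactly one type
  all_ids <- unlist(ids, use.names = FALSE)
  clash <- unique(all_ids[duplicated(all_ids)])
  if (length(clash) > 0L)
    stop("node id(s) appear with two different types: ",
         paste(utils::head(clash, 5), collapse = ", "))
  norm <- tolower(trimws(all_ids))
  if (anyDuplicated(norm))
    warning("node ids differing only by case/whitespace detected; ",
            "they are treated as distinct nodes")
  net <- structure(
    list(microbes = ids$microbe, drugs = ids$drug, diseases = ids$disease,
         md = md, mc = mc, dc = dc),
    class = "tripartite_network")
  validate_network(net)
  net
}

validate_network <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  chk <- function(edges, col, pool, what) {
    miss <- setdiff(edges[, col], pool)
    if (length(miss) > 0L)
      stop("edge endpoint not in ", what, " catalog: ", miss[1])
  }
  chk(net$md, "microbe", net$microbes, "microbe")
  chk(net$md, "disease", net$diseases, "disease")
  chk(net$mc, "microbe", net$microbes, "microbe")
  chk(net$mc, "drug", net$drugs, "drug")
  chk(net$dc, "disease", net$diseases, "disease")
  chk(net$dc, "drug", net$drugs, "drug")
  invisible(net)
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat("Tripartite microbe-drug-disease network\n")
  cat(sprintf("  nodes: %d microbes, %d drugs, %d diseases\n",
              length(x$microbes), length(x$drugs), length(x$diseases)))
  cat(sprintf("  edges: %d microbe-disease, %d microbe-drug, %d disease-drug\n",
              nrow(x$md), nrow(x$mc), nrow(x$dc)))
  dens <- if (length(x$microbes) && length(x$diseases))
    nrow(x$md) / (length(x$microbes) * length(x$diseases)) else NA_real_
  if (is.finite(dens))
    cat(sprintf("  microbe-disease density: %.2f%%\n", 100 * dens))
  invisible(x)
}

node_counts <- function(net) {
  c(n_m = length(net$microbes), n_c = length(net$drugs),
    n_d = length(net$diseases))
}

#' Microbe-disease association matrix
#'
#' Builds the binary association matrix B (microbes in rows, diseases in
#' columns) of a tripartite network. `B[i, j] = 1` exactly when microbe i
#' and disease j are linked; row and column order follow the network
#' catalog (lexicographic in node id), not input order.
#'
#' @param net A [tripartite_network][build_network].
#' @param sparse Return a `Matrix::sparseMatrix` (default) or a dense
#'   base matrix.
#' @return An n_m x n_d binary matrix with node ids as dimnames.
#' @examples
#' net <- fixture_small()
#' association_matrix(net, sparse = FALSE)
#' @export
association_matrix <- function(net, sparse = TRUE) {
  validate_network(net)
  n_m <- length(net$microbes); n_d <- length(net$diseases)
  i <- match(net$md[, "microbe"], net$microbes)
  j <- match(net$md[, "disease"], net$diseases)
  B <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n_m, n_d),
                            dimnames = list(net$microbes, net$diseases))
  if (!sparse) B <- as.matrix(B)
  B
}

#' Association-matrix density
#'
#' Fraction of microbe-disease cells that carry a known association,
#' `|md| / (n_m * n_d)`.
#'
#' @param net A [tripartite_network][build_network].
#' @return A single number in `[0, 1]`.
#' @export
association_density <- function(net) {
  n_m <- length(net$microbes); n_d <- length(net$diseases)
  if (n_m == 0L || n_d == 0L) return(NA_real_)
  nrow(net$md) / (n_m * n_d)
}

#' Export the association matrix
#'
#' Writes B either as MatrixMarket sparse coordinates (`format = "mtx"`)
#' or as a dense CSV with row/column names (`format = "csv"`).
#'
#' @param net A [tripartite_network][build_network].
#' @param path Output file path.
#' @param format `"mtx"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_association_matrix <- function(net, path, format = c("mtx", "csv")) {
  format <- match.arg(format)
  B <- association_matrix(net, sparse = TRUE)
  if (format == "mtx") {
    Matrix::writeMM(B, path)
  } else {
    utils::write.csv(as.matrix(B), path)
  }
  invisible(path)
}

#' Write the three edge lists of a network to a directory
#'
#' Emits `md.csv`, `mc.csv`, `dc.csv` in the exact comma-delimited format
#' that [read_edge_list()] reads back.
#'
#' @param net A [tripartite_network][build_network].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_edge_lists <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(md = file.path(dir, "md.csv"), mc = file.path(dir, "mc.csv"),
             dc = file.path(dir, "dc.csv"))
  for (rel in names(paths)) {
    e <- net[[rel]]
    utils::write.table(e, paths[[rel]], sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}
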