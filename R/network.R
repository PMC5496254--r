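#' Construct a signed gene regulatory network
#'
#' A `gene_network` is a directed graph of genes in which every edge carries a
#' regulation sign: `"+"` (the source's protein activates transcription of the
#' target) or `"-"` (it represses it). Each node additionally carries initial
#' RNA and protein molecule counts used when the network is compiled into a
#' reaction system.
#'
#' @param nodes character vector of unique gene identifiers.
#' @param edges data frame with columns `source`, `target`, `sign`
#'   (`"+"`/`"-"`, or `NA` for a not-yet-signed edge). Zero-row data frames
#'   are allowed.
#' @param init_rna,init_protein non-negative integer initial molecule counts,
#'   recycled across nodes.
#' @return an object of class `gene_network` with components `nodes`,
#'   `edges` and `node_attrs`.
#' @examples
#' net <- gene_network(c("A", "B"), data.frame(source = "B", target = "A",
#'                                             sign = "+"))
#' @export
gene_network <- function(nodes, edges = NULL, init_rna = 0L, init_protein = 0L) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate gene identifiers")
  if (length(nodes) == 0L) stop("a network needs at least one gene")
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      sign   = as.character(edges$sign),
                      stringsAsFactors = FALSE)
  if (nrow(edges)) {
    if (any(edges$source == edges$target))
      stop("self-loops are not allowed")
    if (anyDuplicated(edges[c("source", "target")]))
      stop("duplicate (source, target) edge")
    missing <- setdiff(c(edges$source, edges$target), nodes)
    if (length(missing))
      stop("edge endpoint(s) not declared as nodes: ",
           paste(missing, collapse = ", "))
    bad <- !(edges$sign %in% c("+", "-") | is.na(edges$sign))
    if (any(bad)) stop("edge sign must be '+' or '-'")
  }
  node_attrs <- data.frame(
    gene = nodes,
    init_rna = as.integer(rep_len(init_rna, length(nodes))),
    init_protein = as.integer(rep_len(init_protein, length(nodes))),
    stringsAsFactors = FALSE)
  if (any(node_attrs$init_rna < 0L) || any(node_attrs$init_protein < 0L))
    stop("initial populations must be non-negative")
  structure(list(nodes = nodes, edges = edges, node_attrs = node_attrs),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  n_sign <- sum(!is.na(x$edges$sign))
  cat(sprintf("gene_network: %d genes, %d edges (%d signed)\n",
              length(x$nodes), nrow(x$edges), n_sign))
  invisible(x)
}

#' Generate a random signed gene network
#'
#' Topologies are drawn with igraph: `"scale_free"` uses preferential
#' attachment (`igraph::sample_pa`) and `"erdos_renyi"` an independent-edge
#' G(n, p) model (`igraph::sample_gnp`, directed). Preferential attachment
#' natively yields edges pointing from the later-attached node to the earlier
#' one; they are re-oriented from the earlier-attached node to the later one
#' so that hubs regulate their descendants, deterministically. Every edge is
#' then signed by an independent Bernoulli draw (see [assign_edge_signs()]).
#'
#' @param kind `"scale_free"` or `"erdos_renyi"`.
#' @param n_nodes number of genes (>= 2).
#' @param params generator knobs: `power` and `m` for scale-free (defaults 1
#'   and 1), `p` for Erdos-Renyi (default 0.1); both accept `activation_prob`
#'   (default 0.5), `init_rna` and `init_protein` (defaults 0).
#' @param seed integer seed; fixed seed gives a bit-identical network.
#' @return a [gene_network()].
#' @export
generate_network <- function(kind = c("scale_free", "erdos_renyi"),
                             n_nodes, params = list(), seed = 1L) {
  kind <- match.arg(kind)
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 2L) stop("n_nodes must be >= 2")
  activation_prob <- params$activation_prob %||% 0.5
  set.seed(as.integer(seed))
  if (kind == "scale_free") {
    power <- params$power %||% 1
    m <- params$m %||% 1
    g <- igraph::sample_pa(n_nodes, power = power, m = m, directed = TRUE)
    el <- igraph::as_edgelist(g, names = FALSE)
    # sample_pa points new -> old; orient earlier-attached -> later-attached
    el <- el[, c(2L, 1L), drop = FALSE]
  } else {
    p <- params$p %||% 0.1
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("edge probability p must lie in [0, 1]")
    g <- igraph::sample_gnp(n_nodes, p = p, directed = TRUE)
    el <- igraph::as_edgelist(g, names = FALSE)
  }
  nodes <- paste0("G", seq_len(n_nodes))
  edges <- data.frame(source = nodes[el[, 1L]], target = nodes[el[, 2L]],
                      sign = NA_character_, stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges[c("source", "target")]) &
                   edges$source != edges$target, , drop = FALSE]
  net <- gene_network(nodes, edges,
                      init_rna = params$init_rna %||% 0L,
                      init_protein = params$init_protein %||% 0L)
  # signs drawn from the same seeded stream, so (kind, params, seed) fixes
  # the whole object
  assign_edge_signs(net, activation_prob, seed = NULL)
}

#' Assign activation/repression signs to edges
#'
#' Each edge receives sign `"+"` with probability `activation_prob` and `"-"`
#' otherwise, by independent Bernoulli draws. Existing signs are overwritten.
#'
#' @param network a [gene_network()].
#' @param activation_prob probability in \[0, 1\] of an activating edge.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return the network with all edges signed.
#' @export
assign_edge_signs <- function(network, activation_prob = 0.5, seed = 1L) {
  stopifnot(inherits(network, "gene_network"))
  if (!is.numeric(activation_prob) || activation_prob < 0 || activation_prob > 1)
    stop("activation_prob must lie in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- nrow(network$edges)
  if (m) network$edges$sign <-
      ifelse(stats::runif(m) < activation_prob, "+", "-")
  network
}

#' Read a signed network from disk
#'
#' Three dialects are supported:
#' * `edge_list`: whitespace-separated `source target sign` lines with sign
#'   `+` or `-`; lines starting with `#` are ignored.
#' * `adjacency`: a square TSV with row and column names; entries must be
#'   0, 1 or -1, with `A[i, j] != 0` meaning an edge from gene i to gene j.
#' * `graphml`: GraphML with a `sign` edge attribute (`+`/`-` or +1/-1).
#'
#' Unsigned edges are an error unless `activation_prob` supplies an explicit
#' signing policy; edges are never silently defaulted.
#'
#' @param path file to read.
#' @param format one of `"edge_list"`, `"adjacency"`, `"graphml"`.
#' @param activation_prob optional signing policy for unsigned input.
#' @param seed seed for the signing policy.
#' @return a [gene_network()].
#' @export
load_network <- function(path, format = c("edge_list", "adjacency", "graphml"),
                         activation_prob = NULL, seed = 1L) {
  format <- match.arg(format)
  net <- switch(format,
    edge_list = .load_edge_list(path),
    adjacency = .load_adjacency(path),
    graphml = .load_graphml(path))
  unsigned <- is.na(net$edges$sign)
  if (any(unsigned)) {
    if (is.null(activation_prob))
      stop("input contains unsigned edges; pass activation_prob to sign them")
    net <- assign_edge_signs(net, activation_prob, seed)
  }
  net
}

.load_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty edge list: ", path)
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad))
    stop("malformed edge-list line(s): ",
         paste(lines[bad][seq_len(min(3, sum(bad)))], collapse = "; "))
  m <- do.call(rbind, parts)
  if (!all(m[, 3L] %in% c("+", "-")))
    stop("edge sign must be '+' or '-'")
  nodes <- unique(c(m[, 1L], m[, 2L]))
  gene_network(nodes, data.frame(source = m[, 1L], target = m[, 2L],
                                 sign = m[, 3L], stringsAsFactors = FALSE))
}

.load_adjacency <- function(path) {
  a <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1L, check.names = FALSE))
  if (nrow(a) != ncol(a) || !identical(rownames(a), colnames(a)))
    stop("adjacency matrix must be square with matching row/col names")
  if (!all(a %in% c(-1, 0, 1)))
    stop("adjacency entries must be 0, +1 or -1")
  idx <- which(a != 0, arr.ind = TRUE)
  edges <- data.frame(source = rownames(a)[idx[, 1L]],
                      target = colnames(a)[idx[, 2L]],
                      sign = ifelse(a[idx] > 0, "+", "-"),
                      stringsAsFactors = FALSE)
  o <- order(match(edges$source, rownames(a)), match(edges$target, rownames(a)))
  gene_network(rownames(a), edges[o, , drop = FALSE])
}

.load_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g, names = TRUE)
  sgn <- igraph::edge_attr(g, "sign")
  sgn <- if (is.null(sgn)) rep(NA_character_, nrow(el)) else
    ifelse(as.character(sgn) %in% c("+", "1", "+1"), "+",
           ifelse(as.character(sgn) %in% c("-", "-1"), "-", NA_character_))
  gene_network(igraph::vertex_attr(g, "name") %||%
                 as.character(seq_len(igraph::vcount(g))),
               data.frame(source = el[, 1L], target = el[, 2L], sign = sgn,
                          stringsAsFactors = FALSE))
}

#' Write a signed network to disk
#'
#' Inverse of [load_network()]; the `edge_list` dialect round-trips
#' byte-identically through save/load/save.
#'
#' @inheritParams load_network
#' @param network a [gene_network()] with all edges signed.
#' @export
save_network <- function(network, path,
                         format = c("edge_list", "adjacency", "graphml")) {
  stopifnot(inherits(network, "gene_network"))
  format <- match.arg(format)
  if (any(is.na(network$edges$sign))) stop("cannot save unsigned edges")
  if (format == "edge_list") {
    writeLines(sprintf("%s %s %s", network$edges$source, network$edges$target,
                       network$edges$sign), path)
  } else if (format == "adjacency") {
    n <- length(network$nodes)
    a <- matrix(0L, n, n, dimnames = list(network$nodes, network$nodes))
    if (nrow(network$edges))
      a[cbind(network$edges$source, network$edges$target)] <-
        ifelse(network$edges$sign == "+", 1L, -1L)
    utils::write.table(a, path, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                       vertices = network$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' In-degree split into activators and repressors
#'
#' @param network a [gene_network()].
#' @return data frame with one row per gene: `gene`, `activators`,
#'   `repressors` (in-degree counts).
#' @export
regulator_counts <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  act <- table(factor(network$edges$target[network$edges$sign == "+"],
                      levels = network$nodes))
  rep_ <- table(factor(network$edges$target[network$edges$sign == "-"],
                       levels = network$nodes))
  data.frame(gene = network$nodes, activators = as.integer(act),
             repressors = as.integer(rep_), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
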