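#' Stationary law of the linear birth-death process
#'
#' For production `0 -> X` at rate k and first-order decay `X -> 0` at rate
#' gamma, the stationary distribution of X is Poisson(k/gamma), so mean and
#' variance both equal k/gamma. Used as a closed-form oracle for engine
#' tests; a product delay on the birth shifts the transient but not this
#' stationary mean.
#'
#' @param k production rate (>= 0).
#' @param gamma decay rate (> 0).
#' @return named numeric vector `c(mean, variance)`.
#' @export
birth_death_stationary <- function(k, gamma) {
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (!is.numeric(k) || k < 0) stop("k must be >= 0")
  c(mean = k / gamma, variance = k / gamma)
}

#' Pairwise mutual-information weight matrix
#'
#' Plug-in mutual information (in bits) between every unordered pair of gene
#' rows of an ensemble expression matrix, after discretising each gene's
#' counts into `n_bins` equal-width bins over its own range. Degenerate
#' (constant) genes carry a single bin and get weight 0 against everything.
#' The diagonal is set to 0.
#'
#' @param expr genes x samples matrix (ensemble mode, >= 30 columns
#'   recommended).
#' @param n_bins number of bins (>= 2); default `ceiling(sqrt(ncol))`, a
#'   common plug-in heuristic.
#' @return symmetric non-negative genes x genes matrix of MI weights.
#' @export
mutual_information_matrix <- function(expr, n_bins = ceiling(sqrt(ncol(expr)))) {
  x <- as.matrix(expr)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  n <- ncol(x)
  g <- nrow(x)
  disc <- matrix(1L, g, n)
  for (i in seq_len(g)) {
    r <- range(x[i, ])
    if (r[1L] < r[2L]) {
      br <- seq(r[1L], r[2L], length.out = n_bins + 1L)
      disc[i, ] <- cut(x[i, ], breaks = br, include.lowest = TRUE,
                       labels = FALSE)
    }
  }
  w <- matrix(0, g, g, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (j <= i) next
    w[i, j] <- w[j, i] <- .binned_mi(disc[i, ], disc[j, ], n_bins)
  }
  w
}

# plug-in MI (bits) from the joint histogram of two discretised vectors
.binned_mi <- function(a, b, n_bins) {
  joint <- table(factor(a, levels = seq_len(n_bins)),
                 factor(b, levels = seq_len(n_bins))) / length(a)
  pa <- rowSums(joint); pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(pa, pb)[nz]))
}

# binned marginal entropy (bits); MI(X, X) equals this
binned_entropy <- function(x, n_bins) {
  r <- range(x)
  if (r[1L] >= r[2L]) return(0)
  br <- seq(r[1L], r[2L], length.out = n_bins + 1L)
  p <- tabulate(cut(x, br, include.lowest = TRUE, labels = FALSE),
                n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Edge versus non-edge weight separation
#'
#' Splits the unordered gene pairs into those connected in the ground-truth
#' network (either direction) and those not, and summarises the association
#' weights of the two groups: medians plus the rank-sum effect size
#' P(edge weight > non-edge weight) (the area under the ROC curve of
#' weights as an edge classifier; ties count one half). A simulator that
#' encodes topology should put the edge median above the non-edge median.
#'
#' @param weights symmetric weight matrix from
#'   [mutual_information_matrix()], rownames matching network genes.
#' @param network the generating [gene_network()].
#' @return list: `edge_median`, `nonedge_median`, `effect_size`, `n_edge`,
#'   `n_nonedge`.
#' @export
edge_separation <- function(weights, network) {
  stopifnot(inherits(network, "gene_network"))
  genes <- network$nodes
  if (!all(genes %in% rownames(weights)))
    stop("weights and network must share gene ids")
  w <- weights[genes, genes]
  g <- length(genes)
  adj <- matrix(FALSE, g, g, dimnames = list(genes, genes))
  if (nrow(network$edges)) {
    adj[cbind(network$edges$source, network$edges$target)] <- TRUE
    adj <- adj | t(adj)
  }
  ut <- upper.tri(w)
  we <- w[ut & adj]
  wn <- w[ut & !adj]
  if (!length(we) || !length(wn))
    stop("need at least one edge pair and one non-edge pair")
  # AUC via the rank-sum statistic, ties counted 0.5
  r <- rank(c(we, wn))
  auc <- (sum(r[seq_along(we)]) - length(we) * (length(we) + 1) / 2) /
    (length(we) * length(wn))
  list(edge_median = stats::median(we), nonedge_median = stats::median(wn),
       effect_size = auc, n_edge = length(we), n_nonedge = length(wn))
}

#' Simulate-and-score separation experiment
#'
#' End-to-end diagnostic mirroring the package's network-inference use case:
#' generate (or accept) a signed network, compile it, draw a steady-state
#' ensemble, compute binned-MI weights and score the edge/non-edge
#' separation.
#'
#' @param network a [gene_network()], or `NULL` to generate a scale-free
#'   network of `n_nodes` genes.
#' @param n_nodes,seed generation parameters when `network` is `NULL`; the
#'   seed also drives the simulation.
#' @param config a [sim_config()]; default: 200-replicate ensemble to
#'   t = 1500 (time for RNA and protein pools to equilibrate under the
#'   default rates).
#' @param rates,delays compilation parameters.
#' @return the [edge_separation()] summary, plus `weights` and `network`.
#' @export
separation_experiment <- function(network = NULL, n_nodes = 20L, seed = 1L,
                                  config = NULL, rates = rate_params(),
                                  delays = delay_params()) {
  if (is.null(network))
    network <- generate_network("scale_free", n_nodes, seed = seed)
  if (is.null(config))
    config <- sim_config(stop_time = 1500, readout_interval = 150,
                         seed = seed, sample = 200L)
  system <- compile_network(network, rates, delays)
  expr <- run_ensemble(system, config)
  w <- mutual_information_matrix(expr)
  out <- edge_separation(w, network)
  out$weights <- w
  out$network <- network
  out
}
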