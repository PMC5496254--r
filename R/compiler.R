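#' Enumerate activator combinations driving transcription
#'
#' Transcription of a gene can be driven by any non-empty subset of its
#' bound activators, so a gene with k activators owns 2^k - 1 transcription
#' reactions. Subsets are returned in a deterministic order: by size, then
#' lexicographically within a size.
#'
#' @param activators character vector of activator gene ids (duplicate-free).
#' @return list of character vectors, the 2^k - 1 non-empty subsets.
#' @examples
#' transcription_combinations(c("B", "C"))  # {B}, {C}, {B, C}
#' @export
transcription_combinations <- function(activators) {
  activators <- as.character(activators)
  if (anyDuplicated(activators)) stop("activator list must be duplicate-free")
  k <- length(activators)
  if (k == 0L) return(list())
  sorted <- sort(activators)
  out <- list()
  for (size in seq_len(k)) {
    cmb <- utils::combn(sorted, size, simplify = FALSE)
    # combn on a sorted vector already yields lexicographic order
    out <- c(out, cmb)
  }
  out
}

#' Compile a gene network into a delayed reaction system
#'
#' Each gene X is represented by an RNA species `RX`, a protein species `PX`
#' and promoter species: one free/bound site pair `ProX.NoY` / `ProX.Y` per
#' incoming regulator Y, or a single constitutive promoter `ProX` when X has
#' no regulators. Three reaction sections are generated:
#'
#' 1. *Translation and decay*, per gene: `RX -> RX + PX` (RX catalytic, PX
#'    delayed by `protein_delay`), `RX -> 0`, `PX -> 0`.
#' 2. *Binding/unbinding*, per edge Y -> X: `PY + ProX.NoY -> ProX.Y` at the
#'    binding rate and `ProX.Y -> ProX.NoY + PY` at the unbinding rate.
#' 3. *Transcription*, per gene X: one reaction for every non-empty subset S
#'    of X's activators, with the bound forms `{ProX.Y : Y in S}` and every
#'    free repressor site `ProX.NoZ` as catalytic reactants, producing `RX`
#'    delayed by `rna_delay`. Requiring the free repressor sites makes the
#'    propensity vanish whenever any repressor is bound, which is how bound
#'    repressors block expression. A gene with no activators gets a single
#'    basal reaction driven by `ProX` (or by its free repressor sites).
#'
#' With a nonzero `promoter_delay` the promoter-form catalysts of
#' transcription reactions are consumed at firing and re-released after the
#' sampled delay, modelling occupancy during elongation; with delay kind
#' `none` they are pure catalysts.
#'
#' Initial populations: every promoter site starts at 1 copy (single gene
#' copy); RNA/protein counts come from the network's node attributes.
#'
#' @param network a [gene_network()] with all edges signed.
#' @param rates a [rate_params()].
#' @param delays a [delay_params()].
#' @return a [reaction_system()].
#' @export
compile_network <- function(network, rates = rate_params(),
                            delays = delay_params()) {
  stopifnot(inherits(network, "gene_network"),
            inherits(rates, "rate_params"),
            inherits(delays, "delay_params"))
  if (any(is.na(network$edges$sign)))
    stop("network has unsigned edges; run assign_edge_signs() first")
  genes <- network$nodes
  edges <- network$edges
  regs_of <- lapply(genes, function(g) edges[edges$target == g, , drop = FALSE])
  names(regs_of) <- genes

  # species table, deterministic order: per gene, promoter sites in edge
  # order (or ProX), then RX, PX
  sp <- list()
  for (g in genes) {
    rg <- regs_of[[g]]
    if (nrow(rg)) {
      for (y in rg$source) {
        sp[[length(sp) + 1L]] <- c(paste0("Pro", g, ".No", y), 1L, "promoter", g)
        sp[[length(sp) + 1L]] <- c(paste0("Pro", g, ".", y), 0L, "promoter", g)
      }
    } else {
      sp[[length(sp) + 1L]] <- c(paste0("Pro", g), 1L, "promoter", g)
    }
    ia <- match(g, network$node_attrs$gene)
    sp[[length(sp) + 1L]] <- c(paste0("R", g),
                               network$node_attrs$init_rna[ia], "rna", g)
    sp[[length(sp) + 1L]] <- c(paste0("P", g),
                               network$node_attrs$init_protein[ia], "protein", g)
  }
  sp <- do.call(rbind, sp)
  species <- data.frame(name = sp[, 1L], count = as.integer(sp[, 2L]),
                        role = sp[, 3L], gene = sp[, 4L],
                        stringsAsFactors = FALSE)

  none <- delay_spec("none")
  rxns <- list()
  # section 1: translation + RNA/protein decay
  for (g in genes) {
    rxns[[length(rxns) + 1L]] <- reaction(
      data.frame(species = paste0("R", g), stoich = 1L, consumed = FALSE),
      data.frame(species = paste0("P", g), stoich = 1L,
                 delay = I(list(delays$protein_delay))),
      .rate_for(rates, "translation", g))
    rxns[[length(rxns) + 1L]] <- reaction(
      data.frame(species = paste0("R", g), stoich = 1L, consumed = TRUE),
      NULL, .rate_for(rates, "rna_degradation", g))
    rxns[[length(rxns) + 1L]] <- reaction(
      data.frame(species = paste0("P", g), stoich = 1L, consumed = TRUE),
      NULL, .rate_for(rates, "protein_degradation", g))
  }
  # section 2: binding/unbinding per edge
  for (i in seq_len(nrow(edges))) {
    y <- edges$source[i]; x <- edges$target[i]
    key <- paste0(y, "->", x)
    free <- paste0("Pro", x, ".No", y)
    bound <- paste0("Pro", x, ".", y)
    rxns[[length(rxns) + 1L]] <- reaction(
      data.frame(species = c(paste0("P", y), free), stoich = 1L,
                 consumed = TRUE),
      data.frame(species = bound, stoich = 1L),
      .rate_for(rates, "binding", key))
    rxns[[length(rxns) + 1L]] <- reaction(
      data.frame(species = bound, stoich = 1L, consumed = TRUE),
      data.frame(species = c(free, paste0("P", y)), stoich = 1L),
      .rate_for(rates, "unbinding", key))
  }
  # section 3: transcription
  delayed_promoter <- delays$promoter_delay$kind != "none"
  for (g in genes) {
    rg <- regs_of[[g]]
    activators <- rg$source[rg$sign == "+"]
    repressors <- rg$source[rg$sign == "-"]
    free_rep <- if (length(repressors)) paste0("Pro", g, ".No", repressors)
                else character(0)
    tr_rate <- .rate_for(rates, "transcription", g)
    mk <- function(promoter_forms) {
      if (delayed_promoter) {
        re <- data.frame(species = promoter_forms, stoich = 1L,
                         consumed = TRUE)
        pr <- data.frame(
          species = c(paste0("R", g), promoter_forms),
          stoich = 1L,
          delay = I(c(list(delays$rna_delay),
                      rep(list(delays$promoter_delay),
                          length(promoter_forms)))))
      } else {
        re <- data.frame(species = promoter_forms, stoich = 1L,
                         consumed = FALSE)
        pr <- data.frame(species = paste0("R", g), stoich = 1L,
                         delay = I(list(delays$rna_delay)))
      }
      reaction(re, pr, tr_rate)
    }
    if (length(activators)) {
      for (s in transcription_combinations(activators))
        rxns[[length(rxns) + 1L]] <-
          mk(c(paste0("Pro", g, ".", s), free_rep))
    } else if (length(repressors)) {
      rxns[[length(rxns) + 1L]] <- mk(free_rep)
    } else {
      rxns[[length(rxns) + 1L]] <- mk(paste0("Pro", g))
    }
  }
  reaction_system(species, rxns)
}

#' Predicted reaction count of a compiled network
#'
#' Closed form: `sum over genes of 3 + 2 * indegree + (2^a - 1 if a > 0
#' else 1)` where `a` is the activator in-degree — three
#' translation/decay reactions per gene, a binding/unbinding pair per edge,
#' and one transcription reaction per non-empty activator subset (or one
#' basal reaction).
#'
#' @param network a signed [gene_network()].
#' @return integer reaction count, equal to
#'   `length(compile_network(network, ...)$reactions)`.
#' @export
count_reactions <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  rc <- regulator_counts(network)
  indeg <- rc$activators + rc$repressors
  tr <- ifelse(rc$activators > 0L, 2L^rc$activators - 1L, 1L)
  as.integer(sum(3L + 2L * indeg + tr))
}
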