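# shared fixtures, all built in code

# the 4-gene worked example: B and C activate A, D represses A
worked_example_network <- function() {
  gene_network(c("A", "B", "C", "D"),
               data.frame(source = c("B", "C", "D"), target = "A",
                          sign = c("+", "+", "-"),
                          stringsAsFactors = FALSE))
}

# birth-death: 0 -> X at rate k, X -> 0 at rate gamma
birth_death_system <- function(k = 10, gamma = 1, delay_ann = "") {
  parse_reactions(c("species X = 0",
                    sprintf(" --[%g]--> X%s", k, delay_ann),
                    sprintf("X --[%g]--> ", gamma)))
}

# the ten toggle-switch lines without cooperative binding, typeset with
# typographic dashes and a spaced arrow head exactly as printed
toggle_switch_text <- function() {
  c("ProA + *Ind –[0.002]– > A + ProA",
    "ProB + *Ind –[0.002]– > B + ProB",
    "A –[0.005]– >",
    "B –[0.005]– >",
    "A + ProB + *ProA –[0.2]– > ProB.A",
    "B + ProA + *ProB –[0.2]– > ProA.B",
    "ProB.A –[0.01]– > ProB + A",
    "ProA.B –[0.01]– > ProA + B",
    "ProB.A –[0.005]– > ProB",
    "ProA.B –[0.005]– > ProA")
}

# order-insensitive canonical signature of a reaction multiset
rxn_signature <- function(system) {
  sig <- vapply(system$reactions, function(r) {
    re <- r$reactants[order(r$reactants$species), , drop = FALSE]
    pr <- r$products[order(r$products$species), , drop = FALSE]
    paste(
      paste(sprintf("%s:%d:%d", re$species, re$stoich, re$consumed),
            collapse = ","),
      paste(sprintf("%s:%d:%s:%g:%g", pr$species, pr$stoich, pr$kind,
                    pr$p1, pr$p2), collapse = ","),
      format(r$rate), sep = "|")
  }, character(1L))
  sort(sig)
}

# transcription reactions of a compiled system = reactions producing an RNA
# species with only promoter-form reactants
transcription_reactions_for <- function(system, gene) {
  rna <- paste0("R", gene)
  Filter(function(r) rna %in% r$products$species &&
           all(startsWith(r$reactants$species, "Pro")),
         system$reactions)
}

# star network: k activators (and optionally m repressors) all pointing at X
star_network <- function(k, m = 0L) {
  regs <- c(if (k) paste0("A", seq_len(k)), if (m) paste0("Z", seq_len(m)))
  gene_network(c("X", regs),
               data.frame(source = regs, target = "X",
                          sign = c(rep("+", k), rep("-", m)),
                          stringsAsFactors = FALSE))
}
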