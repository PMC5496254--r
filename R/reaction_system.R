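#' Construct a single delayed mass-action reaction
#'
#' Reactants are `(species, stoich, consumed)` triples: a reactant with
#' `consumed = FALSE` is a pure catalyst — it enters the propensity's
#' combinatorial factor but is never decremented (equivalently, it is
#' re-released instantly). A catalyst whose re-release is *delayed* is
#' instead encoded as a consumed reactant plus a delayed product of the same
#' species. Products are `(species, stoich, delay)` triples.
#'
#' @param reactants data frame with columns `species`, `stoich` (>= 1),
#'   `consumed` (logical); zero rows allowed (pure source reaction).
#' @param products data frame with columns `species`, `stoich` and either a
#'   `delay` list-column of [delay_spec()] objects or columns
#'   `kind`, `p1`, `p2`; zero rows allowed (pure degradation).
#' @param rate non-negative stochastic rate constant c.
#' @return an object of class `reaction`.
#' @export
reaction <- function(reactants, products, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0)
    stop("rate must be a finite non-negative scalar")
  reactants <- .norm_side(reactants, c("species", "stoich", "consumed"))
  if (!is.null(products$delay)) {
    d <- products$delay
    products <- data.frame(species = as.character(products$species),
                           stoich = as.integer(products$stoich),
                           kind = vapply(d, `[[`, "", "kind"),
                           p1 = vapply(d, `[[`, 0, "p1"),
                           p2 = vapply(d, `[[`, 0, "p2"),
                           stringsAsFactors = FALSE)
  }
  products <- .norm_side(products, c("species", "stoich", "kind", "p1", "p2"))
  if (nrow(reactants) == 0L && nrow(products) == 0L)
    stop("a reaction needs at least one reactant or product")
  if (nrow(reactants) && (any(reactants$stoich < 1L)))
    stop("reactant stoichiometry must be >= 1")
  if (nrow(products) && (any(products$stoich < 1L)))
    stop("product stoichiometry must be >= 1")
  if (nrow(products) && !all(products$kind %in% names(.delay_code)))
    stop("unknown delay kind: ",
         paste(setdiff(products$kind, names(.delay_code)), collapse = ", "))
  structure(list(reactants = reactants, products = products,
                 rate = as.numeric(rate)), class = "reaction")
}

.norm_side <- function(df, cols) {
  if (is.null(df) || NROW(df) == 0L) {
    out <- data.frame(species = character(), stoich = integer(),
                      stringsAsFactors = FALSE)
    if ("consumed" %in% cols) out$consumed <- logical()
    if ("kind" %in% cols) { out$kind <- character(); out$p1 <- out$p2 <- numeric() }
    return(out)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$stoich)) df$stoich <- 1L
  if ("consumed" %in% cols && is.null(df$consumed)) df$consumed <- TRUE
  if ("kind" %in% cols && is.null(df$kind)) { df$kind <- "none"; df$p1 <- df$p2 <- 0 }
  df$species <- as.character(df$species)
  df$stoich <- as.integer(df$stoich)
  df[cols]
}

#' Assemble a delayed reaction system
#'
#' @param species data frame with columns `name` and `count` (non-negative
#'   integer initial populations); optional `role`
#'   (`promoter`/`rna`/`protein`/`other`) and `gene` columns record, for
#'   compiled systems, which gene each RNA/protein species reads out.
#' @param reactions list of [reaction()] objects; every referenced species
#'   must be declared.
#' @param waitlist optional data frame of scheduled injections with columns
#'   `species`, `count` (>= 1) and `release_time` (finite, >= 0): the named
#'   molecules are added to the system when simulated time reaches
#'   `release_time`.
#' @return an object of class `reaction_system`.
#' @export
reaction_system <- function(species, reactions = list(), waitlist = NULL) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "count") %in% names(species)))
  species$name <- as.character(species$name)
  species$count <- as.integer(species$count)
  if (is.null(species$role)) species$role <- rep("other", nrow(species))
  if (is.null(species$gene)) species$gene <- rep(NA_character_, nrow(species))
  if (anyDuplicated(species$name)) stop("duplicate species names")
  if (any(species$count < 0L)) stop("initial counts must be non-negative")
  refs <- unique(unlist(lapply(reactions, function(r)
    c(r$reactants$species, r$products$species))))
  missing <- setdiff(refs, species$name)
  if (length(missing))
    stop("reaction references undeclared species: ",
         paste(missing, collapse = ", "))
  if (is.null(waitlist)) {
    waitlist <- data.frame(species = character(), count = integer(),
                           release_time = numeric(), stringsAsFactors = FALSE)
  } else {
    waitlist <- data.frame(species = as.character(waitlist$species),
                           count = as.integer(waitlist$count),
                           release_time = as.numeric(waitlist$release_time),
                           stringsAsFactors = FALSE)
    if (any(waitlist$count < 1L)) stop("waitlist count must be >= 1")
    if (any(!is.finite(waitlist$release_time)) || any(waitlist$release_time < 0))
      stop("waitlist release_time must be finite and >= 0")
    missing <- setdiff(waitlist$species, species$name)
    if (length(missing))
      stop("waitlist references undeclared species: ",
           paste(missing, collapse = ", "))
  }
  structure(list(species = species, reactions = reactions,
                 waitlist = waitlist), class = "reaction_system")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("reaction_system: %d species, %d reactions, %d waitlist entries\n",
              nrow(x$species), length(x$reactions), nrow(x$waitlist)))
  invisible(x)
}

#' Schedule a delayed molecule injection
#'
#' Adds a wait-list entry releasing `count` copies of `species` at simulated
#' time `release_time`, regardless of reaction activity.
#'
#' @param system a [reaction_system()].
#' @param species species name.
#' @param count number of molecules (>= 1).
#' @param release_time release time (>= 0).
#' @export
add_waitlist <- function(system, species, count, release_time) {
  stopifnot(inherits(system, "reaction_system"))
  wl <- rbind(system$waitlist,
              data.frame(species = as.character(species),
                         count = as.integer(count),
                         release_time = as.numeric(release_time),
                         stringsAsFactors = FALSE))
  reaction_system(system$species, system$reactions, wl)
}

#' Mass-action propensity of one reaction
#'
#' The propensity is `c * prod(choose(n_s, stoich_s))` over all reactants
#' (catalysts included); it is zero whenever any reactant count falls below
#' its stoichiometry, which is what guarantees counts never go negative.
#'
#' @param reaction a [reaction()].
#' @param populations named integer vector of current species counts.
#' @return non-negative numeric propensity.
#' @export
propensity <- function(reaction, populations) {
  stopifnot(inherits(reaction, "reaction"))
  a <- reaction$rate
  re <- reaction$reactants
  for (i in seq_len(nrow(re))) {
    n <- populations[[re$species[i]]]
    if (is.null(n) || is.na(n)) stop("unknown species: ", re$species[i])
    a <- a * choose(n, re$stoich[i])
    if (a == 0) return(0)
  }
  a
}
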