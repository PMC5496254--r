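#' Parse a plain-text delayed reaction system
#'
#' One reaction per line, in the grammar
#' `R1 + *R2 --[c]--> P1 + 2 P2(tau)`:
#'
#' * the rate constant sits in a mandatory `--[c]-->` bracket; typographic
#'   en/em dashes and a spaced `-- >` arrow head are normalised before
#'   tokenising, so lines typeset as `A –\[0.005\]– >` parse as written;
#' * a `*` prefix marks a catalytic reactant: counted in the propensity,
#'   never consumed, re-released instantly — unless a delay annotation is
#'   attached (`*X(5)`), in which case it is consumed at firing and
#'   re-released after the delay;
#' * an integer coefficient before a species name is its stoichiometry;
#' * an empty right-hand side (or `0`) means pure degradation;
#' * product delay annotations: `(d)` constant delay, `(gamma:shape,scale)`,
#'   `(gauss:mean,sd)`, `(exp:rate)`;
#' * `#` starts a comment line; `species NAME = COUNT` sets an initial
#'   population; `waitlist NAME = COUNT @ TIME` schedules an injection;
#'   species not mentioned in a `species` line start at 0.
#'
#' Numbers use the decimal point regardless of locale.
#'
#' @param text a single string, a character vector of lines, or a
#'   connection/file path via `parse_reaction_file()`.
#' @return a [reaction_system()].
#' @export
parse_reactions <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  sp_order <- character()
  sp_count <- integer()
  declare <- function(name, count = NA_integer_) {
    if (!(name %in% sp_order)) {
      sp_order <<- c(sp_order, name)
      sp_count <<- c(sp_count, 0L)
    }
    if (!is.na(count)) sp_count[match(name, sp_order)] <<- count
  }
  rxns <- list()
  wl <- list()
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    line <- .normalise_dashes(trimws(raw))
    if (!nzchar(line) || startsWith(line, "#")) next
    m <- regmatches(line, regexec(
      "^species[[:space:]]+([A-Za-z_][A-Za-z0-9_.]*)[[:space:]]*=[[:space:]]*([0-9]+)$",
      line))[[1L]]
    if (length(m)) { declare(m[2L], as.integer(m[3L])); next }
    m <- regmatches(line, regexec(
      "^waitlist[[:space:]]+([A-Za-z_][A-Za-z0-9_.]*)[[:space:]]*=[[:space:]]*([0-9]+)[[:space:]]*@[[:space:]]*([0-9.eE+-]+)$",
      line))[[1L]]
    if (length(m)) {
      declare(m[2L])
      wl[[length(wl) + 1L]] <- data.frame(species = m[2L],
                                          count = as.integer(m[3L]),
                                          release_time = as.numeric(m[4L]),
                                          stringsAsFactors = FALSE)
      next
    }
    m <- regmatches(line, regexec(
      "^(.*?)-+\\[[[:space:]]*([0-9.eE+-]+)[[:space:]]*\\]-*[[:space:]]*>(.*)$",
      line))[[1L]]
    if (!length(m))
      stop(sprintf("line %d: missing or malformed rate bracket: '%s'",
                   ln, raw))
    rate <- suppressWarnings(as.numeric(m[3L]))
    if (is.na(rate) || rate < 0)
      stop(sprintf("line %d: invalid rate constant '%s'", ln, m[3L]))
    lhs <- .parse_terms(m[2L], ln)
    rhs <- .parse_terms(m[4L], ln)
    reactants <- products <- list()
    for (t in lhs) {
      if (t$catalyst && t$delay$kind != "none") {
        reactants[[length(reactants) + 1L]] <-
          data.frame(species = t$species, stoich = t$stoich, consumed = TRUE)
        products[[length(products) + 1L]] <-
          data.frame(species = t$species, stoich = t$stoich,
                     delay = I(list(t$delay)))
      } else {
        reactants[[length(reactants) + 1L]] <-
          data.frame(species = t$species, stoich = t$stoich,
                     consumed = !t$catalyst)
      }
      declare(t$species)
    }
    for (t in rhs) {
      products[[length(products) + 1L]] <-
        data.frame(species = t$species, stoich = t$stoich,
                   delay = I(list(t$delay)))
      declare(t$species)
    }
    rxns[[length(rxns) + 1L]] <- reaction(
      if (length(reactants)) do.call(rbind, reactants) else NULL,
      if (length(products)) do.call(rbind, products) else NULL,
      rate)
  }
  if (!length(sp_order)) stop("no species declared or used")
  reaction_system(
    data.frame(name = sp_order, count = sp_count, stringsAsFactors = FALSE),
    rxns,
    if (length(wl)) do.call(rbind, wl) else NULL)
}

#' @rdname parse_reactions
#' @param path path to a UTF-8 reaction text file.
#' @export
parse_reaction_file <- function(path) {
  parse_reactions(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

.normalise_dashes <- function(x) {
  x <- gsub("–|—|−", "-", x)
  gsub("∅", "", x)  # empty-set glyph on a degradation RHS
}

.parse_terms <- function(side, ln) {
  txt <- trimws(side)
  if (!nzchar(txt) || txt == "0") return(list())
  if (grepl("^\\+", txt) || grepl("\\+$", txt))
    stop(sprintf("line %d: dangling '+' in '%s'", ln, side))
  parts <- strsplit(txt, "+", fixed = TRUE)[[1L]]
  if (length(parts) == 0L || any(!nzchar(trimws(parts))))
    stop(sprintf("line %d: dangling '+' in '%s'", ln, side))
  lapply(parts, .parse_term, ln = ln)
}

.parse_term <- function(part, ln) {
  part <- trimws(part)
  pat <- paste0("^([0-9]+[[:space:]]+)?(\\*)?",
                "([A-Za-z_][A-Za-z0-9_.]*)",
                "(\\(([^)]*)\\))?$")
  m <- regmatches(part, regexec(pat, part))[[1L]]
  if (!length(m))
    stop(sprintf("line %d: cannot parse species term '%s'", ln, part))
  delay <- if (nzchar(m[5L])) .parse_delay_annotation(m[6L], ln)
           else delay_spec("none")
  list(stoich = if (nzchar(trimws(m[2L]))) as.integer(trimws(m[2L])) else 1L,
       catalyst = m[3L] == "*",
       species = m[4L],
       delay = delay)
}

.parse_delay_annotation <- function(txt, ln) {
  txt <- trimws(txt)
  num <- suppressWarnings(as.numeric(txt))
  if (!is.na(num)) return(delay_spec("constant", value = num))
  m <- regmatches(txt, regexec("^([a-z]+):(.*)$", txt))[[1L]]
  if (!length(m))
    stop(sprintf("line %d: malformed delay annotation '(%s)'", ln, txt))
  ps <- suppressWarnings(as.numeric(strsplit(m[3L], ",", fixed = TRUE)[[1L]]))
  if (anyNA(ps))
    stop(sprintf("line %d: non-numeric delay parameters in '(%s)'", ln, txt))
  switch(m[2L],
    gamma = { .need_np(ps, 2L, txt, ln)
              delay_spec("gamma", shape = ps[1L], scale = ps[2L]) },
    gauss = ,
    gaussian = { .need_np(ps, 2L, txt, ln)
                 delay_spec("gaussian", mean = ps[1L], sd = ps[2L]) },
    exp = ,
    exponential = { .need_np(ps, 1L, txt, ln)
                    delay_spec("exponential", rate = ps[1L]) },
    stop(sprintf("line %d: unknown delay kind '%s'", ln, m[2L])))
}

.need_np <- function(ps, n, txt, ln) {
  if (length(ps) != n)
    stop(sprintf("line %d: delay '(%s)' needs %d parameter(s)", ln, txt, n))
}

#' Render a reaction system in the text grammar
#'
#' Emits `species` population lines, `waitlist` lines, then one line per
#' reaction, in the same grammar [parse_reactions()] reads, so that
#' compile/format/parse round trips are lossless up to reaction ordering.
#'
#' @param system a [reaction_system()].
#' @return character vector of lines.
#' @export
format_reactions <- function(system) {
  stopifnot(inherits(system, "reaction_system"))
  out <- sprintf("species %s = %d", system$species$name, system$species$count)
  if (nrow(system$waitlist))
    out <- c(out, sprintf("waitlist %s = %d @ %s", system$waitlist$species,
                          system$waitlist$count,
                          format(system$waitlist$release_time)))
  for (r in system$reactions) {
    lhs <- character()
    re <- r$reactants
    pr <- r$products
    # a consumed reactant re-released as a delayed product of the same
    # species prints as a delayed catalyst *X(tau)
    drop_pr <- logical(nrow(pr))
    for (i in seq_len(nrow(re))) {
      coef <- if (re$stoich[i] > 1L) paste0(re$stoich[i], " ") else ""
      if (re$consumed[i]) {
        j <- which(!drop_pr & pr$species == re$species[i] &
                     pr$stoich == re$stoich[i] & pr$kind != "none")
        if (length(j)) {
          j <- j[1L]
          drop_pr[j] <- TRUE
          d <- structure(list(kind = pr$kind[j], p1 = pr$p1[j],
                              p2 = pr$p2[j]), class = "delay_spec")
          lhs <- c(lhs, sprintf("%s*%s(%s)", coef, re$species[i],
                                format_delay(d)))
        } else {
          lhs <- c(lhs, paste0(coef, re$species[i]))
        }
      } else {
        lhs <- c(lhs, paste0(coef, "*", re$species[i]))
      }
    }
    rhs <- character()
    for (j in seq_len(nrow(pr))) {
      if (drop_pr[j]) next
      coef <- if (pr$stoich[j] > 1L) paste0(pr$stoich[j], " ") else ""
      ann <- if (pr$kind[j] == "none") "" else
        sprintf("(%s)", format_delay(structure(
          list(kind = pr$kind[j], p1 = pr$p1[j], p2 = pr$p2[j]),
          class = "delay_spec")))
      rhs <- c(rhs, paste0(coef, pr$species[j], ann))
    }
    out <- c(out, sprintf("%s --[%s]--> %s",
                          paste(lhs, collapse = " + "),
                          format(r$rate),
                          paste(rhs, collapse = " + ")))
  }
  out
}

#' @rdname format_reactions
#' @param path file to write.
#' @export
write_reaction_file <- function(system, path) {
  writeLines(format_reactions(system), path, useBytes = TRUE)
  invisible(path)
}
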