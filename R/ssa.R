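# Flatten a reaction_system into the CSR-style integer/double vectors the
# C++ engine consumes. Species are indexed 0-based in species-table order.
encode_system <- function(system) {
  stopifnot(inherits(system, "reaction_system"))
  idx <- stats::setNames(seq_along(system$species$name) - 1L,
                         system$species$name)
  nr <- length(system$reactions)
  re_off <- pr_off <- integer(nr + 1L)
  re_sp <- re_st <- pr_sp <- pr_st <- pr_dk <- integer()
  re_cons <- logical()
  pr_p1 <- pr_p2 <- numeric()
  rate <- numeric(nr)
  for (j in seq_len(nr)) {
    r <- system$reactions[[j]]
    rate[j] <- r$rate
    re_off[j + 1L] <- re_off[j] + nrow(r$reactants)
    pr_off[j + 1L] <- pr_off[j] + nrow(r$products)
    re_sp <- c(re_sp, unname(idx[r$reactants$species]))
    re_st <- c(re_st, r$reactants$stoich)
    re_cons <- c(re_cons, r$reactants$consumed)
    pr_sp <- c(pr_sp, unname(idx[r$products$species]))
    pr_st <- c(pr_st, r$products$stoich)
    pr_dk <- c(pr_dk, unname(.delay_code[r$products$kind]))
    pr_p1 <- c(pr_p1, r$products$p1)
    pr_p2 <- c(pr_p2, r$products$p2)
  }
  list(init = system$species$count, rate = rate,
       re_off = re_off, re_sp = re_sp, re_st = re_st, re_cons = re_cons,
       pr_off = pr_off, pr_sp = pr_sp, pr_st = pr_st, pr_dk = pr_dk,
       pr_p1 = pr_p1, pr_p2 = pr_p2,
       wl_sp = unname(idx[system$waitlist$species]),
       wl_ct = system$waitlist$count,
       wl_t = system$waitlist$release_time)
}

#' Simulate a delayed reaction system
#'
#' Runs the delayed stochastic simulation algorithm: exact direct-method
#' firing with exponentially distributed waiting times, plus a time-ordered
#' wait list from which delayed products (and scheduled injections) are
#' released. If the earliest pending release precedes the candidate firing
#' time, the release is applied instead and the firing redrawn; at exactly
#' equal times the release wins (it is an already-committed event). When the
#' total propensity is zero and the wait list is empty the run fast-forwards
#' to `stop_time` (a notice is emitted).
#'
#' Snapshots are recorded on the readout grid `start_time + i *
#' readout_interval`; the snapshot at grid time g reflects every event with
#' event time <= g. A fixed `seed` gives bit-identical trajectories.
#'
#' @param system a [reaction_system()].
#' @param config a [sim_config()].
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param log_events record a per-event audit log (time, kind, id)?
#' @param max_events guard against runaway systems; exceeded => error.
#' @return list with `times` (readout grid), `counts` (species x times
#'   integer matrix, rownames = species), `n_events`, `deadlock`, and with
#'   `log_events = TRUE` a data frame `events` (`time`,
#'   `kind` in `fire`/`release`, `id` = reaction index or species name).
#' @export
simulate_system <- function(system, config, seed = config$seed,
                            log_events = FALSE, max_events = 1e8) {
  stopifnot(inherits(system, "reaction_system"),
            inherits(config, "sim_config"))
  enc <- encode_system(system)
  grid <- readout_grid(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- .ssa_run_cpp(enc$init, enc$rate,
                      enc$re_off, enc$re_sp, enc$re_st, enc$re_cons,
                      enc$pr_off, enc$pr_sp, enc$pr_st, enc$pr_dk,
                      enc$pr_p1, enc$pr_p2,
                      as.integer(enc$wl_sp), as.integer(enc$wl_ct),
                      as.numeric(enc$wl_t),
                      grid, isTRUE(log_events), as.integer(max_events))
  counts <- res$snapshots
  rownames(counts) <- system$species$name
  colnames(counts) <- format(grid, trim = TRUE)
  if (isTRUE(res$deadlock))
    message("simulation deadlocked (zero total propensity, empty wait list); ",
            "fast-forwarded to stop_time")
  out <- list(times = grid, counts = counts, n_events = res$n_events,
              deadlock = isTRUE(res$deadlock))
  if (isTRUE(log_events)) {
    kind <- ifelse(res$event_kind == 1L, "release", "fire")
    id <- ifelse(res$event_kind == 1L,
                 system$species$name[res$event_id + 1L],
                 as.character(res$event_id + 1L))
    out$events <- data.frame(time = res$event_time, kind = kind, id = id,
                             stringsAsFactors = FALSE)
  }
  out
}

#' Reference direct-method SSA (plain R, no delays)
#'
#' An independent, deliberately simple Gillespie direct-method implementation
#' in pure R: full propensity recomputation every step, no wait list, no
#' dependency graph. It exists as a statistical oracle against which the
#' compiled delayed engine is checked in the zero-delay case; it shares no
#' code with the C++ path. Delayed products are not supported and raise an
#' error.
#'
#' @param system a [reaction_system()] whose products all have delay kind
#'   `none` and whose wait list is empty.
#' @param stop_time end of simulated time.
#' @param seed integer seed, or `NULL`.
#' @return named integer vector of species counts at `stop_time`.
#' @export
ssa_direct_reference <- function(system, stop_time, seed = NULL) {
  stopifnot(inherits(system, "reaction_system"))
  if (any(vapply(system$reactions,
                 function(r) any(r$products$kind != "none"), TRUE)))
    stop("reference implementation supports zero-delay systems only")
  if (nrow(system$waitlist)) stop("reference implementation: empty waitlist only")
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- stats::setNames(as.numeric(system$species$count), system$species$name)
  t <- 0
  repeat {
    a <- vapply(system$reactions, propensity, numeric(1L), populations = x)
    atot <- sum(a)
    if (atot <= 0) break
    t <- t + stats::rexp(1L, atot)
    if (t > stop_time) break
    j <- sample.int(length(a), 1L, prob = a)
    r <- system$reactions[[j]]
    cons <- r$reactants$consumed
    if (any(cons)) {
      dec <- tapply(r$reactants$stoich[cons], r$reactants$species[cons], sum)
      x[names(dec)] <- x[names(dec)] - dec
    }
    if (nrow(r$products)) {
      inc <- tapply(r$products$stoich, r$products$species, sum)
      x[names(inc)] <- x[names(inc)] + inc
    }
  }
  stats::setNames(as.integer(x), names(x))
}
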