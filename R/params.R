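#' Delay specification
#'
#' Designated reaction products are not released at firing time but scheduled
#' on a wait list at firing time plus a sampled delay. Supported delay laws:
#'
#' * `none` — zero delay (released immediately);
#' * `constant` — fixed delay `value` (time units);
#' * `gaussian` — Normal(`mean`, `sd`) truncated at zero (resampled up to 100
#'   times, then clamped);
#' * `gamma` — Gamma(`shape`, `scale`), the law recommended for realistic
#'   transcription/translation elongation times;
#' * `exponential` — Exponential with `rate`.
#'
#' @param kind one of `"none"`, `"constant"`, `"gaussian"`, `"gamma"`,
#'   `"exponential"`.
#' @param value,mean,sd,shape,scale,rate distribution parameters; those
#'   required by `kind` must be supplied and (except `mean`) strictly
#'   positive.
#' @return an object of class `delay_spec`.
#' @examples
#' delay_spec("gamma", shape = 2, scale = 1)
#' @export
delay_spec <- function(kind = c("none", "constant", "gaussian", "gamma",
                                "exponential"),
                       value = NULL, mean = NULL, sd = NULL,
                       shape = NULL, scale = NULL, rate = NULL) {
  kind <- match.arg(kind)
  need <- function(x, nm, positive = TRUE) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("delay kind '%s' requires numeric parameter '%s'", kind, nm))
    if (positive && x <= 0)
      stop(sprintf("delay parameter '%s' must be > 0", nm))
    as.numeric(x)
  }
  p <- switch(kind,
    none = c(0, 0),
    constant = c(need(value, "value"), 0),
    gaussian = c(need(mean, "mean", positive = FALSE), need(sd, "sd")),
    gamma = c(need(shape, "shape"), need(scale, "scale")),
    exponential = c(need(rate, "rate"), 0))
  structure(list(kind = kind, p1 = p[1L], p2 = p[2L]), class = "delay_spec")
}

#' @export
print.delay_spec <- function(x, ...) {
  cat("delay_spec:", format_delay(x), "\n")
  invisible(x)
}

# integer codes shared with the C++ engine
.delay_code <- c(none = 0L, constant = 1L, gaussian = 2L, gamma = 3L,
                 exponential = 4L)

format_delay <- function(spec) {
  switch(spec$kind,
    none = "none",
    constant = format(spec$p1),
    gaussian = sprintf("gauss:%s,%s", format(spec$p1), format(spec$p2)),
    gamma = sprintf("gamma:%s,%s", format(spec$p1), format(spec$p2)),
    exponential = sprintf("exp:%s", format(spec$p1)))
}

#' Sample a delay
#'
#' Draws `n` non-negative delay times from a [delay_spec()]. Gaussian draws
#' are truncated at zero by resampling (at most 100 attempts per draw) and
#' finally clamping, so the engine can never stall on a mostly-negative
#' specification.
#'
#' @param spec a [delay_spec()].
#' @param n number of draws.
#' @return numeric vector of `n` non-negative delays.
#' @export
sample_delay <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "delay_spec"))
  switch(spec$kind,
    none = rep(0, n),
    constant = rep(spec$p1, n),
    gaussian = vapply(seq_len(n), function(i) {
      for (k in 1:100) {
        d <- stats::rnorm(1L, spec$p1, spec$p2)
        if (d >= 0) return(d)
      }
      0
    }, numeric(1L)),
    gamma = stats::rgamma(n, shape = spec$p1, scale = spec$p2),
    exponential = stats::rexp(n, rate = spec$p1))
}

#' Kinetic rate constants for network compilation
#'
#' One scalar default per reaction class, in reciprocal time units
#' (bimolecular binding additionally per molecule). Any rate may be
#' overridden per gene (`transcription`, `translation`, `rna_degradation`,
#' `protein_degradation`) or per edge (`binding`, `unbinding`) via the
#' `overrides` list of named vectors, e.g.
#' `overrides = list(transcription = c(G1 = 0.5))`; edge overrides are named
#' `"source->target"`.
#'
#' The defaults describe a prokaryotic-scale single-gene-copy cell: mean RNA
#' level transcription/rna_degradation = 10 and mean protein level around
#' 100 per active gene, with promoter occupancy responsive to regulator
#' abundance.
#'
#' @param transcription,translation,rna_degradation,protein_degradation,binding,unbinding
#'   non-negative scalar rate constants.
#' @param overrides optional list of named numeric vectors as above.
#' @return an object of class `rate_params`.
#' @export
rate_params <- function(transcription = 0.1, translation = 0.05,
                        rna_degradation = 0.01, protein_degradation = 0.005,
                        binding = 0.001, unbinding = 0.1,
                        overrides = list()) {
  vals <- c(transcription = transcription, translation = translation,
            rna_degradation = rna_degradation,
            protein_degradation = protein_degradation,
            binding = binding, unbinding = unbinding)
  if (!all(is.finite(vals)) || any(vals < 0))
    stop("all rates must be finite and non-negative")
  structure(c(as.list(vals), list(overrides = overrides)),
            class = "rate_params")
}

.rate_for <- function(rates, what, key) {
  ov <- rates$overrides[[what]]
  if (!is.null(ov) && key %in% names(ov)) unname(ov[[key]]) else rates[[what]]
}

#' Delay assignment for compiled reaction systems
#'
#' @param rna_delay delay on the RNA product of every transcription reaction.
#' @param protein_delay delay on the protein product of every translation
#'   reaction.
#' @param promoter_delay delay on the re-release of promoter forms consumed
#'   by a transcription reaction (promoter occupancy during elongation).
#' @return an object of class `delay_params`.
#' @export
delay_params <- function(rna_delay = delay_spec("none"),
                         protein_delay = delay_spec("none"),
                         promoter_delay = delay_spec("none")) {
  stopifnot(inherits(rna_delay, "delay_spec"),
            inherits(protein_delay, "delay_spec"),
            inherits(promoter_delay, "delay_spec"))
  structure(list(rna_delay = rna_delay, protein_delay = protein_delay,
                 promoter_delay = promoter_delay), class = "delay_params")
}

#' Simulation run configuration
#'
#' @param stop_time end of simulated time T (> `start_time`).
#' @param readout_interval spacing of the readout grid; snapshots are taken
#'   at `start_time + i * readout_interval` (computed by index, not by
#'   accumulation) up to `stop_time`.
#' @param start_time beginning of simulated time.
#' @param seed master integer seed; all replicate randomness derives from it.
#' @param sample number of independent replicates for ensemble runs.
#' @param record `"rna_only"` (default expression readout) or
#'   `"rna_and_protein"`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(stop_time, readout_interval, start_time = 0,
                       seed = 1L, sample = 1L,
                       record = c("rna_only", "rna_and_protein")) {
  record <- match.arg(record)
  if (!is.numeric(stop_time) || !is.finite(stop_time))
    stop("stop_time must be a finite number")
  if (stop_time <= start_time) stop("stop_time must exceed start_time")
  if (!is.numeric(readout_interval) || readout_interval <= 0)
    stop("readout_interval must be > 0")
  if (readout_interval > stop_time - start_time)
    stop("readout_interval must not exceed stop_time - start_time")
  sample <- as.integer(sample)
  if (sample < 1L) stop("sample must be >= 1")
  structure(list(start_time = as.numeric(start_time),
                 stop_time = as.numeric(stop_time),
                 readout_interval = as.numeric(readout_interval),
                 seed = as.integer(seed), sample = sample, record = record),
            class = "sim_config")
}

readout_grid <- function(config) {
  n <- floor((config$stop_time - config$start_time) / config$readout_interval)
  config$start_time + (0:n) * config$readout_interval
}
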