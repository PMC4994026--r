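#' Observation (LFP) specification
#'
#' Maps population membrane potentials to the recorded source-level signal:
#' per source, `signal = channel_gain * sum_p contribution[p] * v_p(t)`.
#' Pyramidal populations dominate measured potentials, hence the default
#' mixture weights superficial pyramidal cells most heavily.
#'
#' @param contribution named numeric over [cmc_populations]: weight of each
#'   population's voltage in the signal.
#' @param channel_gain scalar or per-source gain.
#' @param noise_sd additive noise standard deviation (>= 0); noise is only
#'   ever added by the synthetic-data generator, never by [observe()].
#' @return object of class `observation_spec`.
#' @export
observation_spec <- function(contribution = c(ss = 0, sp = 0.8, ii = 0, dp = 0.2),
                             channel_gain = 10, noise_sd = 0) {
  contribution <- contribution[cmc_populations]
  if (length(contribution) != 4 || any(is.na(contribution)) ||
      !all(is.finite(contribution)))
    stop("contribution must be finite weights over the four populations")
  stopifnot(all(is.finite(channel_gain)), noise_sd >= 0)
  structure(list(contribution = contribution, channel_gain = channel_gain,
                 noise_sd = noise_sd),
            class = "observation_spec")
}

#' Project population states to an ERP matrix
#'
#' Deterministic linear readout of a simulation: per source the weighted sum
#' of population voltages times the channel gain.
#'
#' @param sim a `cmc_simulation` from [integrate_network()], or a 3-d array
#'   `[n_sources, 4, n_times]`.
#' @param spec an [observation_spec()].
#' @return ERP matrix `[n_sources x n_times]` with source rownames.
#' @export
observe <- function(sim, spec = observation_spec()) {
  stopifnot(inherits(spec, "observation_spec"))
  v <- if (inherits(sim, "cmc_simulation")) sim$v else sim
  if (!all(is.finite(v))) stop("non-finite population states")
  if (length(dim(v)) != 3 || dim(v)[2] != length(spec$contribution))
    stop("state array of wrong arity: expected [n_sources, 4, n_times]")
  n <- dim(v)[1]; nt <- dim(v)[3]
  gain <- rep_len(spec$channel_gain, n)
  out <- matrix(0, n, nt, dimnames = list(dimnames(v)[[1]], NULL))
  for (p in seq_along(spec$contribution))
    out <- out + spec$contribution[p] * v[, p, , drop = FALSE][, 1, ]
  out * gain
}

.as_stack <- function(x) {
  if (is.list(x) && !is.matrix(x)) do.call(cbind, x) else x
}

#' Proportion of variance explained by a model prediction
#'
#' `1 - SS_residual / SS_total`, with `SS_total` taken about the observed
#' grand mean and pooled over all sources, time points and conditions.  Equals
#' 1 for a perfect fit, 0 for predicting the grand mean, and can be negative.
#' Invariant under a common affine rescaling of both arguments.
#'
#' @param predicted,observed ERP matrices, or lists of per-condition matrices
#'   (concatenated before pooling); shapes must match.
#' @return scalar fit score in `[-Inf, 1]`.
#' @export
fit_score <- function(predicted, observed) {
  p <- .as_stack(predicted); o <- .as_stack(observed)
  if (!identical(dim(p), dim(o))) stop("predicted/observed shapes differ")
  sst <- sum((o - mean(o))^2)
  if (sst == 0) stop("observed data are constant: SS_total = 0")
  1 - sum((o - p)^2) / sst
}
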