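# The six states of the backward pair process. Two homologous loci are
# sampled at forward time t_end and traced backward:
#   S11 - two distinct individuals, both carriers
#   S00 - two distinct individuals, both non-carriers
#   S01 - two distinct individuals, one carrier and one non-carrier
#   S1  - loci coalesced in one carrier
#   S0  - loci coalesced in one non-carrier
#   SM  - at least one locus in an (unique-genotype) immigrant
pair_states <- c("S11", "S00", "S01", "S1", "S0", "SM")

# hard cap on any single backward rate, per generation. Rates of the form
# m/(1-C) or 1/(N C) diverge as a class empties; beyond ~1e3/generation a
# transition is instantaneous on every timescale used, so capping changes
# nothing physically while keeping the ODE system integrable.
.RATE_CAP <- 1e3

#' Sampling distribution of a random pair of loci
#'
#' Two cells are drawn independently at random from a community with
#' carrier fraction `C_end`; the pair starts in `S11`, `S01` or `S00` with
#' binomial probabilities `C_end^2`, `2 C_end (1 - C_end)`,
#' `(1 - C_end)^2`.
#'
#' @param C_end Carrier fraction at the sampling time, in `[0, 1]`.
#' @return Named probability vector over the six pair states.
#' @export
sample_pair <- function(C_end) {
  .check_C(C_end)
  stats::setNames(
    c(C_end^2, (1 - C_end)^2, 2 * C_end * (1 - C_end), 0, 0, 0),
    pair_states
  )
}

#' Backward transition-rate generator of the pair process
#'
#' Per-generation rates of the six-state pair process at carrier fraction
#' `C`, as a 6x6 generator matrix `Q` (rows = from-state; each row sums to
#' zero, so probability is conserved). The events are derived by forward
#' bookkeeping:
#'
#' * within-class coalescence: `S11 -> S1` at `1/(N C)` and `S00 -> S0` at
#'   `1/(N (1-C))` (two lineages in a class of that size share a parent);
#' * immigration: every immigrant is a non-carrier, so each *uncoalesced*
#'   non-carrier lineage is a fresh immigrant at backward rate `m/(1-C)`;
#'   `SM` is absorbing and immigrant genotypes are unique (non-identity).
#'   Coalesced states do not enter `SM`: once the pair has coalesced the
#'   sampled copies are identical descendants of one ancestor and identity
#'   is already decided;
#' * transfer (background locus only): forward transfer converts a
#'   non-carrier in place, keeping its background genome, so each
#'   background lineage in a carrier switches backward to the non-carrier
#'   class at \eqn{r(1-C)} (`S11 -> S01` at twice that rate; also
#'   `S01 -> S00` and `S1 -> S0`). Focal-locus lineages instead jump to the
#'   donor - another carrier - and never leave the carrier class; the
#'   donor may be the partner lineage, adding a second-order coalescence
#'   term `2 r (1-C)/(N C)` to `S11 -> S1` for the focal locus.
#'
#' Rates are capped at `1e3`/generation as a numerical guard for vanishing
#' class occupancies (see Details in the package vignette).
#'
#' @param C Carrier fraction at the current forward time.
#' @param p A [sweep_params()] object.
#' @param locus `"focal"` or `"background"`.
#' @return A 6x6 generator matrix with the six pair states as dimnames.
#' @export
backward_rates <- function(C, p, locus = c("focal", "background")) {
  locus <- match.arg(locus)
  .check_C(C)
  N <- p$N
  Cg <- min(max(C, 1e-15), 1 - 1e-15)
  rc11 <- min(1 / (N * Cg), .RATE_CAP)
  rc00 <- min(1 / (N * (1 - Cg)), .RATE_CAP)
  rmig <- min(p$m / (1 - Cg), .RATE_CAP)
  rsw <- p$r * (1 - Cg)
  Q <- matrix(0, 6, 6, dimnames = list(pair_states, pair_states))
  if (locus == "focal") {
    Q["S11", "S1"] <- rc11 + min(2 * rsw / (N * Cg), .RATE_CAP)
  } else {
    Q["S11", "S1"] <- rc11
    Q["S11", "S01"] <- 2 * rsw
    Q["S01", "S00"] <- rsw
    Q["S1", "S0"] <- rsw
  }
  Q["S00", "S0"] <- rc00
  Q["S00", "SM"] <- 2 * rmig
  Q["S01", "SM"] <- rmig
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

# dense interpolant of the forward carrier dynamics on [0, t_end],
# log-spaced early times to resolve the sweep transient
.forward_interp <- function(p, t_end, n = 4000) {
  times <- unique(c(0, exp(seq(log(min(1e-2, t_end / 10)), log(t_end),
                               length.out = n))))
  times[length(times)] <- t_end
  C <- .forward_solve(p, times, migration = TRUE)
  stats::approxfun(times, C, rule = 2)
}

#' Solve the backward pair process
#'
#' Integrates the master equation `dP/dtau = Q(C(t_end - tau))^T P` from the
#' sampling distribution [sample_pair()] at backward time `tau = 0` to
#' `tau = t_end` (forward time 0), with the forward carrier dynamics
#' supplied by a dense interpolation of [sweep_integrate()]'s solution.
#'
#' @param p A [sweep_params()] object.
#' @param t_end Sampling time in generations.
#' @param locus `"focal"` or `"background"`.
#' @param Cfun Optional function of forward time returning the carrier
#'   fraction (computed from `p` when omitted); lets one forward solve be
#'   shared between the two locus processes.
#' @return Named probability vector over the six states at forward time 0,
#'   with attributes `C_end` (carrier fraction at sampling) and
#'   `max_drift` (largest deviation of the total probability from 1 over
#'   checked output times; conserved to `1e-9`).
#' @export
solve_pair <- function(p, t_end, locus = c("focal", "background"),
                       Cfun = NULL) {
  locus <- match.arg(locus)
  stopifnot(t_end > 0)
  if (is.null(Cfun)) Cfun <- .forward_interp(p, t_end)
  C_end <- .check_C(Cfun(t_end))
  P0 <- sample_pair(C_end)
  f <- function(tau, P, parms) {
    Q <- backward_rates(Cfun(t_end - tau), p, locus)
    list(as.vector(crossprod(Q, P)))
  }
  taus <- unique(c(seq(0, t_end, length.out = 21), t_end))
  sol <- deSolve::lsoda(P0, taus, f, NULL, rtol = 1e-8, atol = 1e-14,
                        maxsteps = 1e5)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(taus))
    stop("backward integration of the pair process failed")
  totals <- rowSums(sol[, -1])
  drift <- max(abs(totals - 1))
  if (drift > 1e-9)
    stop(sprintf("pair-process probability drifted by %.3g", drift))
  P <- pmin(pmax(sol[nrow(sol), -1], 0), 1)
  structure(stats::setNames(as.numeric(P), pair_states),
            C_end = C_end, max_drift = drift)
}

# identity probability of a sampled pair given the state distribution at
# forward time 0: coalesced before t = 0, or both lineages still in the
# carrier class at t = 0 (the founding carriers are a single clone)
.pair_identity <- function(P) unname(P["S11"] + P["S1"] + P["S0"])

#' Focal and background diversity from the coalescence model
#'
#' Runs the backward pair process for both loci under the same forward
#' carrier dynamics and converts the identity probabilities into order-2
#' diversities. A pair is identical iff it coalesced before forward time 0
#' or both lineages are in the carrier class at time 0 (the `C0 N` founding
#' carriers are one clone, identical at both genomic regions; founding
#' non-carriers and immigrants are each unique). With `F` the identity
#' probability, `D = 1/F` (the order-2 Hill number equals the reciprocal of
#' the probability that two random copies are identical), and
#' `DR = D_bg / D_f = F_f / F_b`.
#'
#' @inheritParams solve_pair
#' @return An object of class `"coalescence_result"`: list with `F_f`,
#'   `F_b`, `D_f`, `D_bg`, `DR` and `C_end`.
#' @examples
#' \donttest{
#' p <- sweep_params(N = 1e8, s = 0.04, r = 1e-6, m = 0.02, C0 = 1e-5)
#' coalescent_dr(p, t_end = 5e6)
#' }
#' @export
coalescent_dr <- function(p, t_end, Cfun = NULL) {
  if (is.null(Cfun)) Cfun <- .forward_interp(p, t_end)
  Pf <- solve_pair(p, t_end, "focal", Cfun)
  Pb <- solve_pair(p, t_end, "background", Cfun)
  F_f <- .pair_identity(Pf)
  F_b <- .pair_identity(Pb)
  if (F_f <= 0 || F_b <= 0)
    stop("identity probability underflowed to 0; diversities undefined")
  structure(
    list(F_f = F_f, F_b = F_b, D_f = 1 / F_f, D_bg = 1 / F_b,
         DR = F_f / F_b, C_end = attr(Pf, "C_end")),
    class = "coalescence_result"
  )
}

#' @export
print.coalescence_result <- function(x, ...) {
  cat("Pair-coalescence diversity\n")
  cat(sprintf("  C(t_end) = %.4g\n", x$C_end))
  cat(sprintf("  focal locus:      F = %.4g, D_f  = %.4g\n", x$F_f, x$D_f))
  cat(sprintf("  background:       F = %.4g, D_bg = %.4g\n", x$F_b, x$D_bg))
  cat(sprintf("  diversity ratio:  DR = %.4g\n", x$DR))
  invisible(x)
}
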