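#' Parameters of the carrier/non-carrier compartment model
#'
#' Bundles the parameters of the deterministic two-compartment model of a
#' horizontally transferable beneficial allele: a community of constant size
#' `N` is split into carriers (fraction `C`) and non-carriers (`1 - C`).
#' Carriers have relative fitness `1 + s`; non-carriers acquire the allele
#' horizontally with per-capita probability `C * r` per generation; a
#' fraction `m` of the community is replaced each generation by immigrants
#' that all lack the allele.
#'
#' The selection coefficient can be given directly as `s`, or as a local
#' benefit `b` and carriage cost `eps`, in which case `s = b - eps`. If all
#' three are supplied they must agree.
#'
#' @param N Community carrying capacity (number of cells, >= 1).
#' @param s Selection coefficient (dimensionless fitness advantage of
#'   carriers). May be omitted when `b` and `eps` are given.
#' @param r Transfer-rate coefficient per gene per generation; the
#'   per-capita conversion probability of a non-carrier is `C * r`.
#' @param m Migration rate: fraction of the community replaced by immigrant
#'   non-carriers per generation.
#' @param C0 Initial carrier fraction.
#' @param b Optional local benefit of the trait.
#' @param eps Optional carriage cost.
#'
#' @return An object of class `"sweep_params"`: a list with elements `N`,
#'   `s`, `r`, `m`, `C0` (and `b`, `eps` when supplied).
#' @examples
#' p <- sweep_params(N = 1e8, s = 0.04, r = 1e-6, m = 0.02, C0 = 1e-5)
#' steady_states(p)
#' @export
sweep_params <- function(N, s = NULL, r, m = 0, C0, b = NULL, eps = NULL) {
  if (is.null(s)) {
    if (is.null(b) || is.null(eps))
      stop("supply either `s` or both `b` and `eps`")
    s <- b - eps
  } else if (!is.null(b) && !is.null(eps) &&
             abs(s - (b - eps)) > 1e-12) {
    stop("inconsistent parameters: s must equal b - eps")
  }
  stopifnot(
    length(N) == 1, is.finite(N), N >= 1,
    length(s) == 1, is.finite(s),
    length(r) == 1, r >= 0, r <= 1,
    length(m) == 1, m >= 0, m <= 1,
    length(C0) == 1, C0 >= 0, C0 <= 1
  )
  if (s < 0)
    warning("s < 0: carriers are disfavoured in the focal patch")
  structure(
    list(N = N, s = s, r = r, m = m, C0 = C0, b = b, eps = eps),
    class = "sweep_params"
  )
}

#' @export
print.sweep_params <- function(x, ...) {
  cat("Compartment-model parameters\n")
  cat(sprintf("  N = %g cells, s = %g, r = %g, m = %g, C0 = %g\n",
              x$N, x$s, x$r, x$m, x$C0))
  invisible(x)
}

.check_C <- function(C) {
  if (any(!is.finite(C)) || any(C < 0) || any(C > 1))
    stop("carrier fraction C must lie in [0, 1]")
  C
}

#' Rate of change of the carrier fraction
#'
#' The deterministic drift field of the compartment model,
#' \deqn{dC/dt = \frac{s C (1-C)}{1 + s C} + r C (1-C) - m C,}
#' where the first term is growth of the carrier compartment by selection,
#' the second is conversion of non-carriers by horizontal transfer, and the
#' last (present only with migration) is replacement of carriers by
#' immigrant non-carriers.
#'
#' @param C Carrier fraction, in `[0, 1]` (vectorised).
#' @param p A [sweep_params()] object.
#' @param migration Logical; include the `- m C` immigration term.
#' @return `dC/dt` per generation, same length as `C`.
#' @export
drift_field <- function(C, p, migration = TRUE) {
  .check_C(C)
  d <- p$s * C * (1 - C) / (1 + p$s * C) + p$r * C * (1 - C)
  if (migration) d <- d - p$m * C
  d
}

# analytic derivative of the drift field with respect to C
.drift_deriv <- function(C, p, migration = TRUE) {
  s <- p$s
  d <- s * ((1 - 2 * C) * (1 + s * C) - s * C * (1 - C)) / (1 + s * C)^2 +
    p$r * (1 - 2 * C)
  if (migration) d <- d - p$m
  d
}

#' Fixed points of the compartment model
#'
#' Solves `drift_field(C) = 0` for the carrier fraction. `C = 0` is always a
#' fixed point; interior fixed points are the real roots of the quadratic
#' obtained by multiplying the drift field by `(1 + sC)/C`. Without
#' migration the fixed points are `{0, 1}`; with migration and `r` near zero
#' the interior root is the migration-selection balance
#' `C* = (s - m) / ((m + 1) s)`. Roots outside `[0, 1]` are returned with
#' `admissible = FALSE` rather than dropped.
#'
#' @inheritParams drift_field
#' @return A data frame with columns `value`, `stability` (`"stable"`,
#'   `"unstable"` or `"neutral"`, from the sign of the drift-field
#'   derivative) and `admissible` (whether the root lies in `[0, 1]`). When
#'   `s = r = 0` and migration is absent or `m = 0` the field vanishes
#'   identically; a zero-row data frame with attribute `flat_field = TRUE`
#'   is returned.
#' @export
steady_states <- function(p, migration = TRUE) {
  s <- p$s; r <- p$r
  m <- if (migration) p$m else 0
  if (s == 0 && r == 0 && m == 0) {
    out <- data.frame(value = numeric(0), stability = character(0),
                      admissible = logical(0))
    attr(out, "flat_field") <- TRUE
    return(out)
  }
  roots <- 0
  # interior roots: -rs C^2 + (rs - s - r - ms) C + (s + r - m) = 0
  a <- -r * s
  b <- r * s - s - r - m * s
  cc <- s + r - m
  if (abs(a) > 0) {
    disc <- b^2 - 4 * a * cc
    if (disc >= 0) {
      # numerically stable quadratic roots
      q <- -(b + sign(b + (b == 0)) * sqrt(disc)) / 2
      roots <- c(roots, q / a, if (q != 0) cc / q)
    }
  } else if (abs(b) > 0) {
    roots <- c(roots, -cc / b)
  }
  roots <- roots[is.finite(roots)]
  roots <- roots[!duplicated(round(roots, 12))]
  tol <- 1e-9
  deriv <- .drift_deriv(roots, p, migration)
  data.frame(
    value = roots,
    stability = ifelse(abs(deriv) < 1e-14, "neutral",
                       ifelse(deriv < 0, "stable", "unstable")),
    admissible = roots >= -tol & roots <= 1 + tol
  )
}

#' Community-level horizontal gene flux
#'
#' The expected number of horizontal transfer events per generation in the
#' whole community, \eqn{r C (1-C) N}: each of the `(1-C) N`
#' non-carriers is converted with probability `C * r`. The flux vanishes at
#' `C = 0` (no donors) and `C = 1` (no recipients) and is maximal at
#' `C = 0.5`.
#'
#' @inheritParams drift_field
#' @return Events per generation, same length as `C`.
#' @export
gene_flux <- function(C, p) {
  .check_C(C)
  p$r * C * (1 - C) * p$N
}

#' Horizontal gene flux at steady state
#'
#' Evaluates [gene_flux()] at the stable steady state of the model. With
#' migration weaker than selection the system settles at the interior
#' migration-selection balance and the flux is sustained indefinitely;
#' without migration the allele fixes (`C* = 1`) and the steady flux is 0.
#'
#' @inheritParams drift_field
#' @return Events per generation. When migration overpowers selection and no
#'   interior steady state exists in `(0, 1)`, returns 0 with attribute
#'   `no_interior = TRUE` and signals a warning.
#' @export
steady_state_flux <- function(p, migration = TRUE) {
  ss <- steady_states(p, migration)
  ok <- ss$admissible & ss$stability == "stable" &
    ss$value > 1e-12 & ss$value < 1 - 1e-12
  if (!any(ok)) {
    stable1 <- any(ss$admissible & ss$stability == "stable" &
                     abs(ss$value - 1) <= 1e-12)
    if (stable1) return(0) # fixation: no recipients left
    warning("no interior steady state (migration overpowers selection); flux is 0")
    return(structure(0, no_interior = TRUE))
  }
  gene_flux(max(ss$value[ok]), p)
}

# uniform output grid with optional extra user times
.make_grid <- function(t_end, n, extra = NULL) {
  g <- seq(0, t_end, length.out = n)
  if (!is.null(extra)) g <- sort(unique(c(g, extra[extra >= 0 & extra <= t_end])))
  g
}

# lsoda forward solve of the drift field on a fixed time grid.
# Stops integration early (and pads with 0) if C decays below `floor`,
# which happens when migration overpowers selection and C underflows.
.forward_solve <- function(p, times, migration = TRUE,
                           rtol = 1e-8, atol = 1e-12, floor = 1e-30) {
  f <- function(t, y, parms) list(drift_field(min(max(y[1], 0), 1), p, migration))
  root <- function(t, y, parms) y[1] - floor
  use_root <- p$C0 > floor && (if (migration) p$m else 0) > 0
  sol <- if (use_root) {
    deSolve::lsoda(c(C = p$C0), times, f, NULL, rtol = rtol, atol = atol,
                   rootfunc = root, events = list(root = TRUE, terminalroot = 1))
  } else {
    deSolve::lsoda(c(C = p$C0), times, f, NULL, rtol = rtol, atol = atol)
  }
  if (attr(sol, "istate")[1] < 0)
    stop("forward integration of the compartment model failed")
  C <- rep(0, length(times))
  C[seq_len(nrow(sol))] <- sol[, 2]
  esc <- max(0, max(C) - 1, -min(C))
  if (esc > 1e-6)
    stop(sprintf("carrier fraction escaped [0,1] by %.3g", esc))
  pmin(pmax(C, 0), 1)
}

#' Integrate the compartment model forward in time
#'
#' Solves the drift-field ODE from `C(0) = C0` with an adaptive
#' Runge-Kutta/BDF solver (deSolve's `lsoda`, relative tolerance `1e-8`,
#' absolute `1e-12`) and records the carrier fraction, carrier count,
#' instantaneous horizontal gene flux and the running cumulative flux.
#'
#' The cumulative flux is the left-endpoint rectangle-rule integral of the
#' flux over the solution grid. The internal grid starts at `n_grid` points
#' and is doubled until the total cumulative flux changes by less than 0.5%
#' between refinements, so reported totals are grid-converged.
#'
#' @param p A [sweep_params()] object.
#' @param t_end Horizon in generations (> 0).
#' @param migration Logical; include the immigration term.
#' @param grid Optional vector of requested output times (merged into the
#'   internal uniform grid).
#' @param n_grid Initial number of uniform grid points (default 10001).
#' @return A `"sweep_trajectory"`: a data frame with columns `time`, `C`,
#'   `carriers`, `flux` and `cumulative_flux`, with the parameters attached
#'   as attributes.
#' @examples
#' p <- sweep_params(N = 1e8, s = 0.04, r = 1e-6, m = 0.02, C0 = 1e-5)
#' tr <- sweep_integrate(p, t_end = 1e5)
#' cumulative_flux(tr)  # ~2.5e6 expected transfer events
#' @export
sweep_integrate <- function(p, t_end, migration = TRUE, grid = NULL,
                            n_grid = 10001) {
  stopifnot(t_end > 0)
  n <- max(n_grid, 2)
  total <- Inf
  repeat {
    times <- .make_grid(t_end, n, grid)
    C <- .forward_solve(p, times, migration)
    flux <- gene_flux(C, p)
    cum <- c(0, cumsum(flux[-length(flux)] * diff(times)))
    prev <- total
    total <- cum[length(cum)]
    if (is.finite(prev) &&
        (total == prev || abs(total - prev) < 0.005 * max(abs(prev), 1e-300)))
      break
    if (n > 4e5) break # grid already very fine; flux is (near-)constant
    n <- 2L * n
  }
  out <- data.frame(time = times, C = C, carriers = C * p$N,
                    flux = flux, cumulative_flux = cum)
  if (!is.null(grid)) out <- out[out$time %in% grid, , drop = FALSE]
  structure(out, params = p, migration = migration,
            class = c("sweep_trajectory", "data.frame"))
}

#' Cumulative horizontal gene flux of a trajectory
#'
#' Left-endpoint rectangle-rule integral of the instantaneous gene flux over
#' the trajectory grid: the expected total number of horizontal transfer
#' events over the simulated interval.
#'
#' @param traj A `"sweep_trajectory"` from [sweep_integrate()] (or any data
#'   frame with `time` and `flux` columns and at least two rows).
#' @return Expected number of transfer events (scalar).
#' @export
cumulative_flux <- function(traj) {
  if (!is.data.frame(traj) || !all(c("time", "flux") %in% names(traj)))
    stop("`traj` must be a trajectory with `time` and `flux` columns")
  if (nrow(traj) < 2)
    stop("trajectory must contain at least two sample points")
  sum(traj$flux[-nrow(traj)] * diff(traj$time))
}

#' Parameters of the two-patch (focal + external environment) model
#'
#' Extended model in which the external environment is an explicit second
#' compartment rather than an unmodelled source of non-carrier immigrants.
#' Each patch runs the within-patch carrier dynamics with its own selection
#' coefficient (`s` in the focal patch, `s_env <= 0` outside, where the
#' trait is disfavoured), and cells are exchanged between the patches at a
#' balanced per-capita rate so both patch sizes stay constant.
#'
#' @param focal A [sweep_params()] object for the focal patch (`m` is
#'   ignored; migration is replaced by explicit exchange).
#' @param env_size_ratio Size of the external environment relative to the
#'   focal patch (>= 0).
#' @param s_env Selection coefficient of the trait outside the focal patch
#'   (<= 0).
#' @param exchange Per-capita rate at which focal-patch cells swap with
#'   environment cells, per generation, in `[0, 1]`.
#' @return An object of class `"two_patch_params"`.
#' @export
two_patch_params <- function(focal, env_size_ratio, s_env, exchange) {
  stopifnot(inherits(focal, "sweep_params"),
            env_size_ratio >= 0, s_env <= 0,
            exchange >= 0, exchange <= 1)
  structure(list(focal = focal, env_size_ratio = env_size_ratio,
                 s_env = s_env, exchange = exchange),
            class = "two_patch_params")
}

#' Integrate the two-patch model
#'
#' Solves the coupled carrier-fraction ODEs of the focal patch and the
#' external environment. With exchange rate `x` and size ratio `rho =
#' N_env / N_focal`, `x N_focal` cells swap patches per generation, so the
#' focal fraction gains `x (C_env - C_f)` and the environment fraction
#' `(x / rho) (C_f - C_env)`; within-patch selection and transfer use the
#' standard drift field with the patch-specific selection coefficient. The
#' environment starts devoid of carriers.
#'
#' In the limit of a large environment (`env_size_ratio >> 1`) the focal
#' patch reproduces the one-patch migration model with `m = exchange`; in
#' the limit of a small, selectively neutral environment the two patches
#' merge and the allele fixes everywhere as in the no-migration model.
#'
#' @param p2 A [two_patch_params()] object.
#' @param t_end Horizon in generations.
#' @param n_grid Number of uniform output points.
#' @return A list with elements `focal` and `env`, each a
#'   `"sweep_trajectory"` for its patch (flux columns use the patch's own
#'   cell count).
#' @export
two_patch_integrate <- function(p2, t_end, n_grid = 10001) {
  stopifnot(inherits(p2, "two_patch_params"), t_end > 0)
  pf <- p2$focal
  rho <- p2$env_size_ratio
  x <- p2$exchange
  pe <- structure(list(N = max(pf$N * rho, 1), s = p2$s_env, r = pf$r,
                       m = 0, C0 = 0), class = "sweep_params")
  times <- .make_grid(t_end, n_grid)
  f <- function(t, y, parms) {
    CF <- min(max(y[1], 0), 1); CE <- min(max(y[2], 0), 1)
    dF <- drift_field(CF, pf, migration = FALSE) + x * (CE - CF)
    dE <- drift_field(CE, pe, migration = FALSE) +
      if (rho > 0) (x / rho) * (CF - CE) else 0
    list(c(dF, dE))
  }
  sol <- deSolve::lsoda(c(CF = pf$C0, CE = 0), times, f, NULL,
                        rtol = 1e-8, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times))
    stop("two-patch integration failed")
  esc <- max(0, max(sol[, 2:3]) - 1, -min(sol[, 2:3]))
  if (esc > 1e-6)
    stop(sprintf("carrier fraction escaped [0,1] by %.3g", esc))
  mk <- function(C, p) {
    C <- pmin(pmax(C, 0), 1)
    flux <- gene_flux(C, p)
    cum <- c(0, cumsum(flux[-length(flux)] * diff(times)))
    structure(data.frame(time = times, C = C, carriers = C * p$N,
                         flux = flux, cumulative_flux = cum),
              params = p, migration = FALSE,
              class = c("sweep_trajectory", "data.frame"))
  }
  list(focal = mk(sol[, 2], pf), env = mk(sol[, 3], pe))
}
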