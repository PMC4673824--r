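# Experiment drivers: configuration handling, parameter scans and tabular
# output shared by the R API and the command-line front end.

.config_error <- function(msg) {
  stop(structure(class = c("hgtsweep_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.need_field <- function(x, field, where) {
  if (is.null(x[[field]]))
    .config_error(sprintf("missing required field `%s` in %s", field, where))
  x[[field]]
}

# write a data frame as comma-separated text with full double precision so
# that re-reading reproduces the values exactly
.write_csv17 <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
}

.write_outputs <- function(result, cfg, out_dir, name, runtime) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(out_dir, paste0(name, ".csv"))
  prov <- file.path(out_dir, paste0(name, ".provenance.json"))
  tryCatch({
    .write_csv17(result, csv)
    jsonlite::write_json(
      list(config = cfg,
           package_version = as.character(utils::packageVersion("hgtsweep")),
           runtime_seconds = runtime,
           solver = list(rtol = 1e-8, atol = 1e-12)),
      prov, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  }, error = function(e) {
    stop(structure(class = c("hgtsweep_io_error", "error", "condition"),
                   list(message = conditionMessage(e), call = NULL)))
  })
  invisible(c(csv = csv, provenance = prov))
}

.run_one <- function(model, prm, seed) {
  t0 <- proc.time()[["elapsed"]]
  rec <- switch(
    model,
    compartment = {
      p <- sweep_params(N = prm$N, s = prm$s, r = prm$r,
                        m = if (is.null(prm$m)) 0 else prm$m, C0 = prm$C0)
      tr <- sweep_integrate(p, prm$t_end, migration = p$m > 0)
      data.frame(C_end = tr$C[nrow(tr)], cumulative_flux = cumulative_flux(tr))
    },
    two_patch = {
      pf <- sweep_params(N = prm$N, s = prm$s, r = prm$r, m = 0, C0 = prm$C0)
      p2 <- two_patch_params(pf, env_size_ratio = prm$env_size_ratio,
                             s_env = prm$s_env, exchange = prm$exchange)
      tr <- two_patch_integrate(p2, prm$t_end)
      data.frame(C_end = tr$focal$C[nrow(tr$focal)],
                 C_end_env = tr$env$C[nrow(tr$env)],
                 cumulative_flux = cumulative_flux(tr$focal))
    },
    coalescence = {
      p <- sweep_params(N = prm$N, s = prm$s, r = prm$r,
                        m = if (is.null(prm$m)) 0 else prm$m, C0 = prm$C0)
      res <- coalescent_dr(p, prm$t_end)
      data.frame(F_f = res$F_f, F_b = res$F_b, D_f = res$D_f,
                 D_bg = res$D_bg, DR = res$DR, C_end = res$C_end)
    },
    ibm = {
      p <- ibm_params(N = prm$N, n = if (is.null(prm$n)) 1 else prm$n,
                      z = if (is.null(prm$z)) 1 else prm$z,
                      s = prm$s, r = prm$r, m = prm$m, C0 = prm$C0,
                      t_end = prm$t_end, seed = seed)
      res <- ibm_run(p, record_every = max(1L, p$t_end %/% 100L))
      last <- res[nrow(res), ]
      data.frame(C_end = last$C, cumulative_flux = last$cumulative_flux,
                 D_f = last$D_f, D_bg = last$D_bg, DR = last$DR)
    }
  )
  rec$seed <- seed
  attr(rec, "runtime") <- proc.time()[["elapsed"]] - t0
  rec
}

#' Run a configured experiment
#'
#' Dispatches a single configuration to one of the four models, optionally
#' scanning one parameter over a grid (with replicate seeds for the
#' stochastic individual-based model), and writes the result table plus a
#' JSON provenance sidecar.
#'
#' The configuration is a list (or path to a JSON file) with fields:
#' \describe{
#'   \item{model}{one of `"compartment"`, `"two_patch"`, `"coalescence"`,
#'     `"ibm"`.}
#'   \item{params}{named list of model parameters, including `t_end`.}
#'   \item{scan}{optional list with `param` (name) and `values` (non-empty
#'     grid); each grid point overrides that parameter.}
#'   \item{replicates}{integer >= 1, IBM only (deterministic models must
#'     use 1); replicate `k` runs with seed `seed + k - 1`.}
#'   \item{seed}{base RNG seed (default 1).}
#'   \item{name}{basename for the output files (default `"experiment"`).}
#' }
#'
#' Deterministic models re-run identically; stochastic models re-run
#' identically given the same base seed, so output CSVs are byte-stable.
#' Per-run wall times are recorded in the provenance sidecar (keeping them
#' out of the CSV preserves byte-identity across re-runs).
#'
#' @param cfg Configuration list or path to a JSON configuration file.
#' @param out_dir Output directory for `<name>.csv` and
#'   `<name>.provenance.json`; `NULL` writes nothing.
#' @return A data frame with one row per grid point and replicate: the
#'   scanned parameter values, summary statistics, and the seed used.
#' @examples
#' cfg <- list(model = "compartment",
#'             params = list(N = 1e8, s = 0.025, r = 1e-6, m = 0.02,
#'                           C0 = 1e-5, t_end = 1e5))
#' run_config(cfg)  # C_end ~ 0.196 at the migration-selection balance
#' @export
run_config <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) {
    if (!file.exists(cfg)) .config_error(sprintf("config file not found: %s", cfg))
    cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  }
  if (!is.list(cfg)) .config_error("config must be a list or a JSON file path")
  model <- .need_field(cfg, "model", "config")
  if (!model %in% c("compartment", "two_patch", "coalescence", "ibm"))
    .config_error(sprintf("unknown value for field `model`: %s", model))
  prm <- .need_field(cfg, "params", "config")
  required <- if (model == "two_patch")
    c("N", "s", "r", "C0", "t_end", "env_size_ratio", "s_env", "exchange")
  else c("N", "s", "r", "m", "C0", "t_end")
  for (f in required)
    if (is.null(prm[[f]]))
      .config_error(sprintf("missing required field `params.%s` for model %s",
                            f, model))
  replicates <- if (is.null(cfg$replicates)) 1L else as.integer(cfg$replicates)
  if (replicates < 1) .config_error("field `replicates` must be >= 1")
  if (replicates > 1 && model != "ibm")
    .config_error("field `replicates` must be 1 for deterministic models")
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  name <- if (is.null(cfg$name)) "experiment" else cfg$name

  grid <- data.frame(.point = 1)
  if (!is.null(cfg$scan)) {
    axis <- .need_field(cfg$scan, "param", "config$scan")
    values <- .need_field(cfg$scan, "values", "config$scan")
    if (length(values) == 0) .config_error("field `scan.values` must be non-empty")
    grid <- data.frame(.point = seq_along(values), value = unlist(values))
    names(grid)[2] <- axis
  }

  t0 <- proc.time()[["elapsed"]]
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    prm_g <- prm
    if (ncol(grid) > 1) prm_g[[names(grid)[2]]] <- grid[g, 2]
    for (k in seq_len(replicates)) {
      rec <- .run_one(model, prm_g, seed + k - 1L)
      base <- data.frame(model = model, prm_g[required], replicate = k)
      rows[[length(rows) + 1L]] <- cbind(base, rec)
    }
  }
  result <- do.call(rbind, rows)
  runtime <- proc.time()[["elapsed"]] - t0
  .write_outputs(result, cfg, out_dir, name, runtime)
  result
}

#' Cumulative gene flux against selection pressure
#'
#' Scans the selection coefficient over `[0.025, 0.15]` in steps of 0.005,
#' with and without migration (`m = 0.02` and `m = 0`), at transfer rate `1e-6`,
#' `N = 1e8`, `C0 = 1e-5`, and integrates the compartment model to
#' `t = 1e5` generations, recording the cumulative horizontal gene flux.
#' With migration the flux peaks at intermediate selection (`s = 0.04`,
#' about 2.5e6 events); without migration it is maximal at the weakest
#' selection and about three orders of magnitude smaller.
#'
#' @param out_dir Optional output directory (CSV + provenance JSON).
#' @return Data frame with columns `s`, `m`, `C_end`, `cumulative_flux`.
#' @export
repro_fig2b <- function(out_dir = NULL) {
  s_grid <- seq(0.025, 0.15, by = 0.005)
  t0 <- proc.time()[["elapsed"]]
  rows <- lapply(c(0.02, 0), function(m) {
    do.call(rbind, lapply(s_grid, function(s) {
      p <- sweep_params(N = 1e8, s = s, r = 1e-6, m = m, C0 = 1e-5)
      tr <- sweep_integrate(p, 1e5, migration = m > 0)
      data.frame(s = s, m = m, C_end = tr$C[nrow(tr)],
                 cumulative_flux = cumulative_flux(tr))
    }))
  })
  result <- do.call(rbind, rows)
  .write_outputs(result, list(experiment = "flux_vs_selection"), out_dir,
                 "flux_vs_selection", proc.time()[["elapsed"]] - t0)
  result
}

#' Diversity-ratio and carrier-fraction scans
#'
#' Regenerates the diversity-ratio experiments as parameter scans:
#' \describe{
#'   \item{`"a_to_d"`}{coalescence-model `DR` and final carrier fraction
#'     versus selection `s` for several transfer rates, with and without
#'     migration (`N = 1e8`, `t_end = 5e6`, `C0 = 1e-5`).}
#'   \item{`"e_f"`}{the same quantities versus migration rate `m` at
#'     `s = 0.05`.}
#'   \item{`"g"`}{individual-based model: mean and s.d. of `DR` over
#'     replicates versus `s` for `n` in `{1, 10, 20}` niches at `z = 0.2`.}
#'   \item{`"h"`}{IBM `DR` versus `s` at `n = 20` for two niche-association
#'     levels: twice-own-niche competition (`z = 2/21`) and full
#'     specialisation (`z = 1`).}
#' }
#'
#' IBM panels default to a desk-scale setting (`N = 1e5`, `t_end = 1e4`,
#' 20 replicates, a single `s`, and the transfer rate raised to `1e-3`
#' so that the community-level event rate \eqn{r N} matches the full-scale
#' regime); `full_scale = TRUE` restores `N = 1e6`, `t_end = 1e5`,
#' transfer rate `1e-4`, 50 replicates, which needs cluster-scale compute.
#'
#' @param panel Which panel group to compute.
#' @param s_values,r_values,m_values Optional grid overrides.
#' @param replicates Number of IBM replicates per grid point.
#' @param full_scale Use the full-scale IBM setting.
#' @param seed Base seed; IBM replicate `k` uses `seed + k - 1`.
#' @param out_dir Optional output directory (CSV + provenance JSON).
#' @return Data frame of scan records (one row per grid point and, for the
#'   IBM, per replicate).
#' @export
repro_fig3 <- function(panel = c("a_to_d", "e_f", "g", "h"),
                       s_values = NULL, r_values = NULL, m_values = NULL,
                       replicates = NULL, full_scale = FALSE, seed = 1L,
                       out_dir = NULL) {
  panel <- match.arg(panel)
  t0 <- proc.time()[["elapsed"]]
  result <- switch(
    panel,
    a_to_d = {
      s_grid <- if (is.null(s_values)) seq(0.005, 0.15, by = 0.005) else s_values
      r_grid <- if (is.null(r_values)) c(1e-6, 1e-5, 1e-4) else r_values
      m_grid <- if (is.null(m_values)) c(0, 0.02) else m_values
      grid <- expand.grid(s = s_grid, r = r_grid, m = m_grid)
      do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
        p <- sweep_params(N = 1e8, s = grid$s[i], r = grid$r[i],
                          m = grid$m[i], C0 = 1e-5)
        res <- coalescent_dr(p, 5e6)
        cbind(grid[i, ], data.frame(DR = res$DR, D_f = res$D_f,
                                    D_bg = res$D_bg, C_end = res$C_end))
      }))
    },
    e_f = {
      m_grid <- if (is.null(m_values)) seq(0, 0.045, by = 0.005) else m_values
      r_grid <- if (is.null(r_values)) c(1e-6, 1e-5, 1e-4) else r_values
      s <- if (is.null(s_values)) 0.05 else s_values[1]
      grid <- expand.grid(m = m_grid, r = r_grid)
      do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
        p <- sweep_params(N = 1e8, s = s, r = grid$r[i], m = grid$m[i],
                          C0 = 1e-5)
        res <- coalescent_dr(p, 5e6)
        cbind(data.frame(s = s), grid[i, ],
              data.frame(DR = res$DR, D_f = res$D_f, D_bg = res$D_bg,
                         C_end = res$C_end))
      }))
    },
    g = ,
    h = {
      N <- if (full_scale) 1e6 else 1e5
      t_end <- if (full_scale) 1e5 else 1e4
      r <- if (full_scale) 1e-4 else 1e-3 # keep r * N at the full-scale value
      reps <- if (!is.null(replicates)) replicates else if (full_scale) 50L else 20L
      s_grid <- if (is.null(s_values)) 0.05 else s_values
      cfgs <- if (panel == "g")
        data.frame(n = c(1, 10, 20), z = 0.2)
      else data.frame(n = 20, z = c(2 / 21, 1))
      grid <- expand.grid(s = s_grid, i = seq_len(nrow(cfgs)))
      grid <- cbind(grid, cfgs[grid$i, , drop = FALSE])
      do.call(rbind, lapply(seq_len(nrow(grid)), function(gi) {
        do.call(rbind, lapply(seq_len(reps), function(k) {
          p <- ibm_params(N = N, n = grid$n[gi], z = grid$z[gi],
                          s = grid$s[gi], r = r, m = 0.02, C0 = 1000 / N,
                          t_end = t_end, seed = seed + k - 1L)
          res <- ibm_run(p, record_every = max(1L, t_end %/% 50L))
          last <- res[nrow(res), ]
          data.frame(s = grid$s[gi], n = grid$n[gi], z = grid$z[gi],
                     N = N, t_end = t_end, replicate = k,
                     seed = seed + k - 1L, C_end = last$C,
                     cumulative_flux = last$cumulative_flux,
                     D_f = last$D_f, D_bg = last$D_bg, DR = last$DR)
        }))
      }))
    }
  )
  .write_outputs(result, list(experiment = paste0("dr_", panel),
                              full_scale = full_scale, seed = seed),
                 out_dir, paste0("dr_", panel),
                 proc.time()[["elapsed"]] - t0)
  result
}
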