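# Thermodynamic model of many monodisperse domains per unit membrane area.
# State variables: domain number density n (nm^-2), coat area A_d (nm^2)
# and cap depth u, at fixed tension sigma and average protein coverage
# phi_bar. The coat inside domains is close-packed (protein fraction 1),
# so protein conservation reads n * A_d + phi_disp = phi_bar.

.AD_MIN <- 1e3
.AD_MAX <- 1e6

#' Free-energy density of a domain ensemble state
#'
#' Per unit projected membrane area (kBT nm^-2, with kBT = 1 internally):
#' `f = n [E_mech(A_d, u; sigma) + (A_d / a_p) delta] +
#' (phi_disp / a_p) e_f + n (ln(n a_p) - 1)`,
#' where `phi_disp = phi_bar - n A_d` is the dispersed protein fraction,
#' `e_f = 2 kappa_c a_p c0^2` the per-protein flat-frustration energy, and
#' the last term the ideal translational entropy of the domains with
#' reference area `a_p`. `E_mech` includes the rim term.
#'
#' @param n domain number density (nm^-2), >= 0.
#' @param A_d coat area (nm^2).
#' @param u cap depth in [0, 2].
#' @param coat a [coat_params()] object.
#' @param sigma membrane tension (kBT nm^-2).
#' @param phi_bar average protein area fraction in [0, 1).
#' @return free-energy density (kBT nm^-2).
#' @export
free_energy_density <- function(n, A_d, u, coat, sigma, phi_bar) {
  stopifnot(inherits(coat, "coat_params"))
  if (n < 0) stop("n must be >= 0")
  if (n * A_d > phi_bar * (1 + 1e-12))
    stop("protein conservation violated: n * A_d > phi_bar")
  phi_disp <- max(phi_bar - n * A_d, 0)
  e_f <- 2 * coat$kappa_c * coat$a_p * coat$c0^2
  ent <- if (n > 0) n * (log(n * coat$a_p) - 1) else 0
  dom <- if (n > 0) {
    E <- mech_energy(cap_from(A_d, u), coat, sigma)
    n * (E + (A_d / coat$a_p) * coat$delta_assembly)
  } else 0
  dom + (phi_disp / coat$a_p) * e_f + ent
}

# objective in internal coordinates (t, logA, u); t = condensed fraction,
# n = t * phi_bar / A_d, which turns protein conservation into a box bound
.f_obj <- function(par, coat, sigma, phi_bar) {
  t <- par[1]; A_d <- exp(par[2]); u <- par[3]
  n <- t * phi_bar / A_d
  free_energy_density(n, A_d, u, coat, sigma, phi_bar)
}

.as_state <- function(par, coat, sigma, phi_bar, f, diag) {
  t <- par[1]; A_d <- exp(par[2]); u <- par[3]
  n <- t * phi_bar / A_d
  shape <- cap_from(A_d, u)
  structure(list(
    n = n, shape = shape, phi_bar = phi_bar,
    phi_disp = phi_bar - n * A_d,
    f = f, s_stored = n * shape$dA_excess,
    sigma = sigma, coat = coat, par = par, diagnostics = diag),
    class = "ensemble_state")
}

#' Minimize ensemble free energy at one tension
#'
#' Bounded local minimization over (condensed fraction, log A_d, u) with
#' `A_d` in [1e3, 1e6] nm^2 and u in [0, 2]. Without `init`, a
#' deterministic 5 x 5 x 5 multi-start lattice is used and the lowest-f
#' candidate returned (ties within 1e-10 broken toward smaller u, then
#' smaller A_d); with `init` (a previous `ensemble_state`) the search warm
#' starts there and the returned f never exceeds the initial f.
#'
#' @inheritParams free_energy_density
#' @param init optional previous state for warm starting.
#' @return Object of class `ensemble_state` with fields `n`, `shape`,
#'   `phi_bar`, `phi_disp`, `f`, `s_stored` and minimizer diagnostics.
#' @export
minimize_state <- function(coat, sigma, phi_bar, init = NULL) {
  stopifnot(inherits(coat, "coat_params"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (phi_bar < 0 || phi_bar >= 1) stop("phi_bar must lie in [0, 1)")
  if (phi_bar == 0) {
    return(.as_state(c(0, log(.AD_MIN), 0), coat, sigma, 0,
                     0, list(convergence = 0L, n_starts = 0L)))
  }
  lower <- c(1e-9, log(.AD_MIN), 0)
  upper <- c(1, log(.AD_MAX), 2)
  starts <- if (is.null(init)) {
    grid <- expand.grid(t = c(0.02, 0.25, 0.5, 0.75, 0.98),
                        logA = seq(log(.AD_MIN), log(.AD_MAX), length.out = 5),
                        u = c(0.05, 0.5, 1, 1.5, 1.95))
    lapply(seq_len(nrow(grid)), function(i) as.numeric(grid[i, ]))
  } else {
    stopifnot(inherits(init, "ensemble_state"))
    list(pmin(pmax(init$par, lower), upper))
  }

  best <- NULL
  n_fail <- 0L
  for (s0 in starts) {
    opt <- tryCatch(
      stats::optim(s0, .f_obj, coat = coat, sigma = sigma,
                   phi_bar = phi_bar, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e3, maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) { n_fail <- n_fail + 1L; next }
    cand <- list(par = opt$par, f = opt$value, conv = opt$convergence)
    if (is.null(best)) { best <- cand; next }
    if (cand$f < best$f - 1e-10) {
      best <- cand
    } else if (abs(cand$f - best$f) <= 1e-10) {
      # tie-break toward smaller u, then smaller A_d
      if (cand$par[3] < best$par[3] - 1e-12 ||
          (abs(cand$par[3] - best$par[3]) <= 1e-12 &&
           cand$par[2] < best$par[2] - 1e-12))
        best <- cand
    }
  }
  if (is.null(best))
    stop("minimize_state: no start converged (", n_fail, " failures)")

  # warm starts must never degrade the incoming state
  if (!is.null(init)) {
    f_init <- .f_obj(pmin(pmax(init$par, lower), upper),
                     coat, sigma, phi_bar)
    if (f_init < best$f) best <- list(par = init$par, f = f_init, conv = 0L)
  }
  # never return an infeasible state
  if (best$par[1] * phi_bar > phi_bar + 1e-12)
    stop("minimize_state returned an infeasible state")
  .as_state(best$par, coat, sigma, phi_bar, best$f,
            list(convergence = best$conv, n_starts = length(starts),
                 n_failed = n_fail))
}

#' @export
print.ensemble_state <- function(x, ...) {
  cat(sprintf(
    "<ensemble_state '%s'>  sigma=%.4g  phi_bar=%g\n",
    x$coat$name, x$sigma, x$phi_bar))
  cat(sprintf(
    "  n=%.4g nm^-2 (%.3g um^-2)  A_d=%.4g nm^2  u=%.4f (psi=%.1f deg)\n",
    x$n, x$n * 1e6, x$shape$A_d, x$shape$u, x$shape$psi * 180 / pi))
  cat(sprintf("  f=%.6g kBT/nm^2  stored area fraction=%.4g\n",
              x$f, x$s_stored))
  invisible(x)
}

#' Tension sweep of the domain ensemble
#'
#' For each coverage in `phi_bar_list`, minimizes the ensemble free energy
#' along the tension protocol with continuation: each tension warm-starts
#' from the previous minimizer on the same leg (the first point of each
#' sweep uses the full multi-start). Emits per-tension curves of projected
#' diameter, domain density and projected areal strain
#' `areal_strain(sigma) = s(sigma_min) - s(sigma)` with
#' `s = n * dA_excess` the stored area fraction.
#'
#' @param coat a [coat_params()] object.
#' @param protocol a [tension_protocol()]; default 60 log-spaced points in
#'   [1e-4, 1] kBT nm^-2.
#' @param phi_bar_list protein coverages; default `c(0.01, 0.03, 0.06)`.
#' @return list of `ensemble_sweep` objects (one per coverage), each with
#'   a data.frame `states` of columns (leg, sigma, n, A_d, u, psi_deg,
#'   D_proj_nm, s_stored, areal_strain, phi_disp, f).
#' @export
sweep_tension <- function(coat, protocol = default_protocol(direction = "up"),
                          phi_bar_list = c(0.01, 0.03, 0.06)) {
  stopifnot(inherits(coat, "coat_params"),
            inherits(protocol, "tension_protocol"))
  lapply(phi_bar_list, function(phi_bar) {
    rows <- list(); prev <- NULL
    for (leg_name in names(protocol$legs)) {
      grid <- protocol$legs[[leg_name]]
      for (k in seq_along(grid)) {
        st <- if (is.null(prev))
          minimize_state(coat, grid[k], phi_bar)
        else minimize_state(coat, grid[k], phi_bar, init = prev)
        prev <- st
        rows[[length(rows) + 1L]] <- data.frame(
          leg = leg_name, sigma = grid[k], n = st$n, A_d = st$shape$A_d,
          u = st$shape$u, psi_deg = st$shape$psi * 180 / pi,
          D_proj_nm = st$shape$D_proj, s_stored = st$s_stored,
          phi_disp = st$phi_disp, f = st$f)
      }
    }
    states <- do.call(rbind, rows)
    s0 <- states$s_stored[which.min(states$sigma)]
    states$areal_strain <- s0 - states$s_stored
    structure(list(states = states, coat = coat, phi_bar = phi_bar,
                   protocol = protocol),
              class = "ensemble_sweep")
  })
}

#' @export
print.ensemble_sweep <- function(x, ...) {
  cat(sprintf("<ensemble_sweep '%s'>  phi_bar=%g, %d states\n",
              x$coat$name, x$phi_bar, nrow(x$states)))
  invisible(x)
}

.spearman <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

#' Regime report for ensemble sweeps
#'
#' Summarizes, per coat, the tension-adaptation regime of up-leg sweeps:
#' monotone trends (Spearman) of domain density and coat area versus
#' tension, the contact angle at the lowest tension, a shape-invariance
#' score over the upper half of the tension grid, and strain comparisons
#' at the low/high tension deciles across coverages. Labels: `"splitting"`
#' when density rises and coat area falls with tension (|rho| > 0.8);
#' `"number_reduction"` when density falls by more than half over the
#' upper half-grid while (R, u) vary by less than 10%; otherwise
#' `"indeterminate"`.
#'
#' @param sweeps named list with elements `cav1` and `ptrf`, each a list of
#'   `ensemble_sweep` objects from [sweep_tension()] over the same protocol
#'   and coverages.
#' @return Object of class `regime_report`.
#' @export
regime_report <- function(sweeps) {
  stopifnot(all(c("cav1", "ptrf") %in% names(sweeps)))

  one_coat <- function(sw_list) {
    per_cov <- lapply(sw_list, function(sw) {
      st <- sw$states[sw$states$leg == names(sw$protocol$legs)[1], ]
      st <- st[order(st$sigma), ]
      m <- nrow(st)
      upper <- st[st$sigma >= stats::median(st$sigma), ]
      R <- ifelse(upper$u > 0, sqrt(upper$A_d / (2 * pi * upper$u)), Inf)
      rel_var <- function(x) {
        x <- x[is.finite(x)]
        if (!length(x) || mean(x) == 0) return(NA_real_)
        (max(x) - min(x)) / abs(mean(x))
      }
      n_drop <- if (upper$n[1] > 0)
        1 - upper$n[nrow(upper)] / upper$n[1] else NA_real_
      lo_dec <- st[st$sigma <= stats::quantile(st$sigma, 0.1), ]
      hi_dec <- st[st$sigma >= stats::quantile(st$sigma, 0.9), ]
      list(phi_bar = sw$phi_bar,
           rho_n = .spearman(st$sigma, st$n),
           rho_A = .spearman(st$sigma, st$A_d),
           psi_min_sigma = st$psi_deg[1],
           n_drop_upper = n_drop,
           relvar_R_upper = rel_var(R),
           relvar_u_upper = rel_var(upper$u),
           strain_low = mean(lo_dec$areal_strain),
           strain_high = mean(hi_dec$areal_strain))
    })
    agg <- function(fld) vapply(per_cov, `[[`, numeric(1), fld)
    splitting <- all(agg("rho_n") > 0.8, na.rm = FALSE) &&
      all(agg("rho_A") < -0.8, na.rm = FALSE)
    splitting <- isTRUE(splitting) && !anyNA(c(agg("rho_n"), agg("rho_A")))
    number_red <- all(agg("n_drop_upper") > 0.5, na.rm = FALSE) &&
      all(agg("relvar_R_upper") < 0.1) && all(agg("relvar_u_upper") < 0.1)
    number_red <- isTRUE(number_red) &&
      !anyNA(c(agg("n_drop_upper"), agg("relvar_R_upper"),
               agg("relvar_u_upper")))
    label <- if (splitting) "splitting"
    else if (number_red) "number_reduction" else "indeterminate"
    list(per_coverage = per_cov, label = label,
         strain_low = agg("strain_low"), strain_high = agg("strain_high"),
         psi_min_sigma = agg("psi_min_sigma"))
  }

  cav1 <- one_coat(sweeps$cav1)
  ptrf <- one_coat(sweeps$ptrf)
  cov_dep <- function(x) {
    if (mean(x) == 0) return(0)
    (max(x) - min(x)) / abs(mean(x))
  }
  comparison <- list(
    cav1_releases_more_low = mean(cav1$strain_low) > mean(ptrf$strain_low),
    ptrf_releases_more_high = mean(ptrf$strain_high) > mean(cav1$strain_high),
    ptrf_cov_dep_high = cov_dep(ptrf$strain_high),
    ptrf_cov_dep_low = cov_dep(ptrf$strain_low))
  structure(list(cav1 = cav1, ptrf = ptrf, comparison = comparison),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat("<regime_report>\n")
  cat(sprintf("  cav1: %s  (psi at sigma_min: %s deg)\n", x$cav1$label,
              paste(sprintf("%.1f", x$cav1$psi_min_sigma), collapse = ", ")))
  cat(sprintf("  ptrf: %s\n", x$ptrf$label))
  cat(sprintf("  cav1 releases more area at low tension: %s\n",
              x$comparison$cav1_releases_more_low))
  cat(sprintf("  ptrf releases more area at high tension: %s\n",
              x$comparison$ptrf_releases_more_high))
  cat(sprintf("  ptrf coverage dependence high/low: %.3f / %.3f\n",
              x$comparison$ptrf_cov_dep_high, x$comparison$ptrf_cov_dep_low))
  invisible(x)
}
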