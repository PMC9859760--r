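# Quasi-static two-state model of one coated domain: an assembled curved
# domain of fixed coat area A_d competes with fully dispersed coat proteins.
# Bistability is encoded as two branches separated by a finite barrier
# Delta F_b; the high-curvature coat then snaps, the low-curvature coat
# unfolds continuously.

#' Single-domain scenario
#'
#' @param coat a [coat_params()] object.
#' @param A_d fixed coat area (nm^2), within [1e3, 1e6].
#' @param phi0 background dispersed protein area fraction, in (0, 1).
#'   Bookkeeping only; the energy balance is per fixed protein number
#'   `N_p = A_d / a_p`.
#' @param protocol a [tension_protocol()]; defaults to a cycle of 80
#'   log-spaced points in [1e-4, 0.05] kBT nm^-2, bracketing both presets'
#'   transitions.
#' @return Object of class `domain_scenario`.
#' @export
domain_scenario <- function(coat, A_d = NULL, phi0 = 0.01,
                            protocol = NULL) {
  stopifnot(inherits(coat, "coat_params"))
  if (is.null(A_d)) {
    # defaults: full-bud area for the high-curvature coat, doline scale
    # (several-hundred-nm projected diameter) for the low-curvature coat
    A_d <- if (coat$name == "ptrf") 4 * pi / coat$c0^2 else 2e5
  }
  if (A_d < 1e3 || A_d > 1e6) stop("A_d must lie in [1e3, 1e6] nm^2")
  if (phi0 <= 0 || phi0 >= 1) stop("phi0 must lie in (0, 1)")
  if (is.null(protocol))
    protocol <- default_protocol(n = 80, sigma_min = 1e-4, sigma_max = 0.05)
  stopifnot(inherits(protocol, "tension_protocol"))
  structure(list(coat = coat, A_d = A_d, phi0 = phi0, protocol = protocol),
            class = "domain_scenario")
}

#' Assembly free energy of one domain
#'
#' Free-energy difference between the assembled curved domain (at its
#' optimal cap depth `u*`) and the same `N_p = A_d / a_p` proteins
#' dispersed flat on the membrane:
#' `Delta(sigma) = E_mech(u*; sigma) + N_p delta - N_p e_f`, where
#' `e_f = 2 kappa_c a_p c0^2` is the per-protein frustration energy of a
#' flat, curvature-frustrated coat protein. `Delta < 0` means the
#' assembled domain is the equilibrium state.
#'
#' @param scenario a [domain_scenario()].
#' @param sigma membrane tension (kBT nm^-2); may be a vector.
#' @return list with vectors `Delta` (kBT) and `u_star`.
#' @export
assembly_free_energy <- function(scenario, sigma) {
  stopifnot(inherits(scenario, "domain_scenario"))
  coat <- scenario$coat
  if (coat$lambda_rim != 0) {
    # numeric path: optimize the full energy including the rim term
    res <- vapply(sigma, function(s) {
      opt <- stats::optimize(function(u)
        mech_energy(cap_from(scenario$A_d, u), coat, s),
        interval = c(0, 2), tol = 1e-10)
      # guard the boundaries, optimize() never samples them exactly
      cand_u <- c(opt$minimum, 0, 2)
      cand_E <- c(opt$objective,
                  mech_energy(cap_from(scenario$A_d, 0), coat, s),
                  mech_energy(cap_from(scenario$A_d, 2), coat, s))
      i <- which.min(cand_E)
      c(cand_u[i], cand_E[i])
    }, numeric(2))
    u_star <- res[1, ]; E_star <- res[2, ]
  } else {
    cf <- lapply(sigma, function(s)
      optimal_angle_closed_form(scenario$A_d, coat, s))
    u_star <- vapply(cf, `[[`, numeric(1), "u_star")
    E_star <- vapply(cf, `[[`, numeric(1), "E_star")
  }
  N_p <- scenario$A_d / coat$a_p
  e_f <- 2 * coat$kappa_c * coat$a_p * coat$c0^2
  list(Delta = E_star + N_p * (coat$delta_assembly - e_f), u_star = u_star)
}

#' Equilibrium transition tension (closed form, lambda_rim = 0)
#'
#' Solves `Delta(sigma*) = 0`: writing `X = sigma A_d / 2` and
#' `M = N_p (e_f - delta)`, the interior-optimum balance
#' `2 kappa_c A_d c0^2 X / (4 pi kappa_c + X) = M` gives
#' `X = 4 pi kappa_c M / (2 kappa_c A_d c0^2 - M)`.
#'
#' @param scenario a [domain_scenario()] whose coat has `lambda_rim = 0`
#'   (the rim-free balance; used as the analytic oracle).
#' @return sigma* in kBT nm^-2.
#' @export
transition_tension <- function(scenario) {
  coat <- scenario$coat
  if (coat$lambda_rim != 0) stop("closed form requires lambda_rim = 0")
  N_p <- scenario$A_d / coat$a_p
  e_f <- 2 * coat$kappa_c * coat$a_p * coat$c0^2
  M <- N_p * (e_f - coat$delta_assembly)
  cap <- 2 * coat$kappa_c * scenario$A_d * coat$c0^2
  if (M <= 0) stop("domain never assembles (delta >= e_f): no transition")
  if (M >= cap) stop("assembly drive exceeds the saturating bending gain")
  X <- 4 * pi * coat$kappa_c * M / (cap - M)
  2 * X / scenario$A_d
}

# first grid index on a leg where `cond` holds, refined by bisection on the
# continuous Delta(sigma) between the bracketing grid points
.refine_transition <- function(scenario, s_lo, s_hi, threshold, tol = 1e-6) {
  f <- function(s) assembly_free_energy(scenario, s)$Delta - threshold
  stats::uniroot(f, lower = min(s_lo, s_hi), upper = max(s_lo, s_hi),
                 tol = tol)$root
}

#' Quasi-static tension sweep of one domain
#'
#' Branch-switching rule: on the up leg the assembled branch persists
#' while `Delta(sigma) < +barrier` and switches to dispersed (u jumps to
#' 0) at the first grid point violating this; on the down leg the
#' dispersed branch persists while `Delta(sigma) > -barrier`. Transitions
#' are refined by bisection between the bracketing grid points
#' (tolerance 1e-6 in sigma). With `barrier > 0` the up transition occurs
#' at higher tension than the down transition (hysteresis).
#'
#' @param scenario a [domain_scenario()].
#' @return Object of class `sweep_trace`: a data.frame `trace` with
#'   columns (leg, sigma, branch, u, psi_deg, D_proj_nm, E), plus events
#'   `sigma_up_transition`, `sigma_down_transition`, `u_jump_up`,
#'   `u_jump_down`, `loop_area`.
#' @export
sweep_single <- function(scenario) {
  stopifnot(inherits(scenario, "domain_scenario"))
  coat <- scenario$coat
  legs <- scenario$protocol$legs
  B <- coat$barrier
  N_p <- scenario$A_d / coat$a_p
  e_f <- 2 * coat$kappa_c * coat$a_p * coat$c0^2
  disp_E <- 0  # energies reported relative to the dispersed state

  state_row <- function(leg, s, branch) {
    afe <- assembly_free_energy(scenario, s)
    if (branch == "assembled") {
      u <- afe$u_star
      E <- afe$Delta
    } else {
      u <- 0
      E <- disp_E
    }
    data.frame(leg = leg, sigma = s, branch = branch, u = u,
               psi_deg = acos(1 - u) * 180 / pi,
               D_proj_nm = cap_from(scenario$A_d, u)$D_proj,
               E = E)
  }

  events <- list(sigma_up_transition = NA_real_,
                 sigma_down_transition = NA_real_,
                 u_jump_up = NA_real_, u_jump_down = NA_real_)
  rows <- list()

  for (leg_name in names(legs)) {
    grid <- legs[[leg_name]]
    Delta <- assembly_free_energy(scenario, grid)$Delta
    if (leg_name == "up") {
      branch <- "assembled"
      if (Delta[1] >= B)
        stop("up leg starts beyond the disassembly threshold; ",
             "protocol does not bracket the transition")
      for (i in seq_along(grid)) {
        if (branch == "assembled" && Delta[i] >= B) {
          s_t <- .refine_transition(scenario, grid[i - 1], grid[i], B)
          u_at <- assembly_free_energy(scenario, s_t)$u_star
          events$sigma_up_transition <- s_t
          events$u_jump_up <- u_at  # u drops from u*(s_t) to 0
          branch <- "dispersed"
        }
        rows[[length(rows) + 1L]] <- state_row(leg_name, grid[i], branch)
      }
      if (branch == "assembled")
        stop("protocol never crosses the disassembly threshold")
    } else {
      branch <- if (Delta[1] <= -B) "assembled" else "dispersed"
      started_dispersed <- branch == "dispersed"
      for (i in seq_along(grid)) {
        if (branch == "dispersed" && Delta[i] <= -B) {
          s_t <- .refine_transition(scenario, grid[i - 1], grid[i], -B)
          u_at <- assembly_free_energy(scenario, s_t)$u_star
          events$sigma_down_transition <- s_t
          events$u_jump_down <- u_at  # u jumps from 0 to u*(s_t)
          branch <- "assembled"
        }
        rows[[length(rows) + 1L]] <- state_row(leg_name, grid[i], branch)
      }
      if (started_dispersed && branch == "dispersed")
        stop("protocol never crosses the reassembly threshold")
    }
  }

  trace <- do.call(rbind, rows)

  # hysteresis loop area: integral of |u_up - u_down| over sigma
  loop_area <- 0
  if (all(c("up", "down") %in% trace$leg)) {
    up <- trace[trace$leg == "up", ]
    dn <- trace[trace$leg == "down", ]
    dn <- dn[order(dn$sigma), ]
    gap <- abs(up$u - dn$u[match(round(up$sigma, 12), round(dn$sigma, 12))])
    ok <- !is.na(gap)
    if (sum(ok) >= 2)
      loop_area <- sum(diff(up$sigma[ok]) *
                         (gap[ok][-1] + gap[ok][-sum(ok)]) / 2)
  }

  structure(c(list(trace = trace, scenario = scenario,
                   loop_area = loop_area), events),
            class = "sweep_trace")
}

#' Classify a single-domain tension response
#'
#' `snapping` if the up-leg disassembly jump in u is at least
#' `snap_threshold`; `continuous` if every discontinuity in u along either
#' leg is below `smooth_threshold`; otherwise `mixed`.
#'
#' @param trace a [sweep_single()] result.
#' @param snap_threshold,smooth_threshold jump sizes in u.
#' @return `"snapping"`, `"continuous"` or `"mixed"`.
#' @export
classify_response <- function(trace, snap_threshold = 1.0,
                              smooth_threshold = 0.3) {
  stopifnot(inherits(trace, "sweep_trace"))
  jumps <- c(trace$u_jump_up, trace$u_jump_down)
  for (lg in unique(trace$trace$leg)) {
    u <- trace$trace$u[trace$trace$leg == lg]
    jumps <- c(jumps, abs(diff(u)))
  }
  jumps <- jumps[!is.na(jumps)]
  if (!is.na(trace$u_jump_up) && trace$u_jump_up >= snap_threshold)
    return("snapping")
  if (all(jumps < smooth_threshold)) return("continuous")
  "mixed"
}

#' @export
print.sweep_trace <- function(x, ...) {
  cat(sprintf("<sweep_trace '%s'>  %d states, barrier=%g kBT\n",
              x$scenario$coat$name, nrow(x$trace), x$scenario$coat$barrier))
  cat(sprintf("  up transition at sigma=%.4g, u-jump %.3f\n",
              x$sigma_up_transition, x$u_jump_up))
  cat(sprintf("  down transition at sigma=%.4g, u-jump %.3f\n",
              x$sigma_down_transition, x$u_jump_down))
  cat(sprintf("  hysteresis loop area %.4g\n", x$loop_area))
  invisible(x)
}
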