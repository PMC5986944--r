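## Closed-loop lumped-parameter circulation: two reduced-order mechanical
## ventricles plus three linear compliance compartments (systemic arteries,
## systemic veins, pulmonary circuit) exchanging volume through five
## unidirectional resistive connections. The cardiac cycle alternates a
## 480 ms active phase (ventricular inflow gated shut) and a 300 ms passive
## filling phase, giving a 780 ms period (77 bpm). Explicit Euler
## integration with pairwise volume transfers conserves total volume to
## round-off.

#' Circulation parameters
#'
#' Compliances (ml/mmHg), resistances (mmHg ms/ml), phase durations (ms)
#' and reference (zero-pressure) compartment volumes (ml) of the closed
#' loop. The default kappa/R values are package defaults sized to give
#' physiological pig pressures (arterial ~70-100 mmHg, venous ~3-6 mmHg)
#' at the normal-profile stroke volume; all are overridable and can be
#' serialized to JSON.
#'
#' @param kappa_sa,kappa_sv,kappa_p compliances of systemic arteries,
#'   systemic veins and pulmonary circuit, ml/mmHg.
#' @param R_M,R_A,R_SYS,R_T,R_P resistances: mitral inflow, aortic valve,
#'   systemic vasculature, tricuspid inflow, pulmonary valve (mmHg ms/ml).
#' @param T_active,T_fill active-contraction and passive-filling durations,
#'   ms; their sum is the cycle period.
#' @param dt integrator step, ms.
#' @param V0_sa,V0_sv,V0_p compartment volumes at zero pressure, ml.
#' @param P_sa,P_sv,P_p initial (end-diastolic) compartment pressures, mmHg.
#' @return object of class `circulation_params`.
#' @export
circulation_params <- function(kappa_sa = 1.0, kappa_sv = 40, kappa_p = 8,
                               R_M = 40, R_A = 50, R_SYS = 2100, R_T = 40,
                               R_P = 100, T_active = 480, T_fill = 300,
                               dt = 1, V0_sa = 300, V0_sv = 1500, V0_p = 300,
                               P_sa = 78, P_sv = 5, P_p = 7.5) {
  if (any(c(kappa_sa, kappa_sv, kappa_p, R_M, R_A, R_SYS, R_T, R_P) <= 0))
    stop("all compliances and resistances must be positive")
  if (T_active <= 0 || T_fill <= 0 || dt <= 0)
    stop("phase durations and dt must be positive")
  structure(list(kappa_sa = kappa_sa, kappa_sv = kappa_sv, kappa_p = kappa_p,
                 R_M = R_M, R_A = R_A, R_SYS = R_SYS, R_T = R_T, R_P = R_P,
                 T_active = T_active, T_fill = T_fill, period = T_active + T_fill,
                 dt = dt, V0_sa = V0_sa, V0_sv = V0_sv, V0_p = V0_p,
                 P_sa = P_sa, P_sv = P_sv, P_p = P_p),
            class = "circulation_params")
}

#' @export
print.circulation_params <- function(x, ...) {
  cat("Closed-loop circulation parameters\n")
  cat(sprintf("  kappa (ml/mmHg): SA %g, SV %g, P %g\n",
              x$kappa_sa, x$kappa_sv, x$kappa_p))
  cat(sprintf("  R (mmHg ms/ml): M %g, A %g, SYS %g, T %g, P %g\n",
              x$R_M, x$R_A, x$R_SYS, x$R_T, x$R_P))
  cat(sprintf("  phases: %g ms active + %g ms filling = %g ms (%d bpm), dt %g ms\n",
              x$T_active, x$T_fill, x$period, round(60000 / x$period), x$dt))
  invisible(x)
}

#' Pressure of a linear compliance compartment
#'
#' `P = (V - V0) / kappa`.
#'
#' @param V compartment volume, ml.
#' @param V0 reference (zero-pressure) volume, ml.
#' @param kappa compliance, ml/mmHg (> 0).
#' @return pressure, mmHg.
#' @export
compartment_pressure <- function(V, V0, kappa) {
  if (any(kappa <= 0)) stop("compliance must be positive")
  (V - V0) / kappa
}

#' Unidirectional resistive valve flow
#'
#' Ohmic flow `Q = max(P_up - P_down, 0) / R` through an open valve, zero
#' through a closed one; never negative (all exchanges in the circuit are
#' unidirectional).
#'
#' @param P_up,P_down upstream/downstream pressures, mmHg.
#' @param R resistance, mmHg ms/ml (> 0).
#' @param gate `"open"` or `"closed"`.
#' @return flow, ml/ms.
#' @export
valve_flow <- function(P_up, P_down, R, gate = "open") {
  if (R <= 0) stop("resistance must be positive")
  if (!gate %in% c("open", "closed")) stop("gate must be 'open' or 'closed'")
  if (gate == "closed") return(0)
  max(P_up - P_down, 0) / R
}

#' Bundle a coupled heart model
#'
#' Combines LV and RV geometries, the (shared) passive material, the active
#' tension law and the circulation parameters into one object consumed by
#' [run_cycles()] and the calibration stages. The RV uses the same material
#' properties as the LV.
#'
#' @param lv,rv [ventricle_geometry()] objects.
#' @param material a [passive_params()].
#' @param active an [active_params()].
#' @param circ a [circulation_params()].
#' @return object of class `heart_model`.
#' @export
heart_model <- function(lv = preset_geometry("normal", "lv"),
                        rv = preset_geometry("normal", "rv"),
                        material = passive_params(),
                        active = active_params(),
                        circ = circulation_params()) {
  structure(list(lv = lv, rv = rv, material = material, active = active,
                 circ = circ),
            class = "heart_model")
}

#' @export
print.heart_model <- function(x, ...) {
  cat("Coupled biventricular heart model\n")
  cat(sprintf("  LV V0 = %.1f ml, RV V0 = %.1f ml, Tmax = %g kPa, n_s = %g\n",
              x$lv$V0, x$rv$V0, x$active$Tmax, x$active$n_s))
  cat(sprintf("  cycle %g ms (%d bpm)\n", x$circ$period,
              round(60000 / x$circ$period)))
  invisible(x)
}

## find the cavity volume at which the passive ventricle reaches pressure P
volume_at_pressure <- function(geom, material, P_target, V_hint = NULL) {
  if (P_target <= 0) return(geom$V0)
  lam <- 1
  f <- function(V) equilibrium_pressure(geom, V, material, lamL_init = lam)$P -
    P_target
  lo <- geom$V0 * 1.001; hi <- V_hint %||% (geom$V0 * 1.5)
  while (f(hi) < 0 && hi < geom$V0 * 20) hi <- hi * 1.3
  stats::uniroot(f, c(lo, hi), tol = 1e-4 * geom$V0)$root
}

#' Initial (end-diastolic) circulation state
#'
#' Loads each compliance compartment to its configured end-diastolic
#' pressure (inverting the linear compliance relation) and the ventricles
#' to the volumes at which their passive pressure equals the given
#' end-diastolic pressures.
#'
#' @param model a [heart_model()].
#' @param lv_edp,rv_edp ventricular end-diastolic pressures, mmHg.
#' @param lv_edv optional explicit LV end-diastolic volume (ml), overriding
#'   the pressure inversion.
#' @return named list state: volumes (ml), long-axis warm starts, time.
#' @export
initial_state <- function(model, lv_edp = 10, rv_edp = 4, lv_edv = NULL) {
  cp <- model$circ
  V_lv <- lv_edv %||% volume_at_pressure(model$lv, model$material, lv_edp)
  V_rv <- volume_at_pressure(model$rv, model$material, rv_edp)
  list(V_lv = V_lv, V_rv = V_rv,
       V_sa = cp$V0_sa + cp$kappa_sa * cp$P_sa,
       V_sv = cp$V0_sv + cp$kappa_sv * cp$P_sv,
       V_p = cp$V0_p + cp$kappa_p * cp$P_p,
       lamL_lv = 1, lamL_rv = 1, t = 0)
}

## one explicit-Euler step; returns updated state + instantaneous record
step_circulation <- function(state, model, dt, t_cycle) {
  cp <- model$circ
  active_phase <- t_cycle < cp$T_active
  ## outside the twitch window every point has zero tension: skip the
  ## length-dependent tension evaluation entirely
  ap <- model$active
  act <- if ((t_cycle %% ap$period) <
             ap$t0 + ap$m_slope * 2.8 + ap$b_intercept) ap else NULL
  eq_lv <- equilibrium_pressure(model$lv, state$V_lv, model$material,
                                active = act, t = t_cycle,
                                lamL_init = state$lamL_lv,
                                slope_init = state$slope_lv %||% NULL)
  eq_rv <- equilibrium_pressure(model$rv, state$V_rv, model$material,
                                active = act, t = t_cycle,
                                lamL_init = state$lamL_rv,
                                slope_init = state$slope_rv %||% NULL)
  P_sa <- compartment_pressure(state$V_sa, cp$V0_sa, cp$kappa_sa)
  P_sv <- compartment_pressure(state$V_sv, cp$V0_sv, cp$kappa_sv)
  P_p <- compartment_pressure(state$V_p, cp$V0_p, cp$kappa_p)

  gate_in <- if (active_phase) "closed" else "open"
  Q_M <- valve_flow(P_p, eq_lv$P, cp$R_M, gate_in)     # pulmonary -> LV
  Q_A <- valve_flow(eq_lv$P, P_sa, cp$R_A, "open")     # LV -> SA
  Q_S <- valve_flow(P_sa, P_sv, cp$R_SYS, "open")      # SA -> SV
  Q_T <- valve_flow(P_sv, eq_rv$P, cp$R_T, gate_in)    # SV -> RV
  Q_P <- valve_flow(eq_rv$P, P_p, cp$R_P, "open")      # RV -> pulmonary

  ## pairwise transfers: total volume conserved exactly
  new <- state
  new$V_lv <- state$V_lv + dt * (Q_M - Q_A)
  new$V_sa <- state$V_sa + dt * (Q_A - Q_S)
  new$V_sv <- state$V_sv + dt * (Q_S - Q_T)
  new$V_rv <- state$V_rv + dt * (Q_T - Q_P)
  new$V_p <- state$V_p + dt * (Q_P - Q_M)
  if (new$V_lv <= 0 || new$V_rv <= 0 || new$V_sa <= 0 || new$V_sv <= 0 ||
      new$V_p <= 0)
    stop("negative compartment volume: unphysical circulation parameters")
  new$lamL_lv <- eq_lv$lamL
  new$lamL_rv <- eq_rv$lamL
  new$slope_lv <- eq_lv$slope
  new$slope_rv <- eq_rv$slope
  list(state = new,
       record = c(P_lv = eq_lv$P, P_rv = eq_rv$P, P_sa = P_sa, P_sv = P_sv,
                  P_p = P_p, Q_M = Q_M, Q_A = Q_A, Q_S = Q_S, Q_T = Q_T,
                  Q_P = Q_P, long_axis_lv = eq_lv$long_axis,
                  lamL_lv = eq_lv$lamL))
}

#' Run consecutive cardiac cycles of the coupled model
#'
#' Alternates the active-contraction phase (ventricular inflow gated shut)
#' and the passive-filling phase, integrating the five unidirectional flows
#' with explicit Euler, and reports per-cycle end-diastolic/end-systolic
#' volumes, stroke volume, ejection fraction, long-axis shortening and a
#' limit-cycle convergence metric (relative change in stroke volume between
#' consecutive cycles).
#'
#' @param model a [heart_model()].
#' @param n_cycles number of cardiac cycles (default 6).
#' @param init initial state from [initial_state()]; defaults to the
#'   normal-profile end-diastolic loading.
#' @param keep_trace record the full time series (default TRUE).
#' @return object of class `heart_run`: list with `summary` (per-cycle
#'   data.frame), `trace` (time series data.frame), `state` (final),
#'   `model`, `total_volume_drift` (ml).
#' @export
run_cycles <- function(model, n_cycles = 6, init = NULL, keep_trace = TRUE) {
  cp <- model$circ
  state <- init %||% initial_state(model)
  tot0 <- state$V_lv + state$V_rv + state$V_sa + state$V_sv + state$V_p
  steps <- round(cp$period / cp$dt)
  trace <- if (keep_trace)
    vector("list", n_cycles * steps) else NULL
  summ <- NULL
  prev_sv <- NA_real_
  k <- 0L
  for (cyc in seq_len(n_cycles)) {
    edv <- state$V_lv; edv_rv <- state$V_rv
    esv <- Inf; esv_rv <- Inf
    la_hist <- numeric(steps)
    v_hist <- numeric(steps)
    for (i in seq_len(steps)) {
      t_cycle <- (i - 1) * cp$dt
      stp <- step_circulation(state, model, cp$dt, t_cycle)
      state <- stp$state
      esv <- min(esv, state$V_lv); esv_rv <- min(esv_rv, state$V_rv)
      la_hist[i] <- stp$record[["long_axis_lv"]]
      v_hist[i] <- state$V_lv
      if (keep_trace) {
        k <- k + 1L
        trace[[k]] <- c(cycle = cyc, t_ms = (cyc - 1) * cp$period + t_cycle,
                        V_lv = state$V_lv, V_rv = state$V_rv, stp$record,
                        V_sa = state$V_sa, V_sv = state$V_sv, V_p = state$V_p)
      }
    }
    sv <- edv - esv
    summ <- rbind(summ, data.frame(
      cycle = cyc, EDV = edv, ESV = esv, SV = sv, EF = sv / edv,
      EDV_rv = edv_rv, ESV_rv = esv_rv, SV_rv = edv_rv - esv_rv,
      LVLS = lvls(c(la_hist[1], la_hist[which.min(v_hist)])),
      dSV_rel = if (is.na(prev_sv)) NA_real_ else abs(sv - prev_sv) / prev_sv))
    prev_sv <- sv
  }
  tot1 <- state$V_lv + state$V_rv + state$V_sa + state$V_sv + state$V_p
  structure(list(summary = summ,
                 trace = if (keep_trace) as.data.frame(do.call(rbind, trace)),
                 state = state, model = model,
                 total_volume_drift = abs(tot1 - tot0)),
            class = "heart_run")
}

#' @export
print.heart_run <- function(x, ...) {
  cat(sprintf("Closed-loop run: %d cycles at %d bpm\n",
              nrow(x$summary), round(60000 / x$model$circ$period)))
  print(x$summary, digits = 4, row.names = FALSE)
  cat(sprintf("total-volume drift: %.3g ml\n", x$total_volume_drift))
  invisible(x)
}

#' @export
summary.heart_run <- function(object, ...) {
  last <- object$summary[nrow(object$summary), ]
  out <- list(cycles = nrow(object$summary), EDV = last$EDV, ESV = last$ESV,
              SV = last$SV, EF = last$EF, LVLS = last$LVLS,
              converged_dSV = last$dSV_rel,
              volume_drift = object$total_volume_drift)
  class(out) <- "summary.heart_run"
  out
}

#' @export
print.summary.heart_run <- function(x, ...) {
  cat(sprintf(paste0("Converged cycle: EDV %.1f ml, ESV %.1f ml, SV %.1f ml, ",
                     "EF %.1f%%, LVLS %.1f%%\n"),
              x$EDV, x$ESV, x$SV, 100 * x$EF, x$LVLS))
  cat(sprintf("cycle-to-cycle |dSV|/SV: %.3g; volume drift %.3g ml\n",
              x$converged_dSV, x$volume_drift))
  invisible(x)
}

#' Pressure-volume loop plot
#'
#' Plots the LV (and optionally RV) PV loops of a [run_cycles()] result,
#' base graphics.
#'
#' @param x a `heart_run`.
#' @param rv include the RV loop (dashed).
#' @param ... passed to [graphics::plot()].
#' @export
plot.heart_run <- function(x, rv = TRUE, ...) {
  tr <- x$trace
  if (is.null(tr)) stop("run was recorded without a trace")
  graphics::plot(tr$V_lv, tr$P_lv, type = "l",
                 xlab = "Cavity volume (ml)", ylab = "Pressure (mmHg)",
                 xlim = range(c(tr$V_lv, if (rv) tr$V_rv)), ...)
  if (rv) graphics::lines(tr$V_rv, tr$P_rv, lty = 2)
  last <- tr[tr$cycle == max(tr$cycle), ]
  graphics::lines(last$V_lv, last$P_lv, lwd = 2)
  invisible(x)
}

#' Locate the four labeled PV-loop corners of a cycle
#'
#' End diastole (cycle start), start of ejection (aortic flow onset), end
#' systole (aortic flow offset) and end of relaxation (end of the active
#' phase), returned in time order with volumes and pressures.
#'
#' @param run a `heart_run` with a trace.
#' @param cycle which cycle to analyze (default: last).
#' @return data.frame with `corner`, `t_ms`, `V`, `P`.
#' @export
pv_corners <- function(run, cycle = max(run$trace$cycle)) {
  tr <- run$trace[run$trace$cycle == cycle, ]
  ej <- which(tr$Q_A > 0)
  if (length(ej) == 0) stop("no ejection detected in cycle ", cycle)
  Tact <- run$model$circ$T_active
  t_rel <- tr$t_ms - min(tr$t_ms)
  idx <- c(ed = 1L, se = ej[1], es = ej[length(ej)],
           er = max(which(t_rel < Tact)))
  data.frame(corner = c("end_diastole", "start_ejection", "end_systole",
                        "end_relaxation"),
             t_ms = t_rel[idx], V = tr$V_lv[idx], P = tr$P_lv[idx])
}
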