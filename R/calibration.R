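## Three-stage material calibration: (1) bounded nonlinear least squares of
## the eight passive parameters against six-mode simple-shear data; (2)
## scaling of the a-type (A) and b-type (B) coefficients so the passive
## inflation curve matches a Klotz-type single-beat end-diastolic
## pressure-volume relation; (3) active parameters (Tmax, n_s) against
## stroke-volume and long-axis-shortening targets using the first simulated
## beat as the forward model.

#' Six-mode shear dataset
#'
#' Container for tri-axial simple-shear data: per mode, strictly increasing
#' shear amounts and measured shear stresses.
#'
#' @param data data.frame with columns `mode` (fs, fn, sf, sn, nf, ns),
#'   `gamma`, `stress_kpa`.
#' @return object of class `shear_dataset` (a validated data.frame).
#' @export
shear_dataset <- function(data) {
  stopifnot(all(c("mode", "gamma", "stress_kpa") %in% names(data)))
  data$mode <- as.character(data$mode)
  if (!setequal(unique(data$mode), SHEAR_MODES))
    stop("all six shear modes must be present: ",
         paste(SHEAR_MODES, collapse = ", "))
  for (m in SHEAR_MODES) {
    g <- data$gamma[data$mode == m]
    if (is.unsorted(g, strictly = TRUE))
      stop("gamma must be strictly increasing within mode ", m)
  }
  class(data) <- c("shear_dataset", "data.frame")
  data
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` between model predictions and data.
#'
#' @param model,data numeric vectors of equal length (>= 2).
#' @return R-squared.
#' @export
goodness_of_fit <- function(model, data) {
  if (length(model) != length(data) || length(data) < 2)
    stop("model and data must have equal length >= 2")
  ss_tot <- sum((data - mean(data))^2)
  if (ss_tot == 0) stop("zero variance in data: R^2 undefined")
  1 - sum((model - data)^2) / ss_tot
}

## shared result container
new_fit <- function(par, objective, initial_objective, iterations, converged,
                    r_squared = NA_real_, stage, extra = list()) {
  structure(c(list(par = par, objective = objective,
                   initial_objective = initial_objective,
                   iterations = iterations, converged = converged,
                   r_squared = r_squared, stage = stage), extra),
            class = c(paste0(stage, "_fit"), "cardio_fit"))
}

#' @export
print.cardio_fit <- function(x, ...) {
  cat(sprintf("%s calibration (%s)\n", x$stage,
              if (x$converged) "converged" else "NOT converged"))
  print(signif(x$par, 6))
  cat(sprintf("objective %.4g -> %.4g in %d iterations",
              x$initial_objective, x$objective, x$iterations))
  if (is.finite(x$r_squared)) cat(sprintf(", R^2 = %.4f", x$r_squared))
  cat("\n")
  invisible(x)
}

#' @export
coef.cardio_fit <- function(object, ...) object$par

#' @export
summary.cardio_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

## bounded Levenberg-Marquardt least squares on residual function;
## failures are reported, not raised
run_nls <- function(resid_fun, init, lower, upper, maxit = 200) {
  r0 <- resid_fun(init)
  out <- try(minpack.lm::nls.lm(
    par = init, fn = resid_fun, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = maxit, ftol = 1e-10)),
    silent = TRUE)
  if (inherits(out, "try-error"))
    return(list(par = init, obj = sum(r0^2), obj0 = sum(r0^2), it = 0L,
                ok = FALSE, msg = as.character(out)))
  list(par = out$par, obj = out$deviance, obj0 = sum(r0^2),
       it = out$niter, ok = out$info %in% 1:4, msg = out$message)
}

#' Fit the eight passive parameters to six-mode shear data
#'
#' Minimizes the summed squared differences between model and measured
#' shear stresses over all six modes and all shear amounts, by bounded
#' nonlinear least squares (Levenberg-Marquardt with box constraints) over
#' `(a, b, a_f, b_f, a_s, b_s, a_fs, b_fs)`. The forward model is
#' [simple_shear_curve()] with healthy tissue.
#'
#' @param data a [shear_dataset()] (or compatible data.frame).
#' @param init named initial vector (defaults to the packaged parameter
#'   set); order `a, b, a_f, b_f, a_s, b_s, a_fs, b_fs`.
#' @param lower,upper box bounds (positive).
#' @param template a [passive_params()] supplying the fixed settings (D,
#'   invariant conventions).
#' @return a `cardio_fit` with fields `par`, `objective`, `r_squared`, ...
#' @export
fit_shear <- function(data, init = NULL,
                      lower = rep(1e-4, 8), upper = rep(100, 8),
                      template = passive_params()) {
  data <- shear_dataset(as.data.frame(data))
  p0 <- c(a = template$a, b = template$b, a_f = template$a_f,
          b_f = template$b_f, a_s = template$a_s, b_s = template$b_s,
          a_fs = template$a_fs, b_fs = template$b_fs)
  init <- init %||% p0
  if (any(init < lower) || any(init > upper))
    stop("initial values must lie within the bounds")
  modes <- split(seq_len(nrow(data)), data$mode)
  make_params <- function(v)
    passive_params(a = v[1], b = v[2], a_f = v[3], b_f = v[4], a_s = v[5],
                   b_s = v[6], a_fs = v[7], b_fs = v[8], D = template$D,
                   isochoric_split = template$isochoric_split,
                   tension_only = template$tension_only)
  resid_fun <- function(v) {
    pp <- make_params(v)
    unlist(lapply(names(modes), function(m) {
      i <- modes[[m]]
      simple_shear_curve(m, data$gamma[i], pp) - data$stress_kpa[i]
    }), use.names = FALSE)
  }
  res <- run_nls(resid_fun, init, lower, upper)
  pred <- resid_fun(res$par) + data$stress_kpa[unlist(modes, use.names = FALSE)]
  r2 <- goodness_of_fit(pred, data$stress_kpa[unlist(modes, use.names = FALSE)])
  new_fit(stats::setNames(res$par, names(p0)), res$obj, res$obj0, res$it,
          res$ok, r2, stage = "shear",
          extra = list(params = make_params(res$par), message = res$msg))
}

#' Klotz-type single-beat end-diastolic pressure-volume relation
#'
#' Analytic EDPVR through one measured (EDV, EDP) anchor using the
#' normalized-volume power law `P = An * Vn^Bn`, where
#' `Vn = (V - V0) / (V30 - V0)` and `V30` (the volume at 30 mmHg) is placed
#' so the curve passes through the anchor exactly. The empirical constants
#' default to `An = 28.2`, `Bn = 2.79` (the human normalized EDPVR) and sit
#' in one overridable config block.
#'
#' @param EDV end-diastolic volume, ml.
#' @param EDP end-diastolic pressure, mmHg (warning outside (0, 50]).
#' @param V0 unloaded volume, ml (< EDV).
#' @param N number of sample points spanning `[V0, EDV]`.
#' @param constants list with `An`, `Bn`.
#' @return object of class `klotz_target`: data.frame `(V, P)` with
#'   attributes `EDV`, `EDP`, `V0`, `constants`.
#' @export
klotz_edpvr <- function(EDV, EDP, V0, N = 25,
                        constants = list(An = 28.2, Bn = 2.79)) {
  if (EDP <= 0) stop("EDP must be positive")
  if (EDP > 50) warning("EDP = ", EDP,
                        " mmHg is outside the validated range (0, 50]")
  if (V0 >= EDV) stop("V0 must be smaller than EDV")
  V <- seq(V0, EDV, length.out = N)
  ## V30 chosen so that P(EDV) = EDP exactly
  Vn_edv <- (EDP / constants$An)^(1 / constants$Bn)
  V30 <- V0 + (EDV - V0) / Vn_edv
  Vn <- (V - V0) / (V30 - V0)
  P <- constants$An * Vn^constants$Bn
  out <- data.frame(V = V, P = P)
  attr(out, "EDV") <- EDV; attr(out, "EDP") <- EDP; attr(out, "V0") <- V0
  attr(out, "V30") <- V30; attr(out, "constants") <- constants
  class(out) <- c("klotz_target", "data.frame")
  out
}

#' Fit the passive scaling multipliers (A, B) to a Klotz target
#'
#' Minimizes the squared pressure differences along the passive inflation
#' curve plus a squared end-diastolic-volume term, over the scalar
#' multiplier `A` (a-type terms) and exponential multiplier `B` (b-type
#' terms). Trans-septal loading from simultaneous RV pressurization enters
#' as a ramped additive offset `ts_weight * rv_edp * (V - V0)/(EDV - V0)`
#' on the model pressure (the reduced geometry has no shared septum; this
#' is a documented approximation).
#'
#' @param geom LV [ventricle_geometry()] built with unscaled parameters.
#' @param klotz a [klotz_edpvr()] target.
#' @param material base [passive_params()] (its `A`, `B` are replaced).
#' @param rv_edp RV end-diastolic pressure, mmHg.
#' @param ts_weight trans-septal coupling fraction.
#' @param init,lower,upper optimizer start and box bounds for `c(A, B)`.
#' @return a `cardio_fit`; `par` holds `A`, `B`, extras hold the achieved
#'   EDV and the calibrated `passive_params`.
#' @export
fit_passive_scaling <- function(geom, klotz, material = passive_params(),
                                rv_edp = 4, ts_weight = 0.1,
                                init = c(A = 1, B = 1),
                                lower = c(0.001, 0.05), upper = c(50, 3)) {
  V0 <- attr(klotz, "V0")
  EDV <- attr(klotz, "EDV")
  if (abs(V0 - geom$V0) > 1e-6 * geom$V0)
    stop("Klotz target V0 must match the geometry's unloaded volume")
  edp <- attr(klotz, "EDP")
  ramp <- (klotz$V - V0) / (EDV - V0)
  offset <- ts_weight * rv_edp * ramp
  with_params <- function(v) {
    pp <- material; pp$A <- unname(v[1]); pp$B <- unname(v[2]); pp
  }
  forward <- function(v)
    passive_inflation_curve(geom, with_params(v), klotz$V)$P + offset
  ## volume at which the model (including trans-septal offset) reaches EDP
  achieved_edv <- function(v) {
    pp <- with_params(v)
    f <- function(V) equilibrium_pressure(geom, V, pp)$P +
      ts_weight * rv_edp * (V - V0) / (EDV - V0) - edp
    hi <- EDV * 1.2
    while (f(hi) < 0 && hi < EDV * 6) hi <- hi * 1.3
    stats::uniroot(f, c(V0 * 1.0001, hi), tol = 1e-4 * V0)$root
  }
  resid_fun <- function(v) {
    out <- try(c(forward(v) - klotz$P, achieved_edv(v) - EDV), silent = TRUE)
    if (inherits(out, "try-error")) return(rep(1e4, nrow(klotz) + 1))
    out
  }
  ## the objective spans many decades in (A, B) (exponential law under large
  ## inflation), so optimize in log space and pick the best of the supplied
  ## start and a coarse log-grid scan
  starts <- rbind(init,
                  as.matrix(expand.grid(
                    A = exp(seq(log(max(lower[1], 0.002)),
                                log(min(upper[1], 5)), length.out = 6)),
                    B = exp(seq(log(max(lower[2], 0.05)),
                                log(min(upper[2], 1.5)), length.out = 5)))))
  ssq <- apply(starts, 1, function(v) {
    r <- try(forward(v) - klotz$P, silent = TRUE)
    if (inherits(r, "try-error")) Inf else sum(r^2)
  })
  best <- starts[which.min(ssq), ]
  resid_log <- function(lv) resid_fun(exp(lv))
  res <- run_nls(resid_log, log(pmin(pmax(best, lower), upper)),
                 log(lower), log(upper))
  res$par <- exp(res$par)
  pp <- with_params(res$par)
  P_fit <- forward(res$par)
  r2 <- goodness_of_fit(P_fit, klotz$P)
  edv_hat <- try(achieved_edv(res$par), silent = TRUE)
  new_fit(stats::setNames(res$par, c("A", "B")), res$obj, res$obj0, res$it,
          res$ok, r2, stage = "passive",
          extra = list(params = pp,
                       achieved_EDV = if (inherits(edv_hat, "try-error"))
                         NA_real_ else edv_hat,
                       target_EDV = EDV, message = res$msg))
}

#' Fit active parameters (Tmax, n_s) to hemodynamic targets
#'
#' Minimizes `(SV - SV_target)^2 + w_lvls * (LVLS - LVLS_target)^2` over
#' the peak active tension `Tmax` and the sheet-direction fraction `n_s`
#' (constrained to \[0, 1\]), with the first simulated closed-loop beat as
#' the forward model. The long-axis-shortening term is a low-weighted
#' regularizer (default weight 0.2) that keeps the optimizer away from
#' parameter sets producing ventricular elongation.
#'
#' @param model a [heart_model()] with passive calibration already applied.
#' @param sv_target stroke volume target, ml.
#' @param lvls_target long-axis shortening target, percent (default 15).
#' @param w_lvls weight of the LVLS term.
#' @param lv_edp,rv_edp,lv_edv initial-state targets passed to
#'   [initial_state()].
#' @param init,lower,upper optimizer start and bounds for `c(Tmax, n_s)`.
#' @return a `cardio_fit`; extras hold the calibrated [heart_model()] and
#'   the achieved first-beat SV and LVLS.
#' @export
fit_active <- function(model, sv_target, lvls_target = 15, w_lvls = 0.2,
                       lv_edp = 10, rv_edp = 4, lv_edv = NULL,
                       init = c(Tmax = 80, n_s = 0.2),
                       lower = c(1, 0), upper = c(500, 1)) {
  init_st <- initial_state(model, lv_edp = lv_edp, rv_edp = rv_edp,
                           lv_edv = lv_edv)
  beat <- function(v) {
    m <- model
    m$active$Tmax <- v[1]; m$active$n_s <- v[2]
    run <- run_cycles(m, n_cycles = 1, init = init_st, keep_trace = FALSE)
    c(SV = run$summary$SV[1], LVLS = run$summary$LVLS[1])
  }
  resid_fun <- function(v) {
    out <- try(beat(v), silent = TRUE)
    if (inherits(out, "try-error")) return(c(1e3, 1e3))
    c(out[["SV"]] - sv_target,
      sqrt(w_lvls) * (out[["LVLS"]] - lvls_target))
  }
  res <- run_nls(resid_fun, init, lower, upper, maxit = 60)
  final <- beat(res$par)
  m <- model
  m$active$Tmax <- unname(res$par[1]); m$active$n_s <- unname(res$par[2])
  new_fit(stats::setNames(res$par, c("Tmax", "n_s")), res$obj, res$obj0,
          res$it, res$ok, stage = "active",
          extra = list(model = m, achieved_SV = final[["SV"]],
                       achieved_LVLS = final[["LVLS"]],
                       sv_target = sv_target, lvls_target = lvls_target,
                       initial_state = init_st, message = res$msg))
}
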