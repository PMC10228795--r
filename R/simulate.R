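#' Integrate the model to steady state
#'
#' Runs a stiff-capable adaptive implicit (backward-Euler) integration of
#' the `4 x n_compartments` coupled system from the uniform initial state
#' until `max |du/dt|` drops below `cfg$ss_tol` (converged) or the time
#' horizon `cfg$t_max` is reached (not converged).  Local step error is
#' controlled against a trapezoidal comparison step; the banded Jacobian
#' (half-bandwidth 4 from nearest-neighbour diffusion of Eiger and Upd) is
#' factorized with LAPACK's banded LU.  The run is deterministic for fixed
#' inputs.  Solver breakdown (step-size collapse, step cap) is reported in
#' the `diag` field; it never raises an error, so ensemble scans continue.
#'
#' @param q Dimensionless parameters ([dimensionless_params()]).
#' @param cfg A [model_config()].
#' @param init Optional initial [species_state()]; defaults to the uniform
#'   state at `cfg$init_value`.
#' @return An object of class `wf_steady_state`: list with `state`
#'   (a `wf_state`), `converged`, `t_final`, `residual` (max absolute RHS
#'   at termination), `steps`, `diag`, `traj_min` (most negative entry
#'   seen anywhere along the trajectory; solver noise floor is -1e-9),
#'   and, if `cfg$kymograph`, `kymograph` (frames x compartments x
#'   species array) with attribute `times`.
#' @examples
#' q <- dimensionless_params(kact_EIG = 1e-6, kact_JNK = 1e-6,
#'                           kact_JAK = 1e-6, kact_UPD = 1e-6)
#' cfg <- model_config(n_compartments = 20)
#' ss <- integrate_to_steady_state(q, cfg)
#' ss$converged
#' @export
integrate_to_steady_state <- function(q, cfg, init = NULL) {
  qv <- .q_vec(q)
  if (is.null(init)) init <- .uniform_state(cfg)
  if (!inherits(init, "wf_state")) init <- do.call(species_state, init)
  u0 <- .flatten_state(init)
  frame_times <- numeric(0)
  if (isTRUE(cfg$kymograph)) {
    frame_times <- c(0, 10^seq(log10(1e-3), log10(cfg$t_max),
                               length.out = cfg$kymo_frames))
  }
  res <- .integrate_cpp(qv, wound_indicator(cfg),
                        cfg$topology == "mutual",
                        if (cfg$boundary == "zero-flux") 0L else 1L,
                        u0, cfg$t_max, cfg$ss_tol, cfg$rtol, cfg$atol,
                        cfg$max_steps, frame_times)
  out <- list(state = do.call(species_state, .unflatten_state(res$state)),
              converged = res$converged, t_final = res$t,
              residual = res$residual, steps = res$steps, diag = res$diag,
              traj_min = res$traj_min,
              topology = cfg$topology, ss_tol = cfg$ss_tol)
  if (length(frame_times)) {
    k <- res$kymograph
    arr <- array(NA_real_, dim = c(nrow(k), cfg$n_compartments, 4),
                 dimnames = list(NULL, NULL, c("EIG", "JNK", "JAK", "UPD")))
    for (s in 1:4) arr[, , s] <- k[, seq(s, ncol(k), by = 4)]
    attr(arr, "times") <- frame_times
    out$kymograph <- arr
  }
  structure(out, class = "wf_steady_state")
}

#' Newton root-finding oracle for steady states
#'
#' Solves `rhs(u) = 0` by damped Newton iteration from a supplied guess,
#' independently of the time integrator.  Roots need not coincide with the
#' attractor the integration reaches; seeded from a converged integration
#' endpoint the two should agree closely.
#'
#' @param q Dimensionless parameters.
#' @param cfg A [model_config()].
#' @param guess Initial [species_state()] (non-negative).
#' @param tol Residual max-norm target (default `1e-9`).
#' @param max_iter Newton iteration cap.
#' @return List with `state` (`wf_state`), `residual`, `converged`,
#'   `iterations`, `diag` (`"singular_jacobian"` when LU breaks down —
#'   callers fall back to integration; `"step_floor"` when the Newton
#'   step reaches machine precision, i.e. the iterate is a root to
#'   double precision even though the absolute residual floor of a
#'   large-rate parameter set sits above `tol`).
#' @export
steady_state_by_rootfinding <- function(q, cfg, guess, tol = 1e-9,
                                        max_iter = 200L) {
  if (!inherits(guess, "wf_state")) guess <- do.call(species_state, guess)
  if (length(guess$EIG) != cfg$n_compartments)
    stop("guess and configuration disagree on compartment count")
  res <- .newton_cpp(.q_vec(q), wound_indicator(cfg),
                     cfg$topology == "mutual",
                     if (cfg$boundary == "zero-flux") 0L else 1L,
                     .flatten_state(guess), tol, as.integer(max_iter))
  list(state = .unflatten_state(res$state) ,
       residual = res$residual, converged = res$converged,
       iterations = res$iterations, diag = res$diag)
}

#' @export
print.wf_steady_state <- function(x, ...) {
  cat(sprintf("wound-field steady state (%s topology): %s at t = %.4g, max|du/dt| = %.3g\n",
              x$topology, if (x$converged) "converged" else
                paste0("NOT converged (", x$diag, ")"),
              x$t_final, x$residual))
  invisible(x)
}
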