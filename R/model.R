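#' Configure the spatial model
#'
#' Defines the network topology, the 1D discretization of the
#' center-to-periphery axis, the wound geometry, the initial state and the
#' integration controls.  The domain `[0, 1]` is split into `n_compartments`
#' equal compartments of width `1/n_compartments` with centers at
#' `(i - 1/2)/n_compartments`; a compartment lies in the wound iff its
#' center falls inside `wound`.  With the defaults (100 compartments,
#' wound `[0, 0.05]`) exactly 5 compartments carry basal Eiger production.
#'
#' @param topology `"mutual"` (JNK also represses JAK) or
#'   `"unidirectional"` (JAK represses JNK only).
#' @param n_compartments Number of spatial compartments (>= 2).
#' @param wound Interval of basal Eiger production, a sub-interval of \[0, 1\].
#' @param init_value Initial value of all four species in every compartment.
#' @param boundary `"zero-flux"` (reflecting, default) or `"absorbing"`.
#' @param ss_tol Steady-state tolerance on `max |du/dt|`.
#' @param t_max Integration horizon in characteristic time units.
#' @param rtol,atol Local error tolerances of the adaptive integrator.
#' @param max_steps Step-count safety cap.
#' @param kymograph Record a space-time kymograph?
#' @param kymo_frames Number of log-spaced kymograph frames (plus the t = 0
#'   frame).
#' @return A list of class `wf_config`.
#' @export
model_config <- function(topology = c("mutual", "unidirectional"),
                         n_compartments = 100L,
                         wound = c(0, 0.05),
                         init_value = 0.1,
                         boundary = c("zero-flux", "absorbing"),
                         ss_tol = 1e-6, t_max = 1000,
                         rtol = 1e-4, atol = 1e-8,
                         max_steps = 200000L,
                         kymograph = FALSE, kymo_frames = 100L) {
  topology <- match.arg(topology)
  boundary <- match.arg(boundary)
  n_compartments <- as.integer(n_compartments)
  if (is.na(n_compartments) || n_compartments < 2L)
    stop("n_compartments must be >= 2")
  if (length(wound) != 2L || wound[1] > wound[2] ||
      wound[1] < 0 || wound[2] > 1)
    stop("wound must be a sub-interval of [0, 1]")
  if (init_value < 0) stop("init_value must be >= 0")
  if (ss_tol <= 0 || t_max <= 0 || rtol <= 0 || atol <= 0)
    stop("tolerances and horizon must be positive")
  structure(list(topology = topology, n_compartments = n_compartments,
                 domain = c(0, 1), wound = as.numeric(wound),
                 init_value = as.numeric(init_value), boundary = boundary,
                 ss_tol = ss_tol, t_max = t_max, rtol = rtol, atol = atol,
                 max_steps = as.integer(max_steps),
                 kymograph = isTRUE(kymograph),
                 kymo_frames = as.integer(kymo_frames)),
            class = "wf_config")
}

#' Compartment centers of a configuration
#' @param cfg A `wf_config`.
#' @return Numeric vector of compartment center positions in \[0, 1\].
#' @export
compartment_centers <- function(cfg) {
  n <- cfg$n_compartments
  (seq_len(n) - 0.5) / n
}

#' Wound indicator 1(x)
#'
#' @param cfg A `wf_config`.
#' @return 0/1 vector over compartments; 1 where the compartment center
#'   lies inside the wound interval.
#' @export
wound_indicator <- function(cfg) {
  x <- compartment_centers(cfg)
  as.numeric(x >= cfg$wound[1] & x <= cfg$wound[2])
}

#' Four-species state container
#'
#' @param EIG,JNK,JAK,UPD Non-negative concentration vectors of equal length.
#' @return A list of class `wf_state`.
#' @export
species_state <- function(EIG, JNK, JAK, UPD) {
  vs <- list(EIG = as.numeric(EIG), JNK = as.numeric(JNK),
             JAK = as.numeric(JAK), UPD = as.numeric(UPD))
  n <- unique(lengths(vs))
  if (length(n) != 1L) stop("all four species vectors must share one length")
  if (any(unlist(vs) < 0)) stop("species concentrations must be >= 0")
  structure(vs, class = "wf_state")
}

# interleaved flat vector <-> wf_state
.flatten_state <- function(s) {
  as.numeric(rbind(s$EIG, s$JNK, s$JAK, s$UPD))
}

.unflatten_state <- function(u) {
  m <- matrix(u, nrow = 4)
  list(EIG = m[1, ], JNK = m[2, ], JAK = m[3, ], UPD = m[4, ])
}

.uniform_state <- function(cfg, value = cfg$init_value) {
  n <- cfg$n_compartments
  species_state(rep(value, n), rep(value, n), rep(value, n), rep(value, n))
}

.q_vec <- function(q) as.numeric(validate_params(q))

#' Right-hand side of the nondimensional model
#'
#' Computes the per-compartment time derivative of the four species.  Eiger
#' is produced basally in the wound, activated by JNK through a Hill term,
#' degraded linearly and diffuses; JNK is activated by Eiger and inhibited
#' by JAK; JAK self-amplifies in a Upd-dependent Hill term and, under the
#' mutual topology only, is inhibited by JNK; Upd is produced downstream of
#' JNK and diffuses with relative diffusivity `d`.
#'
#' @param state A [species_state()] (all entries >= 0).
#' @param q A dimensionless parameter set ([dimensionless_params()]).
#' @param cfg A [model_config()] whose compartment count matches `state`.
#' @return A `wf_state`-shaped list of derivatives (entries may be negative).
#' @export
model_rhs <- function(state, q, cfg) {
  if (!inherits(state, "wf_state")) state <- do.call(species_state, state)
  if (length(state$EIG) != cfg$n_compartments)
    stop("state and configuration disagree on compartment count")
  u <- .flatten_state(state)
  f <- .rhs_cpp(u, .q_vec(q), wound_indicator(cfg),
                cfg$topology == "mutual",
                if (cfg$boundary == "zero-flux") 0L else 1L)
  .unflatten_state(f)
}

#' Discrete Laplacian on the compartment grid
#'
#' Second-difference operator scaled by `1/dx^2` with `dx = 1/n`.  Under
#' the default zero-flux boundary the end compartments reflect, so the
#' output always sums to zero (no flux enters or leaves the field).
#'
#' @param field Numeric vector of per-compartment values (length >= 2).
#' @param cfg Optional [model_config()]; only the boundary setting is used.
#' @param dx Compartment width; defaults to `1/length(field)`.
#' @return Numeric vector of the same length.
#' @export
laplacian <- function(field, cfg = NULL, dx = 1 / length(field)) {
  n <- length(field)
  if (n < 2L) stop("laplacian needs at least 2 compartments")
  boundary <- if (!is.null(cfg) && cfg$boundary == "absorbing") "absorbing" else "zero-flux"
  left <- c(if (boundary == "zero-flux") field[1] else 0, field[-n])
  right <- c(field[-1], if (boundary == "zero-flux") field[n] else 0)
  (left - 2 * field + right) / dx^2
}
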