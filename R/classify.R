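#' Pearson product-moment correlation
#'
#' Thin wrapper over the standard product-moment formula that signals
#' degenerate (constant) input explicitly instead of returning `NA`
#' silently, since the observed-bistable classifier must treat an undefined
#' correlation as "not bistable" with a diagnostic.
#'
#' @param a,b Equal-length numeric vectors (length >= 3).
#' @return Correlation in \[-1, 1\], or `NA_real_` with attribute
#'   `degenerate = TRUE` when either input is constant.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stop("sequences must have equal length")
  if (length(a) < 3L) stop("need at least 3 points")
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(structure(NA_real_, degenerate = TRUE))
  stats::cor(a, b)
}

.rel_diff <- function(u0, u1) {
  den <- max(u0, u1)
  if (den <= 0) return(structure(NA_real_, degenerate = TRUE))
  abs(u1 - u0) / den
}

.field_curves <- function(field) {
  if (inherits(field, "wf_steady_state")) field$state else field
}

#' Descriptive ("simple") bistability test
#'
#' A converged steady state is a simple bistable pattern when JAK rises
#' and JNK falls from wound to periphery, each by more than
#' `min_rel_change` in relative terms:
#' `JAK(0) < JAK(1)`, `JNK(0) > JNK(1)`,
#' `relD(JAK) > 0.10` and `relD(JNK) > 0.10`, with
#' `relD(u) = |u(1) - u(0)| / max(u(0), u(1))`.  All four thresholds are
#' strict, so a relative difference of exactly 10% does not qualify.
#'
#' @param field A `wf_steady_state` (or a list with `JNK` and `JAK`
#'   curves).  Non-converged fields are classified `FALSE`.
#' @param min_rel_change Relative-difference threshold (default 0.10).
#' @return List with `simple` flag and the four diagnostics
#'   (`jak_rises`, `jnk_falls`, `rel_diff_jak`, `rel_diff_jnk`).
#' @export
classify_simple <- function(field, min_rel_change = 0.10) {
  if (inherits(field, "wf_steady_state") && !isTRUE(field$converged)) {
    return(list(simple = FALSE, jak_rises = NA, jnk_falls = NA,
                rel_diff_jak = NA_real_, rel_diff_jnk = NA_real_,
                diag = "not_converged"))
  }
  s <- .field_curves(field)
  jnk <- s$JNK; jak <- s$JAK
  n <- length(jnk)
  rj <- .rel_diff(jak[1], jak[n])
  rk <- .rel_diff(jnk[1], jnk[n])
  if (is.na(rj) || is.na(rk)) {
    return(list(simple = FALSE, jak_rises = NA, jnk_falls = NA,
                rel_diff_jak = as.numeric(rj), rel_diff_jnk = as.numeric(rk),
                diag = "zero_curve"))
  }
  jak_rises <- jak[1] < jak[n]
  jnk_falls <- jnk[1] > jnk[n]
  list(simple = jak_rises && jnk_falls &&
         rj > min_rel_change && rk > min_rel_change,
       jak_rises = jak_rises, jnk_falls = jnk_falls,
       rel_diff_jak = as.numeric(rj), rel_diff_jnk = as.numeric(rk),
       diag = "ok")
}

#' Correlation-based ("observed") bistability test
#'
#' A converged steady state matches the experimentally observed pattern
#' when the Pearson correlation of the model JNK curve with the reference
#' JNK profile AND of the model JAK curve with the reference JAK profile
#' both exceed `threshold` (strictly; r = 0.7 exactly does not qualify).
#' Reference profiles are resampled to the model grid; masked reference
#' positions are dropped from both curves.
#'
#' @param field A `wf_steady_state` (or list with `JNK`, `JAK` curves).
#' @param ref A reference pair: list with elements `JNK` and `JAK`, each a
#'   [reporter_profile()] (e.g. from [generate_reference_pair()]).
#' @param threshold Correlation threshold (default 0.7).
#' @return List with `observed` flag, `r_jnk`, `r_jak`, `diag`.
#' @export
classify_observed <- function(field, ref, threshold = 0.7) {
  if (inherits(field, "wf_steady_state") && !isTRUE(field$converged)) {
    return(list(observed = FALSE, r_jnk = NA_real_, r_jak = NA_real_,
                diag = "not_converged"))
  }
  s <- .field_curves(field)
  n <- length(s$JNK)
  grid <- (seq_len(n) - 0.5) / n
  rs <- lapply(list(JNK = ref$JNK, JAK = ref$JAK), function(p) {
    keep <- profile_unmasked(p)
    list(y = stats::approx(p$position[keep], p$intensity[keep], xout = grid,
                           rule = 2)$y,
         keep = stats::approx(p$position, as.numeric(profile_unmasked(p)),
                              xout = grid, method = "constant", rule = 2)$y > 0.5)
  })
  r_jnk <- pearson(s$JNK[rs$JNK$keep], rs$JNK$y[rs$JNK$keep])
  r_jak <- pearson(s$JAK[rs$JAK$keep], rs$JAK$y[rs$JAK$keep])
  degenerate <- isTRUE(attr(r_jnk, "degenerate")) ||
    isTRUE(attr(r_jak, "degenerate"))
  list(observed = !degenerate && as.numeric(r_jnk) > threshold &&
         as.numeric(r_jak) > threshold,
       r_jnk = as.numeric(r_jnk), r_jak = as.numeric(r_jak),
       diag = if (degenerate) "degenerate_correlation" else "ok")
}

#' Half-maximum position of a gradient
#'
#' The gradient "width" of a monotone-ish profile: the leftmost position,
#' scanning away from the maximum, where the linearly interpolated curve
#' first crosses half its maximum.
#'
#' @param x Positions (strictly increasing) or a [reporter_profile()].
#' @param y Intensities (ignored when `x` is a profile).
#' @param orientation `"decreasing"` scans rightwards from the maximum
#'   (wound-centred gradients); `"increasing"` scans leftwards.
#' @return Position in \[0, 1\].  A curve that never falls below half max
#'   returns the far domain end with attribute `censored = TRUE`; a flat
#'   curve returns `NA_real_` with attribute `degenerate = TRUE`.
#' @export
half_max_position <- function(x, y = NULL,
                              orientation = c("decreasing", "increasing")) {
  orientation <- match.arg(orientation)
  if (inherits(x, "wf_profile")) { y <- x$intensity; x <- x$position }
  if (is.null(y)) { y <- x; x <- (seq_along(y) - 0.5) / length(y) }
  if (length(x) != length(y) || length(y) < 2L) stop("need matching x, y of length >= 2")
  if (max(y) == min(y)) return(structure(NA_real_, degenerate = TRUE))
  half <- max(y) / 2
  idx <- if (orientation == "decreasing") which.max(y):length(y) else rev(1:which.max(y))
  xs <- x[idx]; ys <- y[idx]
  below <- which(ys < half)
  if (!length(below)) {
    end <- if (orientation == "decreasing") x[length(x)] else x[1]
    return(structure(end, censored = TRUE))
  }
  j <- below[1]
  # linear interpolation between the bracketing samples
  x0 <- xs[j - 1]; y0 <- ys[j - 1]; x1 <- xs[j]; y1 <- ys[j]
  x0 + (half - y0) * (x1 - x0) / (y1 - y0)
}

#' Position where the JAK curve overtakes the JNK curve
#'
#' Both curves are rescaled to their own maximum, then the leftmost
#' position where the rescaled JAK curve meets or exceeds the rescaled JNK
#' curve is located by linear interpolation between the bracketing
#' compartments.  Absence of a crossing is a valid outcome (`NA_real_`).
#'
#' @param jnk,jak Numeric curves on a common grid, or [reporter_profile()]s.
#' @param x Optional shared positions; defaults to compartment centers.
#' @return Position in \[0, 1\] or `NA_real_` when the curves never cross.
#' @export
intersection_position <- function(jnk, jak, x = NULL) {
  if (inherits(jnk, "wf_profile")) { x <- jnk$position; jnk <- jnk$intensity }
  if (inherits(jak, "wf_profile")) { jak <- jak$intensity }
  if (length(jnk) != length(jak)) stop("curves must share a grid")
  if (is.null(x)) x <- (seq_along(jnk) - 0.5) / length(jnk)
  if (max(jnk) <= 0 || max(jak) <= 0) return(NA_real_)
  a <- jnk / max(jnk)
  b <- jak / max(jak)
  diff <- b - a
  if (all(diff == 0)) return(NA_real_)  # identical after rescaling: no crossing
  if (diff[1] >= 0) return(x[1])
  cross <- which(diff[-1] >= 0 & diff[-length(diff)] < 0)
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  x[i] + (0 - diff[i]) * (x[i + 1] - x[i]) / (diff[i + 1] - diff[i])
}
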