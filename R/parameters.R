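#' Canonical order of the dimensionless parameters
#'
#' The scanned constants of the nondimensional wound-signalling model, in
#' the fixed column order used throughout the package: the reaction/diffusion
#' time-scale ratio `gamma`, relative degradation rates, activation rates,
#' Michaelis constants, the two cross-inhibition constants, the Upd/Eiger
#' diffusivity ratio `d`, and six Hill coefficients.
#'
#' @return Character vector of the 21 parameter names.
#' @export
param_names <- function() {
  c("gamma", "kdeg_JNK", "kdeg_JAK", "kdeg_UPD",
    "kact_EIG", "kact_JNK", "kact_JAK", "kact_UPD",
    "Km_EIG", "Km_JNK", "Km_JAK", "Km_UPD",
    "kinh_JAK_by_JNK", "kinh_JNK_by_JAK", "d",
    "n1", "n2", "n3", "n4", "ni1", "ni2")
}

.hill_names <- function() c("n1", "n2", "n3", "n4", "ni1", "ni2")

#' Construct a validated dimensionless parameter set
#'
#' @param ... Named parameter values (see [param_names()]); alternatively a
#'   single named list or named numeric vector.
#' @return A named numeric vector of class `wf_params` in canonical order.
#' @examples
#' q <- dimensionless_params(gamma = 100, kact_JNK = 50)
#' q[["gamma"]]
#' @export
dimensionless_params <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) &&
      (is.list(args[[1L]]) || (is.numeric(args[[1L]]) && !is.null(names(args[[1L]]))))) {
    args <- as.list(args[[1L]])
  }
  q <- stats::setNames(rep(1, 21L), param_names())
  if (length(args)) {
    bad <- setdiff(names(args), param_names())
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    q[names(args)] <- vapply(args, as.numeric, numeric(1))
  }
  validate_params(q)
}

validate_params <- function(q) {
  q <- as.numeric(q[param_names()])
  names(q) <- param_names()
  if (anyNA(q) || any(!is.finite(q))) stop("parameters must be finite and complete")
  # activation and inhibition constants may vanish exactly (switching a
  # term off); everything else must be strictly positive
  zero_ok <- c("kact_EIG", "kact_JNK", "kact_JAK", "kact_UPD",
               "kinh_JAK_by_JNK", "kinh_JNK_by_JAK")
  if (any(q[zero_ok] < 0) || any(q[setdiff(param_names(), zero_ok)] <= 0))
    stop("dimensionless parameters must be positive (kact/kinh may be 0)")
  if (any(q[.hill_names()] < 1)) stop("Hill coefficients must be >= 1")
  structure(q, class = c("wf_params", "numeric"))
}

#' Construct a dimensional parameter set
#'
#' Rates, Michaelis/inhibition constants, diffusivities, Hill coefficients
#' and the characteristic length of the dimensional model, prior to
#' nondimensionalization.  Basal production rates `b_*` may be zero; all
#' other rates, constants and `L` must be strictly positive; Hill
#' coefficients must be at least 1.
#'
#' @param b_EIG,b_JNK,b_JAK,b_UPD Basal production rates (concentration/time).
#' @param kdeg_EIG,kdeg_JNK,kdeg_JAK,kdeg_UPD Linear degradation rates (1/time).
#' @param kact_EIG,kact_JNK,kact_JAK,kact_UPD Activation rate constants.
#' @param Km_EIG,Km_JNK,Km_JAK,Km_UPD Michaelis constants (concentration).
#' @param kinh_JNK_by_JAK,kinh_JAK_by_JNK Cross-inhibition constants.
#' @param D_EIG,D_UPD Diffusion coefficients (length^2/time).
#' @param n1,n2,n3,n4,ni1,ni2 Hill coefficients (dimensionless, >= 1).
#' @param L Characteristic length of the tissue field.
#' @return A named list of class `wf_dim_params`.
#' @export
dimensional_params <- function(b_EIG = 1, b_JNK = 1, b_JAK = 1, b_UPD = 1,
                               kdeg_EIG = 1, kdeg_JNK = 1, kdeg_JAK = 1,
                               kdeg_UPD = 1,
                               kact_EIG = 1, kact_JNK = 1, kact_JAK = 1,
                               kact_UPD = 1,
                               Km_EIG = 1, Km_JNK = 1, Km_JAK = 1, Km_UPD = 1,
                               kinh_JNK_by_JAK = 1, kinh_JAK_by_JNK = 1,
                               D_EIG = 1, D_UPD = 1,
                               n1 = 1, n2 = 1, n3 = 1, n4 = 1,
                               ni1 = 1, ni2 = 1, L = 1) {
  p <- as.list(environment())
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("all dimensional parameters must be numeric")
  basal <- c("b_EIG", "b_JNK", "b_JAK", "b_UPD")
  vals <- unlist(p)
  if (anyNA(vals) || any(!is.finite(vals))) stop("non-finite dimensional parameter")
  if (any(vals[basal] < 0)) stop("basal production rates must be >= 0")
  strict <- setdiff(names(vals), basal)
  if (any(vals[strict] <= 0)) stop("rates, constants, diffusivities and L must be > 0")
  hills <- c("n1", "n2", "n3", "n4", "ni1", "ni2")
  if (any(vals[hills] < 1)) stop("Hill coefficients must be >= 1")
  structure(p, class = "wf_dim_params")
}

#' Map dimensional parameters to the dimensionless scan parameters
#'
#' Collapses the dimensional model onto its nondimensional form: time is
#' measured in diffusion units `L^2/D_EIG`, each species in units of its
#' basal production over the Eiger turnover rate.  The resulting constants
#' are the ones scanned by [sample_parameters()].  Hill coefficients pass
#' through unchanged.
#'
#' @param p A `wf_dim_params` object from [dimensional_params()].
#' @return A `wf_params` dimensionless parameter set.
#' @examples
#' nondimensionalize(dimensional_params(D_UPD = 2))[["d"]]  # 2
#' @export
nondimensionalize <- function(p) {
  if (!inherits(p, "wf_dim_params")) stop("p must be a wf_dim_params object")
  div <- c(p$D_EIG, p$kdeg_EIG, p$b_EIG, p$b_JNK, p$b_JAK, p$b_UPD, p$L)
  if (any(div <= 0)) stop("non-positive divisor in nondimensionalization")
  tau <- p$L^2 / p$D_EIG  # characteristic (diffusion) time
  dimensionless_params(
    gamma = p$kdeg_EIG * tau,
    kdeg_JNK = p$kdeg_JNK / p$kdeg_EIG,
    kdeg_JAK = p$kdeg_JAK / p$kdeg_EIG,
    kdeg_UPD = p$kdeg_UPD / p$kdeg_EIG,
    kact_EIG = p$kact_EIG / p$b_EIG,
    kact_JNK = p$kact_JNK / p$b_JNK,
    kact_JAK = p$kact_JAK * p$b_UPD * tau / p$b_JAK,
    kact_UPD = p$kact_UPD / p$b_UPD,
    Km_EIG = p$Km_EIG / (tau * p$b_EIG),
    Km_JNK = p$Km_JNK / (tau * p$b_JNK),
    Km_JAK = p$Km_JAK / (tau * p$b_JAK),
    Km_UPD = p$Km_UPD / (tau * p$b_UPD),
    kinh_JAK_by_JNK = p$kinh_JAK_by_JNK * p$b_JNK * tau,
    kinh_JNK_by_JAK = p$kinh_JNK_by_JAK * p$b_JAK * tau,
    d = p$D_UPD / p$D_EIG,
    n1 = p$n1, n2 = p$n2, n3 = p$n3, n4 = p$n4,
    ni1 = p$ni1, ni2 = p$ni2)
}

#' Scanned ranges of the dimensionless parameters
#'
#' Per-parameter log-uniform sampling ranges for the ensemble scan.  Most
#' rate ratios span `[1e-2, 1e4]`; the Eiger activation rate and Michaelis
#' constant span `[1e-5, 10]`; the diffusivity ratio `d` spans `[1.5, 4]`
#' in the default (Upd-faster) regime; Hill coefficients are drawn
#' uniformly (not log-uniformly) on `[1, 4]`.
#'
#' @param diffusion_regime `"upd_faster"` (`d` in \[1.5, 4\]),
#'   `"upd_slower"` (`d` in \[0.25, 0.67\]) or `"equal"` (`d = 1`).
#' @param global_interval If `TRUE`, all non-Hill parameters share the
#'   single interval `[1e-3, 1e2]` instead of per-parameter ranges.
#' @return Data frame with columns `parameter`, `low`, `high`, `scale`
#'   (`"log"` or `"uniform"`).
#' @export
default_ranges <- function(diffusion_regime = c("upd_faster", "upd_slower", "equal"),
                           global_interval = FALSE) {
  diffusion_regime <- match.arg(diffusion_regime)
  wide <- c(1e-2, 1e4)
  narrow <- c(1e-5, 10)
  d_range <- switch(diffusion_regime,
                    upd_faster = c(1.5, 4),
                    upd_slower = c(0.25, 0.67),
                    equal = c(1, 1))
  lows <- c(gamma = wide[1], kdeg_JNK = wide[1], kdeg_JAK = wide[1],
            kdeg_UPD = wide[1], kact_EIG = narrow[1], kact_JNK = wide[1],
            kact_JAK = wide[1], kact_UPD = wide[1], Km_EIG = narrow[1],
            Km_JNK = wide[1], Km_JAK = wide[1], Km_UPD = wide[1],
            kinh_JAK_by_JNK = wide[1], kinh_JNK_by_JAK = wide[1],
            d = d_range[1])
  highs <- c(gamma = wide[2], kdeg_JNK = wide[2], kdeg_JAK = wide[2],
             kdeg_UPD = wide[2], kact_EIG = narrow[2], kact_JNK = wide[2],
             kact_JAK = wide[2], kact_UPD = wide[2], Km_EIG = narrow[2],
             Km_JNK = wide[2], Km_JAK = wide[2], Km_UPD = wide[2],
             kinh_JAK_by_JNK = wide[2], kinh_JNK_by_JAK = wide[2],
             d = d_range[2])
  if (global_interval) {
    keep_d <- c(lows[["d"]], highs[["d"]])
    lows[] <- 1e-3
    highs[] <- 1e2
    lows[["d"]] <- keep_d[1]
    highs[["d"]] <- keep_d[2]
  }
  hills <- .hill_names()
  data.frame(
    parameter = c(names(lows), hills),
    low = c(unname(lows), rep(1, length(hills))),
    high = c(unname(highs), rep(4, length(hills))),
    scale = c(rep("log", length(lows)), rep("uniform", length(hills))),
    stringsAsFactors = FALSE)
}
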