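#' Specification of a synthetic reporter profile
#'
#' Parametric stand-ins for traced fluorescence profiles: a shape family
#' evaluated on \[0, 1\], plus track-level Gaussian noise truncated at zero
#' (fluorescence is non-negative).  Defaults emulate confocal line traces:
#' 15 tracks, 100 points per track, noise at 5% of amplitude.
#'
#' @param shape `"logistic"`, `"tanh"`, `"flat"` or `"linear"`.
#' @param midpoint Inflection position in \[0, 1\].
#' @param steepness Slope parameter of the sigmoid families.
#' @param baseline,amplitude Curve offset and dynamic range (`amplitude > 0`).
#' @param orientation `"decreasing"` (JNK-like) or `"increasing"` (JAK-like).
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param n_tracks,points_per_track Track-set geometry.
#' @param seed Integer seed; every generator is a pure function of its
#'   spec including this seed.
#' @return List of class `wf_profile_spec`.
#' @export
synthetic_profile_spec <- function(shape = c("logistic", "tanh", "flat", "linear"),
                                   midpoint = 0.45, steepness = 10,
                                   baseline = 0.02, amplitude = 1,
                                   orientation = c("decreasing", "increasing"),
                                   noise_sd = 0.05, n_tracks = 15L,
                                   points_per_track = 100L, seed = 1L) {
  shape <- match.arg(shape)
  orientation <- match.arg(orientation)
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (midpoint < 0 || midpoint > 1) stop("midpoint must be in [0, 1]")
  if (n_tracks < 1L || points_per_track < 2L) stop("invalid track geometry")
  structure(list(shape = shape, midpoint = midpoint, steepness = steepness,
                 baseline = baseline, amplitude = amplitude,
                 orientation = orientation, noise_sd = noise_sd,
                 n_tracks = as.integer(n_tracks),
                 points_per_track = as.integer(points_per_track),
                 seed = as.integer(seed)),
            class = "wf_profile_spec")
}

#' Evaluate the noiseless shape of a profile spec
#' @param spec A [synthetic_profile_spec()].
#' @param x Positions (default: the spec's uniform grid on \[0, 1\]).
#' @return Numeric vector of noiseless intensities.
#' @export
profile_shape <- function(spec, x = seq(0, 1, length.out = spec$points_per_track)) {
  s <- if (spec$orientation == "increasing") 1 else -1
  core <- switch(spec$shape,
    logistic = 1 / (1 + exp(-s * spec$steepness * (x - spec$midpoint))),
    tanh = (1 + tanh(s * spec$steepness * (x - spec$midpoint))) / 2,
    flat = rep(0.5, length(x)),
    linear = if (s > 0) x else 1 - x)
  spec$baseline + spec$amplitude * core
}

# run fn with a private RNG stream, restoring global state afterwards
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

# derive a per-task seed below 2^31 from a root seed
.split_seed <- function(root, i) {
  ((as.double(root) %% 2147483629) * 48271 + i * 16807) %% 2147483629 + 1
}

#' Generate a noisy synthetic track set
#'
#' `n_tracks` copies of the spec's shape plus i.i.d. Gaussian noise,
#' truncated at zero; deterministic per seed.
#'
#' @param spec A [synthetic_profile_spec()].
#' @return A [track_set()].
#' @export
generate_tracks <- function(spec) {
  if (!inherits(spec, "wf_profile_spec")) stop("spec must be a wf_profile_spec")
  x <- seq(0, 1, length.out = spec$points_per_track)
  mu <- profile_shape(spec, x)
  m <- .with_seed(spec$seed, function() {
    t(vapply(seq_len(spec$n_tracks), function(i)
      pmax(mu + stats::rnorm(length(mu), 0, spec$noise_sd), 0),
      numeric(length(mu))))
  })
  track_set(m, position = x,
            channel = if (spec$orientation == "decreasing") "JNK" else "JAK")
}

#' Generate the default reference profile pair
#'
#' Noiseless, max-scaled stand-ins for the traced JNK (decreasing) and
#' JAK/STAT (increasing) reporter curves used by the observed-bistable
#' classifier, evaluated on the model's compartment-center grid.  The
#' defaults (logistic, midpoint 0.45, steepness 10) satisfy the simple
#' bistability criteria by construction.  The true experimental curves were
#' never published as numbers: this pair is a configurable stand-in, not
#' ground truth.
#'
#' @param jnk_spec,jak_spec Profile specs; the JNK spec should be
#'   decreasing and the JAK spec increasing (a warning is issued otherwise).
#' @param n_grid Number of grid points (model compartments).
#' @return List with scaled `JNK` and `JAK` [reporter_profile()]s.
#' @export
generate_reference_pair <- function(jnk_spec = synthetic_profile_spec(orientation = "decreasing"),
                                    jak_spec = synthetic_profile_spec(orientation = "increasing"),
                                    n_grid = 100L) {
  if (jnk_spec$orientation != "decreasing")
    warning("JNK reference is usually decreasing")
  if (jak_spec$orientation != "increasing")
    warning("JAK reference is usually increasing")
  x <- (seq_len(n_grid) - 0.5) / n_grid
  mk <- function(spec, channel) {
    y <- profile_shape(spec, x)
    reporter_profile(x, y / max(y), channel = channel, scaled = TRUE)
  }
  list(JNK = mk(jnk_spec, "JNK"), JAK = mk(jak_spec, "JAK"))
}

# centered unit-norm version of a curve
.unitize <- function(v) {
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

# build a curve whose Pearson correlation with `target` is exactly r
# (to double precision), using `helper` for the orthogonal component
.curve_with_cor <- function(target, r, helper, offset = 1, amp = 1) {
  a <- .unitize(target)
  h <- helper - mean(helper)
  b <- .unitize(h - sum(h * a) * a)
  z <- r * a + sqrt(1 - r^2) * b
  offset + amp * z
}

# direct product-moment evaluation, independent of the classifier path
.pm_cor <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

#' Analytically labelled classifier fixtures
#'
#' A deterministic battery of steady-state-shaped JNK/JAK curve pairs with
#' expected `simple` and `observed` labels assigned at construction time:
#' `simple` from the known endpoint values via the relative-difference
#' arithmetic, `observed` from a direct product-moment evaluation against
#' the default reference pair.  The battery spans true bistable pairs,
#' flat and wrong-orientation pairs, sub-threshold (5%) and exactly-at-
#' threshold (10%) relative differences, correlations pinned at exactly
#' 0.7 (strictly-greater rule: label `FALSE`), a noisy r ~ 0.9 pair, and
#' anti-correlated curves.
#'
#' @param seed Seed for the noisy cases.
#' @param n_grid Grid size (model compartments).
#' @return A list with `ref` (the default reference pair) and `cases`, a
#'   list of fixtures, each `list(name, JNK, JAK, simple, observed)`.
#' @export
generate_labeled_fixtures <- function(seed = 1L, n_grid = 100L) {
  ref <- generate_reference_pair(n_grid = n_grid)
  x <- (seq_len(n_grid) - 0.5) / n_grid
  rj <- ref$JNK$intensity
  rs <- ref$JAK$intensity

  simple_label <- function(jnk, jak, thr = 0.10) {
    n <- length(jnk)
    rel <- function(u0, u1) abs(u1 - u0) / max(u0, u1)
    jak[1] < jak[n] && jnk[1] > jnk[n] &&
      rel(jak[1], jak[n]) > thr && rel(jnk[1], jnk[n]) > thr
  }
  observed_label <- function(jnk, jak, thr = 0.7) {
    if (stats::sd(jnk) == 0 || stats::sd(jak) == 0) return(FALSE)
    .pm_cor(jnk, rj) > thr && .pm_cor(jak, rs) > thr
  }
  cases <- list()
  add <- function(name, jnk, jak, simple = NULL, observed = NULL) {
    if (is.null(simple)) simple <- simple_label(jnk, jak)
    if (is.null(observed)) observed <- observed_label(jnk, jak)
    cases[[length(cases) + 1L]] <<- list(name = name, JNK = jnk, JAK = jak,
                                         simple = simple, observed = observed)
  }

  # sigmoid stand-ins of varying placement/steepness
  lg <- function(mid, k, s) 1 / (1 + exp(-s * k * (x - mid)))
  add("reference_pair", rj, rs)                      # identical to reference
  add("reference_scaled", 0.37 * rj, 2.5 * rs)       # scale invariance
  add("steep_early", lg(0.2, 30, -1), lg(0.2, 30, 1))
  add("tanh_pair", (1 + tanh(-8 * (x - 0.5))) / 2, (1 + tanh(8 * (x - 0.5))) / 2)
  add("shallow_late", lg(0.7, 6, -1), lg(0.7, 6, 1))

  # degenerate / wrong-orientation
  add("flat_flat", rep(0.5, n_grid), rep(0.5, n_grid),
      simple = FALSE, observed = FALSE)
  add("flat_jnk_rising_jak", rep(0.8, n_grid), rs,
      simple = FALSE, observed = FALSE)
  add("flat_jak_falling_jnk", rj, rep(0.3, n_grid),
      simple = FALSE, observed = FALSE)
  add("orientation_swapped", rs, rj)                 # anti-correlated to ref
  add("jak_reversed_only", rj, rev(rs))
  add("jnk_reversed_only", rev(rj), rs)

  # relative-difference thresholds (endpoint arithmetic is the label);
  # ramp t runs exactly 0 -> 1 across the sampled grid so endpoint values
  # hit the stated levels exactly
  t <- (x - x[1]) / (x[n_grid] - x[1])
  add("rel_diff_jak_5pct", 1 - t, 0.95 + 0.05 * t,
      simple = FALSE)                                # relD(JAK) = 0.05
  add("rel_diff_jak_exact_10pct", 1 - t, 0.9 + 0.1 * t,
      simple = FALSE)                                # relD(JAK) = 0.10, strict
  add("rel_diff_jnk_exact_10pct", 1 - 0.1 * t, t,
      simple = FALSE)                                # relD(JNK) = 0.10, strict
  add("rel_diff_just_above", 1 - 0.2 * t, 0.8 + 0.2 * t,
      simple = TRUE)                                 # relD = 0.20 both
  add("rel_diff_jnk_5pct", 1 - 0.05 * t, t, simple = FALSE)
  add("linear_pair", 1 - t, t, simple = TRUE)

  # correlations pinned by construction against the reference; the
  # at-threshold cases use the cosine helper, whose mixture evaluates to
  # r - 0.7 in {0, -1e-16} under IEEE doubles, so the strict > 0.7 rule
  # classifies them FALSE deterministically
  helper <- sin(2 * pi * x) + 0.3 * cos(5 * pi * x)
  helper_thr <- cos(3 * pi * x)
  jnk_r07 <- .curve_with_cor(rj, 0.7, helper_thr)
  add("cor_jnk_exact_0.7", jnk_r07, rs, observed = FALSE)
  jak_r07 <- .curve_with_cor(rs, 0.7, helper_thr)
  add("cor_jak_exact_0.7", rj, jak_r07, observed = FALSE)
  add("cor_both_0.75",
      .curve_with_cor(rj, 0.75, helper), .curve_with_cor(rs, 0.75, helper),
      observed = TRUE)
  add("cor_jnk_0.6", .curve_with_cor(rj, 0.6, helper), rs, observed = FALSE)
  add("anticorrelated", .curve_with_cor(rj, -1, helper),
      .curve_with_cor(rs, -1, helper), observed = FALSE)

  # noisy-but-correlated (r computed from the realized noisy curves)
  noisy <- .with_seed(seed, function() {
    list(jnk = pmax(rj + stats::rnorm(n_grid, 0, 0.12), 0),
         jak = pmax(rs + stats::rnorm(n_grid, 0, 0.12), 0))
  })
  add("noisy_correlated", noisy$jnk, noisy$jak)
  add("noisy_jnk_only", noisy$jnk, rs)

  list(ref = ref, cases = cases)
}
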