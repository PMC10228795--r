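#' Configure ensemble sampling of the parameter space
#'
#' @param n_sets Number of parameter sets to draw (>= 1).
#' @param seed Root seed; all randomness derives from it.
#' @param ranges Data frame of per-parameter ranges as from
#'   [default_ranges()] (columns `parameter`, `low`, `high`, `scale`).
#' @param hill_values `"continuous"` (uniform on \[1, 4\]) or `"integer"`.
#' @param hill_scheme `"six"` independent Hill coefficients, or `"four"`
#'   which ties the inhibition coefficients to the activation ones
#'   (`ni1 = n2`, `ni2 = n3`), giving the 19-free-parameter scan.
#' @param diffusion_regime Passed to [default_ranges()] when `ranges` is
#'   not supplied.
#' @param global_interval Passed to [default_ranges()].
#' @return List of class `wf_sampling`.
#' @export
sampling_config <- function(n_sets = 1000L, seed = 1L, ranges = NULL,
                            hill_values = c("continuous", "integer"),
                            hill_scheme = c("six", "four"),
                            diffusion_regime = "upd_faster",
                            global_interval = FALSE) {
  hill_values <- match.arg(hill_values)
  hill_scheme <- match.arg(hill_scheme)
  if (n_sets < 1L) stop("n_sets must be >= 1")
  if (is.null(ranges))
    ranges <- default_ranges(diffusion_regime, global_interval)
  need <- c("parameter", "low", "high", "scale")
  if (!all(need %in% names(ranges))) stop("ranges must have columns ",
                                          paste(need, collapse = ", "))
  if (!setequal(ranges$parameter, param_names()))
    stop("ranges must cover exactly the scanned parameters")
  if (any(ranges$low <= 0) || any(ranges$low > ranges$high))
    stop("ranges must be positive with low <= high")
  structure(list(n_sets = as.integer(n_sets), seed = as.integer(seed),
                 ranges = ranges, hill_values = hill_values,
                 hill_scheme = hill_scheme),
            class = "wf_sampling")
}

#' Draw parameter sets log-uniformly
#'
#' Reproducible log-uniform sampling of the non-Hill parameters within
#' their configured ranges and uniform (or integer-uniform) sampling of
#' the Hill coefficients on \[1, 4\].
#'
#' @param cfg A [sampling_config()].
#' @return Data frame with one row per set, columns `set_id` plus
#'   [param_names()].
#' @export
sample_parameters <- function(cfg) {
  if (!inherits(cfg, "wf_sampling")) stop("cfg must be a wf_sampling")
  rg <- cfg$ranges
  rownames(rg) <- rg$parameter
  n <- cfg$n_sets
  draws <- .with_seed(cfg$seed, function() {
    out <- lapply(param_names(), function(p) {
      lo <- rg[p, "low"]; hi <- rg[p, "high"]
      if (rg[p, "scale"] == "log") {
        if (lo == hi) rep(lo, n) else exp(stats::runif(n, log(lo), log(hi)))
      } else {
        if (cfg$hill_values == "integer") sample(seq(lo, hi), n, replace = TRUE)
        else stats::runif(n, lo, hi)
      }
    })
    names(out) <- param_names()
    out
  })
  if (cfg$hill_scheme == "four") {
    draws$ni1 <- draws$n2
    draws$ni2 <- draws$n3
  }
  cbind(data.frame(set_id = seq_len(n)), as.data.frame(draws))
}

.record_one <- function(q, cfg, ref, set_id, topology) {
  cfg$topology <- topology
  ss <- tryCatch(integrate_to_steady_state(q, cfg),
                 error = function(e) NULL)
  if (is.null(ss)) {
    return(data.frame(set_id = set_id, topology = topology,
                      converged = FALSE, residual = NA_real_,
                      t_final = NA_real_, observed = FALSE, simple = FALSE,
                      r_jnk = NA_real_, r_jak = NA_real_,
                      jak_rises = NA, jnk_falls = NA,
                      rel_diff_jak = NA_real_, rel_diff_jnk = NA_real_,
                      jnk_half_max = NA_real_, jnk_half_max_censored = NA,
                      eig_half_max = NA_real_, eig_half_max_censored = NA,
                      intersection = NA_real_, diag = "error"))
  }
  simp <- classify_simple(ss)
  obs <- classify_observed(ss, ref)
  jnk_hm <- eig_hm <- inter <- NA_real_
  jnk_cens <- eig_cens <- NA
  if (ss$converged) {
    h1 <- half_max_position(ss$state$JNK)
    h2 <- half_max_position(ss$state$EIG)
    jnk_hm <- as.numeric(h1); jnk_cens <- isTRUE(attr(h1, "censored"))
    eig_hm <- as.numeric(h2); eig_cens <- isTRUE(attr(h2, "censored"))
    inter <- intersection_position(ss$state$JNK, ss$state$JAK)
  }
  data.frame(set_id = set_id, topology = topology,
             converged = ss$converged, residual = ss$residual,
             t_final = ss$t_final, observed = obs$observed,
             simple = simp$simple, r_jnk = obs$r_jnk, r_jak = obs$r_jak,
             jak_rises = simp$jak_rises, jnk_falls = simp$jnk_falls,
             rel_diff_jak = simp$rel_diff_jak,
             rel_diff_jnk = simp$rel_diff_jnk,
             jnk_half_max = jnk_hm, jnk_half_max_censored = jnk_cens,
             eig_half_max = eig_hm, eig_half_max_censored = eig_cens,
             intersection = inter, diag = ss$diag)
}

#' Run a paired-topology ensemble scan
#'
#' For every sampled parameter set, integrates BOTH topologies on the
#' identical draw (the inhibition term toggled), classifies the steady
#' states by the simple and observed criteria, and records gradient
#' geometry (JNK and Eiger half-max positions, JNK-JAK intersection).
#' Non-converged runs carry both flags `FALSE` and are tallied via the
#' `converged` column; per-set failures are recorded, never abort the scan.
#'
#' @param sampling A [sampling_config()] (or a pre-drawn parameter table
#'   from [sample_parameters()]).
#' @param cfg A [model_config()]; its `topology` field is overridden.
#' @param ref Reference profile pair for the observed criterion
#'   (default: [generate_reference_pair()]).
#' @param topologies Which topologies to run (default both, paired).
#' @param progress Print a progress line every 1000 sets?
#' @return Data frame of classification records (one row per set per
#'   topology) merged with the sampled parameter columns; the parameter
#'   table is attached as attribute `params`.
#' @export
run_scan <- function(sampling, cfg = model_config(),
                     ref = generate_reference_pair(n_grid = cfg$n_compartments),
                     topologies = c("mutual", "unidirectional"),
                     progress = FALSE) {
  params <- if (is.data.frame(sampling)) sampling else sample_parameters(sampling)
  topologies <- match.arg(topologies, several.ok = TRUE)
  rows <- vector("list", nrow(params) * length(topologies))
  k <- 0L
  for (i in seq_len(nrow(params))) {
    q <- dimensionless_params(as.list(params[i, param_names()]))
    for (tp in topologies) {
      k <- k + 1L
      rows[[k]] <- .record_one(q, cfg, ref, params$set_id[i], tp)
    }
    if (progress && i %% 1000L == 0L)
      message(sprintf("scan: %d / %d sets done", i, nrow(params)))
  }
  rec <- do.call(rbind, rows)
  rec <- merge(rec, params, by = "set_id", sort = TRUE)
  rec <- rec[order(rec$set_id, rec$topology), ]
  rownames(rec) <- NULL
  attr(rec, "params") <- params
  class(rec) <- c("wf_records", "data.frame")
  rec
}

#' Compare topologies on a paired scan
#'
#' Counts and percentages of observed-, simple- and both-criteria bistable
#' solutions per topology, plus the paired (same parameter set)
#' contingency of the simple flag between topologies.
#'
#' @param records Records from [run_scan()] covering both topologies on
#'   the same parameter sets.
#' @return List with `summary` (one row per topology) and `paired_simple`
#'   (2x2 contingency counts of the mutual vs unidirectional simple flag).
#' @export
compare_models <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty record table")
  tps <- sort(unique(records$topology))
  ids <- lapply(tps, function(tp) sort(records$set_id[records$topology == tp]))
  if (length(tps) == 2L && !identical(ids[[1]], ids[[2]]))
    stop("topologies do not cover identical parameter sets")
  summ <- do.call(rbind, lapply(tps, function(tp) {
    r <- records[records$topology == tp, ]
    n <- nrow(r)
    data.frame(topology = tp, n_sets = n,
               n_converged = sum(r$converged),
               n_observed = sum(r$observed),
               n_simple = sum(r$simple),
               n_both = sum(r$observed & r$simple),
               pct_observed = 100 * sum(r$observed) / n,
               pct_simple = 100 * sum(r$simple) / n,
               pct_both = 100 * sum(r$observed & r$simple) / n)
  }))
  out <- list(summary = summ)
  if (all(c("mutual", "unidirectional") %in% tps)) {
    m <- records[records$topology == "mutual", ]
    u <- records[records$topology == "unidirectional", ]
    m <- m[order(m$set_id), ]; u <- u[order(u$set_id), ]
    out$paired_simple <- table(mutual = factor(m$simple, c(FALSE, TRUE)),
                               unidirectional = factor(u$simple, c(FALSE, TRUE)))
  }
  out
}

#' Frequency of simple bistability across a parameter's range
#'
#' Bins one scanned parameter log-uniformly over its range and reports the
#' per-bin fraction of simple-bistable classifications (the diagonal bar
#' graphs of the parameter-density analysis).
#'
#' @param records Records from [run_scan()] (filter to one topology first
#'   if both are present; default keeps `"mutual"` rows when present).
#' @param parameter One of [param_names()].
#' @param bins Number of bins (default 10).
#' @param range Optional `c(low, high)`; defaults to the observed range.
#' @return Data frame with `bin_low`, `bin_high`, `n`, `n_simple`,
#'   `frequency`; `sum(n)` equals the number of classified records.
#' @export
parameter_density <- function(records, parameter, bins = 10L, range = NULL) {
  if (!parameter %in% param_names()) stop("unknown parameter: ", parameter)
  if ("topology" %in% names(records) && "mutual" %in% records$topology)
    records <- records[records$topology == "mutual", ]
  v <- records[[parameter]]
  if (is.null(range)) range <- base::range(v)
  hill <- parameter %in% .hill_names()
  edges <- if (hill) seq(range[1], range[2], length.out = bins + 1L)
           else exp(seq(log(range[1]), log(range[2]), length.out = bins + 1L))
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  out <- data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
                    n = tabulate(idx, nbins = bins),
                    n_simple = vapply(seq_len(bins), function(b)
                      sum(records$simple[idx == b]), numeric(1)))
  out$frequency <- ifelse(out$n > 0, out$n_simple / out$n, 0)
  out
}
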