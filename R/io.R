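# CSV writing with 17 significant digits so numeric round-trips are
# value-exact; missing values are empty fields, never sentinel numbers.
.write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- ""
      out[[j]] <- v
    } else if (is.logical(out[[j]]) || is.integer(out[[j]])) {
      v <- as.character(out[[j]])
      v[is.na(out[[j]])] <- ""
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "", eol = "\n")
  invisible(path)
}

#' Parameter-table round-trip
#'
#' One row per parameter set, columns named canonically (see
#' [param_names()]); numeric text carries 17 significant digits.
#'
#' @param params Data frame from [sample_parameters()].
#' @param path CSV path.
#' @return `read_parameter_table()` returns the data frame; the writer
#'   returns `path` invisibly.
#' @export
write_parameter_table <- function(params, path) .write_csv_precise(params, path)

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(param_names(), names(df))
  if (length(miss)) stop("malformed parameter table, missing: ",
                         paste(miss, collapse = ", "))
  df
}

#' Classification-record round-trip
#'
#' @param records Records from [run_scan()].
#' @param path CSV path.
#' @return Reader returns the records data frame (absent intersection
#'   positions stay `NA`, not 0); writer returns `path` invisibly.
#' @export
write_records <- function(records, path) {
  .write_csv_precise(as.data.frame(records), path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("converged", "observed", "simple", "jak_rises", "jnk_falls",
                "jnk_half_max_censored", "eig_half_max_censored"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  class(df) <- c("wf_records", "data.frame")
  df
}

#' Steady-state field round-trip
#'
#' Tabular text form: one row per compartment with position and the four
#' species; convergence metadata travels in a JSON sidecar
#' (`<path>.meta.json`).  [save_steady_state_archive()] additionally
#' offers a compact binary container (RDS) for kymograph-bearing runs.
#'
#' @param ss A `wf_steady_state` from [integrate_to_steady_state()].
#' @param path CSV path.
#' @return Reader returns a list mirroring the steady state; writers
#'   return `path` invisibly.
#' @export
write_steady_state <- function(ss, path) {
  n <- length(ss$state$EIG)
  df <- data.frame(x = (seq_len(n) - 0.5) / n,
                   EIG = ss$state$EIG, JNK = ss$state$JNK,
                   JAK = ss$state$JAK, UPD = ss$state$UPD)
  .write_csv_precise(df, path)
  meta <- list(converged = ss$converged, t_final = ss$t_final,
               residual = ss$residual, steps = ss$steps, diag = ss$diag,
               topology = ss$topology, ss_tol = ss$ss_tol)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_steady_state
#' @export
read_steady_state <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  c(list(state = species_state(df$EIG, df$JNK, df$JAK, df$UPD)), meta)
}

#' @rdname write_steady_state
#' @export
save_steady_state_archive <- function(ss, path) {
  saveRDS(ss, path)
  invisible(path)
}

#' @rdname write_steady_state
#' @export
load_steady_state_archive <- function(path) readRDS(path)

.config_schema <- list(
  model = c("topology", "n_compartments", "wound", "init_value", "boundary",
            "ss_tol", "t_max", "rtol", "atol", "max_steps", "kymograph",
            "kymo_frames"),
  sampling = c("n_sets", "seed", "hill_values", "hill_scheme",
               "diffusion_regime", "global_interval", "ranges"),
  classify = c("threshold", "min_rel_change"),
  profile = c("span"))

#' Load and validate a pipeline configuration
#'
#' Reads a JSON configuration with optional sections `model`, `sampling`,
#' `classify` and `profile`, fills defaults (100 compartments, wound
#' \[0, 0.05\], initial value 0.1, steady-state tolerance 1e-6, tabulated
#' scan ranges, span 0.8, thresholds 0.7 and 10%), and rejects unknown
#' keys with an itemized message.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return List with `model` (a `wf_config`), `sampling` (a
#'   `wf_sampling`), `classify`, `profile`, and `raw` (the snapshot that
#'   goes into the run manifest).
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list()
         else jsonlite::read_json(path, simplifyVector = TRUE)
  bad_top <- setdiff(names(raw), names(.config_schema))
  errs <- if (length(bad_top)) paste0("unknown section(s): ",
                                      paste(bad_top, collapse = ", "))
  for (sec in intersect(names(raw), names(.config_schema))) {
    bad <- setdiff(names(raw[[sec]]), .config_schema[[sec]])
    if (length(bad))
      errs <- c(errs, paste0("unknown key(s) in '", sec, "': ",
                             paste(bad, collapse = ", ")))
  }
  if (length(errs)) stop(paste(errs, collapse = "; "))
  model <- do.call(model_config, raw$model %||% list())
  samp_args <- raw$sampling %||% list()
  if (!is.null(samp_args$ranges)) samp_args$ranges <- as.data.frame(samp_args$ranges)
  sampling <- do.call(sampling_config, samp_args)
  classify <- utils::modifyList(list(threshold = 0.7, min_rel_change = 0.10),
                                as.list(raw$classify %||% list()))
  profile <- utils::modifyList(list(span = 0.8), as.list(raw$profile %||% list()))
  list(model = model, sampling = sampling, classify = classify,
       profile = profile, raw = raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Captures the configuration snapshot, seeds, package version, per-stage
#' timings and MD5 digests of the files a run produced, so a deterministic
#' run can be reproduced from the manifest alone.
#'
#' @param dir Output directory (one manifest per scan directory).
#' @param config Configuration snapshot (any JSON-serializable list).
#' @param seeds Named list/vector of seeds used.
#' @param timings Named numeric vector of stage timings (seconds).
#' @param files Character vector of produced files to digest.
#' @return Path of `manifest.json`, invisibly.
#' @export
write_manifest <- function(dir, config, seeds, timings = NULL, files = character()) {
  digests <- if (length(files)) as.list(tools::md5sum(files)) else list()
  manifest <- list(
    package = "woundfield",
    version = as.character(utils::packageVersion("woundfield")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config, seeds = as.list(seeds),
    timings_sec = as.list(timings), digests = digests)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
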