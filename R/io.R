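## Plain-text interchange for the assay data the analysis stages consume:
## titration CSVs (with explicit concentration-unit columns), stopped-flow
## trace CSVs, trajectory CSVs with metadata headers, velocity-curve CSVs,
## and YAML mixture/rate configs. All concentrations are converted to molar
## on read.

#' Read a titration series from CSV
#'
#' Expects a header with a titrant column named `titrant_M`, `titrant_nM`
#' or `titrant_uM` (the suffix fixes the unit), a `signal` column, and an
#' optional `signal_err` column.
#'
#' @param path CSV file path.
#' @return a [titration_series()].
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path)
  unit_col <- grep("^titrant_(M|nM|uM)$", names(df), value = TRUE)
  if (length(unit_col) != 1) {
    stop("expected exactly one titrant_M / titrant_nM / titrant_uM column",
         call. = FALSE)
  }
  unit <- sub("^titrant_", "", unit_col)
  titration_series(
    titrant_total = to_molar(df[[unit_col]], unit),
    signal = df$signal,
    signal_err = if ("signal_err" %in% names(df)) df$signal_err else NULL
  )
}

#' Read a stopped-flow trace from CSV
#'
#' Expects columns `time_s` and `intensity`. The titrant concentration is
#' taken from `conc_nM` metadata in the filename (convention
#' `trace_<conc>nM.csv`) unless given explicitly.
#'
#' @param path CSV file path.
#' @param profilin_total titrant concentration (molar); if `NULL`, parsed
#'   from a `trace_<conc>nM` filename.
#' @return a [stopped_flow_trace()].
#' @export
read_trace_csv <- function(path, profilin_total = NULL) {
  df <- utils::read.csv(path)
  if (is.null(profilin_total)) {
    m <- regmatches(basename(path),
                    regexec("trace_([0-9.]+)nM", basename(path)))[[1]]
    if (length(m) < 2) {
      stop("profilin_total not given and filename does not follow ",
           "trace_<conc>nM convention", call. = FALSE)
    }
    profilin_total <- to_molar(as.numeric(m[2]), "nM")
  }
  stopped_flow_trace(df$time_s, df$intensity, profilin_total)
}

#' Write a filament trajectory to CSV with metadata headers
#'
#' Metadata (`# seed=`, `# conc_uM=` and the cycle rates) is written as
#' comment lines before the header; columns are `time_s`,
#' `length_subunits`, `end_state`.
#'
#' @param traj a `filament_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "filament_trajectory"))
  p <- traj$params
  meta <- c(sprintf("# seed=%d", traj$seed),
            sprintf("# conc_uM=%.10g", p$conc * 1e6))
  if (inherits(p$rates, "cycle_rates")) {
    meta <- c(meta,
              sprintf("# k_bind=%.10g", p$rates$k_bind),
              sprintf("# k_trans=%.10g", p$rates$k_trans),
              sprintf("# k_release=%.10g", p$rates$k_release))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(data.frame(time_s = traj$times,
                              length_subunits = traj$lengths,
                              end_state = traj$end_state),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a filament trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path CSV file path.
#' @return a `filament_trajectory` (params restored from metadata when
#'   present).
#' @export
read_trajectory_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=")[[1]]
    meta[[kv[1]]] <- as.numeric(kv[2])
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  params <- list(conc = if (!is.null(meta$conc_uM)) meta$conc_uM * 1e-6 else NA)
  if (!is.null(meta$k_bind)) {
    params$rates <- cycle_rates(meta$k_bind, meta$k_trans, meta$k_release)
  }
  .new_trajectory(df$time_s, as.integer(df$length_subunits),
                  as.character(df$end_state),
                  seed = if (!is.null(meta$seed)) as.integer(meta$seed) else NA_integer_,
                  params = params)
}

#' Write a velocity curve to CSV
#'
#' Columns: `conc_uM`, `v_mean_sub_per_s`, `v_sd`, `n`.
#'
#' @param curve a [velocity_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_velocity_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "velocity_curve"))
  utils::write.csv(data.frame(conc_uM = curve$conc * 1e6,
                              v_mean_sub_per_s = curve$v_mean,
                              v_sd = curve$v_sd, n = curve$n),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a velocity curve from CSV
#'
#' @param path CSV with columns `conc_uM`, `v_mean_sub_per_s`, `v_sd`, `n`.
#' @return a [velocity_curve()].
#' @export
read_velocity_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  velocity_curve(df$conc_uM * 1e-6, df$v_mean_sub_per_s, df$v_sd, df$n)
}

#' Read a competition-mixture config from YAML
#'
#' Keys `a_total`, `p_total`, `w_total`, `kp`, `kw`, each either a bare
#' number (molar) or a list with `value` and `unit`.
#'
#' @param path YAML file path.
#' @return a [competition_mixture()].
#' @export
read_mixture_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  get_molar <- function(key) {
    x <- cfg[[key]]
    if (is.null(x)) stop("missing key `", key, "` in mixture YAML", call. = FALSE)
    if (is.list(x)) to_molar(x$value, x$unit) else as.numeric(x)
  }
  competition_mixture(get_molar("a_total"), get_molar("p_total"),
                      get_molar("w_total"), get_molar("kp"), get_molar("kw"))
}

#' Read elongation-cycle rates (and optional formin factors) from YAML
#'
#' Keys: `k_bind` (either per_M_per_s as a number, or a list with `value`
#' and `unit` in `per_M_per_s` / `per_uM_per_s`), `k_trans`, `k_release`,
#' optional `formin: {f_bind, f_release, label}`.
#'
#' @param path YAML file path.
#' @return a list with `rates` (a [cycle_rates()]) and `formin`
#'   (a [formin_factors()] or `NULL`).
#' @export
read_cycle_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  kb <- cfg$k_bind
  if (is.list(kb)) {
    kb <- switch(kb$unit,
                 per_M_per_s = kb$value,
                 per_uM_per_s = kb$value * 1e6,
                 stop("unknown k_bind unit: ", kb$unit, call. = FALSE))
  }
  rates <- cycle_rates(kb, cfg$k_trans, cfg$k_release)
  formin <- NULL
  if (!is.null(cfg$formin)) {
    formin <- formin_factors(cfg$formin$f_bind, cfg$formin$f_release,
                             cfg$formin$label %||% "formin")
  }
  list(rates = rates, formin = formin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
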