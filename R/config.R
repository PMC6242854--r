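# Unit handling and run configuration.
#
# Config files carry explicit units on every physical quantity
# ("hamaker: 5 zJ", "branch_width: 15 um"); everything is converted to SI
# on load so the numerics never see a non-SI number.

.unit_si <- c(
  # length
  "m" = 1, "mm" = 1e-3, "um" = 1e-6, "µm" = 1e-6, "nm" = 1e-9,
  # energy
  "J" = 1, "zJ" = 1e-21, "aJ" = 1e-18,
  # voltage
  "V" = 1, "mV" = 1e-3,
  # conductivity
  "S/m" = 1, "mS/m" = 1e-3, "uS/m" = 1e-6, "µS/m" = 1e-6,
  # frequency
  "Hz" = 1, "kHz" = 1e3, "MHz" = 1e6,
  # inverse length
  "1/m" = 1, "1/nm" = 1e9, "nm^-1" = 1e9,
  # viscosity
  "Pa.s" = 1, "Pa*s" = 1, "mPa.s" = 1e-3, "mPa*s" = 1e-3,
  # volumetric flow
  "m3/s" = 1, "ul/min" = 1e-9 / 60, "µl/min" = 1e-9 / 60,
  "ul/s" = 1e-9, "ml/min" = 1e-6 / 60,
  # time
  "s" = 1, "ms" = 1e-3, "min" = 60,
  # temperature
  "K" = 1,
  # percent and dimensionless
  "%" = 1, "-" = 1
)

#' Parse a quantity with units into SI
#'
#' Accepts a bare number or a string `"<number> <unit>"` (e.g. `"5 zJ"`,
#' `"15 um"`, `"1 kHz"`, `"1 ul/min"`) and returns the value in SI base
#' units. Unknown unit strings are an error, so configuration typos fail
#' loudly instead of silently changing scale.
#'
#' @param x Number or string.
#' @return Numeric scalar in SI units.
#' @examples
#' parse_quantity("5 zJ")      # 5e-21
#' parse_quantity("0.159 nm^-1")
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) {
    stopifnot(length(x) == 1L)
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L)
    stop("quantity must be a number or a '<value> <unit>' string")
  s <- trimws(x)
  m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*(.*)$", s))[[1L]]
  if (length(m) != 3L || m[2L] == "" || is.na(suppressWarnings(as.numeric(m[2L]))))
    stop(sprintf("cannot parse quantity '%s'", x))
  val <- as.numeric(m[2L])
  unit <- trimws(m[3L])
  if (unit == "") return(val)
  if (!unit %in% names(.unit_si))
    stop(sprintf("unknown unit '%s' in quantity '%s'", unit, x))
  val * .unit_si[[unit]]
}

# allowed keys and their defaults (SI after parsing)
.config_schema <- function() {
  list(
    seed = NULL,                 # required
    haematocrit_pct = 25,
    volume_ul = 0.02,
    voltage = 20,
    frequency = 1e3,
    duration = 60,
    dt = 0.25,
    noise_cv = 0.1,
    replicates = 3L,
    output_dir = NULL,
    network = list(main_width = 100e-6, depth = 80e-6, branch_width = 15e-6,
                   n_branches = 50L, branch_length = 5e-3,
                   main_segment_length = 200e-6, outlet_length = 2e-3,
                   inlet_flow = 1e-9 / 60, fluid_viscosity = 1.2e-3),
    adhesion = list(hamaker = 5e-21, debye_kappa = 0.159e9,
                    temperature = 296.15, valency = 1L,
                    zeta_particle = -10.8e-3, zeta_wall = -13.825e-3,
                    eps_medium = 78),
    field = list(electrode_gap = 5e-6, electrode_pitch = 10e-6,
                 voltage_is_rms = FALSE),
    control = list(h_capture = 1e-8, approach_window = 10, clog_fraction = 1,
                   aggregation_factor = 3, attach_rate = 0.002,
                   margination_d_ref = 10e-6,
                   debris_diameter = 0.5e-6, lysis_rate = 0.009,
                   lysis_threshold = 20, time_compression = 60,
                   checkpoint_every = 10L)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys (at every level),
#' converts every quantity to SI via [parse_quantity()], and fills the
#' documented defaults for anything not given. Only `seed` is mandatory.
#' All validation failures are reported together.
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config`: the flat settings plus ready
#'   `network`, `adhesion`, `field` (a [field_model()]) and `control`
#'   components.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  schema <- .config_schema()
  errors <- character()

  check_level <- function(given, allowed, prefix = "") {
    unknown <- setdiff(names(given), names(allowed))
    if (length(unknown) > 0L)
      errors <<- c(errors, sprintf("unknown key(s): %s",
                                   paste0(prefix, unknown, collapse = ", ")))
  }
  check_level(raw, schema)
  merged <- schema
  for (k in intersect(names(raw), names(schema))) {
    if (is.list(schema[[k]]) && k != "output_dir") {
      if (!is.list(raw[[k]])) {
        errors <- c(errors, sprintf("key '%s' must be a mapping", k))
        next
      }
      check_level(raw[[k]], schema[[k]], paste0(k, "."))
      for (k2 in intersect(names(raw[[k]]), names(schema[[k]]))) {
        merged[[k]][[k2]] <- raw[[k]][[k2]]
      }
    } else {
      merged[[k]] <- raw[[k]]
    }
  }
  if (is.null(merged$seed)) errors <- c(errors, "missing required key 'seed'")

  to_si <- function(x, key) {
    tryCatch(parse_quantity(x),
             error = function(e) {
               errors <<- c(errors, sprintf("%s: %s", key, conditionMessage(e)))
               NA_real_
             })
  }
  num_keys <- c("haematocrit_pct", "volume_ul", "voltage", "frequency",
                "duration", "dt", "noise_cv")
  for (k in num_keys) merged[[k]] <- to_si(merged[[k]], k)
  for (k in setdiff(names(merged$network), character()))
    merged$network[[k]] <- to_si(merged$network[[k]], paste0("network.", k))
  for (k in names(merged$adhesion))
    merged$adhesion[[k]] <- to_si(merged$adhesion[[k]], paste0("adhesion.", k))
  for (k in setdiff(names(merged$field), "voltage_is_rms"))
    merged$field[[k]] <- to_si(merged$field[[k]], paste0("field.", k))
  for (k in names(merged$control))
    merged$control[[k]] <- to_si(merged$control[[k]], paste0("control.", k))

  if (length(errors) > 0L)
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))

  net <- channel_network(
    main_width = merged$network$main_width, depth = merged$network$depth,
    branch_width = merged$network$branch_width,
    n_branches = as.integer(merged$network$n_branches),
    branch_length = merged$network$branch_length,
    main_segment_length = merged$network$main_segment_length,
    outlet_length = merged$network$outlet_length,
    inlet_flow = merged$network$inlet_flow,
    fluid_viscosity = merged$network$fluid_viscosity)
  adh <- adhesion_params(
    hamaker_A = merged$adhesion$hamaker,
    debye_kappa = merged$adhesion$debye_kappa,
    temperature_T = merged$adhesion$temperature,
    valency_z = as.integer(merged$adhesion$valency),
    zeta_particle = merged$adhesion$zeta_particle,
    zeta_wall = merged$adhesion$zeta_wall,
    eps_medium = merged$adhesion$eps_medium)
  fld <- field_model(
    voltage_amplitude = merged$voltage, frequency = merged$frequency,
    electrode_gap_g = merged$field$electrode_gap,
    electrode_pitch_p = merged$field$electrode_pitch,
    voltage_is_rms = isTRUE(merged$field$voltage_is_rms))
  ctl <- sim_control(
    h_capture = merged$control$h_capture,
    approach_window = merged$control$approach_window,
    clog_fraction = merged$control$clog_fraction,
    aggregation_factor = merged$control$aggregation_factor,
    attach_rate = merged$control$attach_rate,
    margination_d_ref = merged$control$margination_d_ref,
    debris_diameter = merged$control$debris_diameter,
    lysis_rate = merged$control$lysis_rate,
    lysis_threshold = merged$control$lysis_threshold,
    time_compression = merged$control$time_compression,
    checkpoint_every = as.integer(merged$control$checkpoint_every))

  structure(list(seed = as.integer(merged$seed),
                 haematocrit_pct = merged$haematocrit_pct,
                 volume_ul = merged$volume_ul,
                 voltage = merged$voltage, frequency = merged$frequency,
                 duration = merged$duration, dt = merged$dt,
                 noise_cv = merged$noise_cv,
                 replicates = as.integer(merged$replicates),
                 output_dir = merged$output_dir,
                 network = net, adhesion = adh, field = fld, control = ctl,
                 source_path = normalizePath(path)),
            class = "run_config")
}

#' Read / write count-table CSVs
#'
#' The CSV has a header `species,c_in,c_blood_out,c_plasma_out`; species
#' rows carry concentrations in cells/ul, and an optional row with species
#' `haematocrit` carries the three haematocrit percentages in the same
#' columns.
#'
#' @param path CSV path.
#' @return `read_count_table()`: a [count_table()].
#' @export
read_count_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "c_in", "c_blood_out", "c_plasma_out")
  if (!all(need %in% names(df)))
    stop("count-table CSV must have columns: ", paste(need, collapse = ", "))
  hrow <- df$species == "haematocrit"
  h <- if (any(hrow)) unlist(df[which(hrow)[1L], c("c_in", "c_blood_out", "c_plasma_out")])
       else c(NA_real_, NA_real_, NA_real_)
  df <- df[!hrow, , drop = FALSE]
  count_table(df$species, df$c_in, df$c_blood_out, df$c_plasma_out,
              h_in = h[[1L]], h_blood_out = h[[2L]], h_plasma_out = h[[3L]])
}

#' @rdname read_count_table
#' @param table A [count_table()].
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- as.data.frame(table)
  h <- c(attr(table, "h_in"), attr(table, "h_blood_out"),
         attr(table, "h_plasma_out"))
  if (!all(is.na(h)))
    df <- rbind(df, data.frame(species = "haematocrit", c_in = h[1L],
                               c_blood_out = h[2L], c_plasma_out = h[3L]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run report
#'
#' Writes the derived count table, the performance report, the branch-state
#' time series, and a plain-text run summary (seed, operating point, config
#' hash) sufficient for an exact re-run.
#'
#' @param results A list as returned by [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  f <- file.path(dir, "count_table.csv")
  write_count_table(results$outcome$count_table, f); files <- c(files, f)
  f <- file.path(dir, "performance.csv")
  utils::write.csv(cbind(as.data.frame(results$report),
                         plasma_yield_pct = attr(results$report, "plasma_yield_pct")),
                   f, row.names = FALSE); files <- c(files, f)
  f <- file.path(dir, "branch_timeseries.csv")
  utils::write.csv(results$outcome$timeseries, f, row.names = FALSE)
  files <- c(files, f)

  cfg <- results$config
  cfg_hash <- unname(tools::md5sum(cfg$source_path))
  f <- file.path(dir, "run_summary.txt")
  writeLines(c(
    sprintf("depclog run summary (%s)",
            as.character(utils::packageVersion("depclog"))),
    sprintf("config: %s (md5 %s)", cfg$source_path, cfg_hash),
    sprintf("seed: %d", cfg$seed),
    sprintf("voltage: %g V, frequency: %g Hz", cfg$voltage, cfg$frequency),
    sprintf("haematocrit: %g %%, sample volume: %g ul",
            cfg$haematocrit_pct, cfg$volume_ul),
    sprintf("duration: %g s (dt %g s), time compression: %g",
            cfg$duration, cfg$dt, cfg$control$time_compression),
    sprintf("plasma share (mean): %.4f", results$outcome$plasma_share_mean),
    sprintf("clogged branches: %d/%d", sum(results$outcome$branches$clogged),
            nrow(results$outcome$branches))
  ), f)
  files <- c(files, f)
  invisible(files)
}

#' Run the full pipeline from a configuration
#'
#' generate population -> simulate separation -> emulate noisy replicate
#' counting -> performance metrics, all driven by one [load_config()]
#' result (or a path to one). No external input is needed.
#'
#' @param config A `run_config` or a path to a YAML config.
#' @return List with `config`, `population`, `outcome`, `noisy` (replicate
#'   tables and summary) and `report` (a [performance_report()], computed
#'   on the mean of the noisy replicates).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  pop <- generate_population(config$haematocrit_pct, config$volume_ul,
                             seed = config$seed)
  out <- simulate_separation(pop, config$network, voltage = config$voltage,
                             frequency = config$frequency,
                             duration = config$duration, dt = config$dt,
                             seed = config$seed, adhesion = config$adhesion,
                             field = config$field, control = config$control)
  noisy <- emulate_count_experiment(out$count_table, config$noise_cv,
                                    config$replicates, seed = config$seed + 1L)
  mean_tab <- count_table(noisy$mean$species, noisy$mean$c_in,
                          noisy$mean$c_blood_out, noisy$mean$c_plasma_out,
                          h_in = attr(out$count_table, "h_in"),
                          h_blood_out = attr(out$count_table, "h_blood_out"),
                          h_plasma_out = attr(out$count_table, "h_plasma_out"),
                          q_in = attr(out$count_table, "q_in"),
                          q_blood_out = attr(out$count_table, "q_blood_out"),
                          q_plasma_out = attr(out$count_table, "q_plasma_out"))
  report <- suppressWarnings(performance_report(mean_tab))
  list(config = config, population = pop, outcome = out, noisy = noisy,
       report = report)
}
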