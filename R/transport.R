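#' Branch entry probability at a junction (bifurcation law)
#'
#' Probability that a particle arriving at a junction enters the branch.
#' The baseline is the branch's share of the local flow (what a fluid
#' element experiences); cells are multiplied by a margination factor < 1
#' because they concentrate along the channel axis away from the skimming
#' region. The factor is `class_weight * exp(-d / d_ref)`, decreasing in
#' cell diameter (larger cells marginate more strongly toward the axis);
#' plasma tracers use factor 1.
#'
#' @param diameter_d Particle diameter in m.
#' @param lateral_class `"core"`, `"wall"`, or `"plasma"`.
#' @param flow_fraction Branch share of the local node flow, in (0, 1).
#' @param margination_d_ref Diameter scale of the margination factor in m
#'   (default 10 um).
#' @param class_weights Named weights for the two cell lateral classes.
#' @return Probability in \eqn{[0, 1]}, vectorized.
#' @export
branch_entry_probability <- function(diameter_d, lateral_class, flow_fraction,
                                     margination_d_ref = 10e-6,
                                     class_weights = c(core = 0.5, wall = 1.0)) {
  if (any(flow_fraction <= 0 | flow_fraction >= 1))
    stop("`flow_fraction` must be in (0, 1)")
  m <- ifelse(lateral_class == "plasma", 1,
              unname(class_weights[lateral_class]) *
                exp(-diameter_d / margination_d_ref))
  pmin(pmax(flow_fraction * m, 0), 1)
}

#' Near-wall capture rule
#'
#' A cell inside a branch is captured when it approaches the wall closer
#' than the capture distance and, at that separation, the adhesive force
#' exceeds the DEP repulsion. Deterministic given the approach distance and
#' the force context.
#'
#' @param diameter_d Cell diameter in m.
#' @param distance_h Cell-wall separation at the approach in m.
#' @param field A [field_model()] (drive voltage and electrode geometry).
#' @param adhesion An [adhesion_params()].
#' @param re_fcm Real part of the Clausius-Mossotti factor at the drive
#'   frequency.
#' @param h_capture Capture distance in m (default 10 nm).
#' @return Logical, vectorized over `distance_h`.
#' @export
capture_rule <- function(diameter_d, distance_h, field = field_model(),
                         adhesion = adhesion_params(), re_fcm = -0.5,
                         h_capture = 1e-8) {
  f_adh <- abs(adhesive_force(diameter_d, pmax(distance_h, 1e-15), adhesion))
  f_dep <- abs(dep_force_at(diameter_d, distance_h, field, re_fcm,
                            adhesion$eps_medium))
  distance_h < h_capture & f_adh > f_dep
}

#' Voltage-dependent lysis probability
#'
#' Electroporation-driven lysis: zero at or below the threshold voltage
#' (20 V in this device), above it an exponential-time hazard
#' p = 1 - exp(-rate * (V - V_thr) * t_exposure), increasing in both the
#' overvoltage and the exposure time (slower flow means longer exposure and
#' more severe lysis).
#'
#' @param voltage Drive amplitude in V (>= 0).
#' @param exposure_time Time the cell spends over the energized electrodes,
#'   in s.
#' @param rate Hazard coefficient in 1/(V s) (default 0.009).
#' @param threshold Lysis threshold voltage in V (default 20).
#' @return Probability in \eqn{[0, 1]}.
#' @export
lysis_probability <- function(voltage, exposure_time, rate = 0.009,
                              threshold = 20) {
  if (any(voltage < 0)) stop("`voltage` must be nonnegative")
  1 - exp(-rate * pmax(voltage - threshold, 0) * exposure_time)
}

#' @rdname lysis_probability
#' @param n Number of cells to draw for.
#' @return `lysis_rule()`: logical vector of length `n` (seed-driven draw
#'   from the ambient RNG stream).
#' @export
lysis_rule <- function(voltage, exposure_time, n = 1L, rate = 0.009,
                       threshold = 20) {
  p <- lysis_probability(voltage, exposure_time, rate, threshold)
  stats::runif(n) < p
}

#' Fresh branch state
#'
#' @param width Nominal branch width in m.
#' @return An object of class `branch_state`: effective width, capture
#'   multiplier (aggregation acceleration), capture tally, clog flag/time.
#' @export
new_branch_state <- function(width) {
  stopifnot(width > 0)
  structure(list(effective_width = width, capture_multiplier = 1,
                 captured_cells = 0L, captured_diameter_sum = 0,
                 clogged = FALSE, clog_time = NA_real_),
            class = "branch_state")
}

#' Update a branch state after a capture
#'
#' A captured cell narrows the branch by a fraction of its diameter, and
#' accelerates subsequent captures in that branch (cell-to-cell aggregation)
#' by multiplying the capture multiplier. The branch is marked clogged once
#' the effective width falls below the smallest simulated cell diameter -
#' nothing cellular can pass any more.
#'
#' @param branch A [new_branch_state()] object (not yet clogged).
#' @param captured_diameter Diameter of the captured cell in m.
#' @param clog_fraction Fraction of the captured diameter removed from the
#'   effective width (default 1: a stuck cell obstructs its full diameter).
#' @param aggregation_factor Multiplier (> 1) applied to the branch capture
#'   multiplier per capture (default 3).
#' @param min_cell_diameter Smallest simulated cell diameter in m; the clog
#'   criterion.
#' @param time Simulation time to record as `clog_time` if this capture
#'   clogs the branch.
#' @return Updated `branch_state`.
#' @export
clog_update <- function(branch, captured_diameter, clog_fraction = 1,
                        aggregation_factor = 3, min_cell_diameter = 2e-6,
                        time = NA_real_) {
  stopifnot(inherits(branch, "branch_state"))
  if (branch$clogged) stop("cannot update a clogged branch")
  stopifnot(captured_diameter > 0, clog_fraction > 0, aggregation_factor >= 1)
  branch$effective_width <- max(branch$effective_width -
                                  clog_fraction * captured_diameter, 0)
  branch$capture_multiplier <- branch$capture_multiplier * aggregation_factor
  branch$captured_cells <- branch$captured_cells + 1L
  branch$captured_diameter_sum <- branch$captured_diameter_sum + captured_diameter
  if (branch$effective_width < min_cell_diameter) {
    branch$clogged <- TRUE
    branch$clog_time <- time
  }
  branch
}

#' nDEP deflection probability at a branch mouth
#'
#' The energized electrodes sit at the branch entrances, so a cell headed
#' into a branch must cross the DEP barrier there. The deflection
#' probability is modeled as r / (1 + r) with r = |F_DEP| at the
#' characteristic approach height (half the branch width) divided by the
#' Stokes drag carrying the cell into the branch at the mean branch
#' velocity. Large cells at full drive are deflected almost surely; at zero
#' voltage nothing is deflected.
#'
#' @param diameter_d Cell diameter in m.
#' @param field A [field_model()].
#' @param re_fcm Real part of the Clausius-Mossotti factor.
#' @param network A [channel_network()].
#' @param branch_velocity Mean branch velocity in m/s; defaults to the
#'   unfouled network value.
#' @return Probability in \eqn{[0, 1]}, vectorized over `diameter_d`.
#' @export
dep_deflection_probability <- function(diameter_d, field, re_fcm, network,
                                       branch_velocity = NULL) {
  stopifnot(inherits(network, "channel_network"))
  if (is.null(branch_velocity)) {
    fs <- flow_split(network)
    branch_velocity <- mean(fs$branch_flows) /
      (network$branch_width * network$depth)
  }
  h_gate <- network$branch_width / 2
  f_dep <- abs(dep_force_at(diameter_d, h_gate, field, re_fcm))
  f_drag <- 6 * pi * network$fluid_viscosity * (diameter_d / 2) * branch_velocity
  r <- f_dep / f_drag
  r / (1 + r)
}

#' Simulation control parameters
#'
#' Tunables of the stochastic transport/capture model, all in SI units.
#'
#' @param h_capture Capture distance in m (default 10 nm).
#' @param approach_window The near-wall approach distance inside a branch is
#'   drawn uniformly on (0, `approach_window * h_capture /` capture
#'   multiplier); default 10.
#' @param clog_fraction See [clog_update()].
#' @param aggregation_factor See [clog_update()].
#' @param margination_d_ref,class_weights See [branch_entry_probability()].
#' @param attach_rate Scale of mouth aggregation: once a branch holds a
#'   captured aggregate, a cell passing the junction in the main channel
#'   attaches to it with probability `attach_rate` times the in-branch
#'   capture probability (default 0.002 - the aggregate occupies a small
#'   fraction of the main-channel cross-section). This is what lets a
#'   nearly clogged branch finish clogging even though its through-flow has
#'   collapsed; nDEP suppresses it the same way it suppresses capture.
#' @param debris_diameter Diameter assigned to lysed-cell debris in m
#'   (default 0.5 um, below the DEP protection threshold).
#' @param lysis_rate,lysis_threshold See [lysis_probability()].
#' @param time_compression Device seconds represented by one simulated
#'   second (bookkeeping only; default 60, i.e. one simulated minute per
#'   device hour).
#' @param checkpoint_every Record the branch-state time series every this
#'   many timesteps (default 10).
#' @return A list of class `sim_control`.
#' @export
sim_control <- function(h_capture = 1e-8, approach_window = 10,
                        clog_fraction = 1, aggregation_factor = 3,
                        margination_d_ref = 10e-6,
                        class_weights = c(core = 0.5, wall = 1.0),
                        attach_rate = 0.002,
                        debris_diameter = 0.5e-6,
                        lysis_rate = 0.009, lysis_threshold = 20,
                        time_compression = 60, checkpoint_every = 10L) {
  stopifnot(h_capture > 0, approach_window > 0, clog_fraction > 0,
            aggregation_factor >= 1, attach_rate >= 0,
            debris_diameter > 0, lysis_rate >= 0)
  structure(list(h_capture = h_capture, approach_window = approach_window,
                 clog_fraction = clog_fraction,
                 aggregation_factor = aggregation_factor,
                 margination_d_ref = margination_d_ref,
                 class_weights = class_weights,
                 attach_rate = attach_rate,
                 debris_diameter = debris_diameter,
                 lysis_rate = lysis_rate, lysis_threshold = lysis_threshold,
                 time_compression = time_compression,
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "sim_control")
}

#' Stochastic simulation of blood plasma separation with DEP anti-clogging
#'
#' Event-driven, time-stepped Lagrangian transport of a synthetic cell
#' population through the bifurcating network. Each cell is advected along
#' the main channel, may be lysed by overvoltage (becoming sub-micron
#' debris that re-enters transport), draws a branch entry at each junction
#' (bifurcation law with margination and an nDEP gate at the branch mouth),
#' and inside a branch may be captured near the wall when adhesion beats
#' the DEP repulsion. Captures narrow the branch, accelerate subsequent
#' captures (aggregation), and eventually clog it; flow redistributes over
#' the remaining open branches after every capture.
#'
#' @param population A [generate_population()] result.
#' @param network A [channel_network()].
#' @param voltage Drive amplitude in V (default 20).
#' @param frequency Drive frequency in Hz (default 1 kHz).
#' @param duration Simulated duration in s (scaled time; default 60).
#' @param dt Timestep in s (default 0.25).
#' @param seed Integer RNG seed (mandatory).
#' @param adhesion An [adhesion_params()].
#' @param field Optional [field_model()]; defaults to one built from
#'   `voltage`/`frequency` with the default electrode geometry.
#' @param control A [sim_control()].
#' @return An object of class `separation_outcome`: list with
#'   \describe{
#'     \item{counts}{per-species fate matrix (inlet, blood_out, plasma_out,
#'       captured, lysed) including a `debris` row for lysed-cell fragments}
#'     \item{cells}{per-cell record with final `fate`}
#'     \item{branches}{per-branch final state data.frame}
#'     \item{all_clogged_time}{time at which the last branch clogged
#'       (`NA` if the device stayed open)}
#'     \item{plasma_volume_ul}{plasma volume recovered}
#'     \item{plasma_share_mean}{time-averaged branch flow share}
#'     \item{timeseries}{checkpoint data.frame (time, clogged count, shares,
#'       cumulative fates)}
#'     \item{count_table}{derived [count_table()] for the metrics stage}
#'   }
#' @examples
#' pop <- generate_population(25, volume_ul = 0.0005, seed = 7)
#' out <- simulate_separation(pop, voltage = 20, duration = 10, seed = 7)
#' out$counts
#' @export
simulate_separation <- function(population, network = channel_network(),
                                voltage = 20, frequency = 1e3,
                                duration = 60, dt = 0.25, seed,
                                adhesion = adhesion_params(),
                                field = NULL, control = sim_control()) {
  stopifnot(inherits(population, "cell_population"),
            inherits(network, "channel_network"),
            inherits(control, "sim_control"))
  if (missing(seed)) stop("`seed` is required (reproducibility contract)")
  if (!(duration > 0) || !(dt > 0)) stop("`duration` and `dt` must be positive")
  if (voltage < 0) stop("`voltage` must be nonnegative")
  if (is.null(field))
    field <- field_model(voltage_amplitude = voltage, frequency = frequency)

  set.seed(as.integer(seed))
  n0 <- nrow(population)
  species0 <- unique(default_species()$species)
  species_levels <- union(unique(population$species), c(species0, "debris"))

  re_fcm <- Re(clausius_mossotti(
    complex_permittivity(blood_cell_material(), frequency),
    complex_permittivity(blood_plasma(), frequency)))

  # physical residence time over the electrodes (scales with 1/flow rate)
  exposure <- main_channel_volume(network) / network$inlet_flow

  # lysis happens on entry; lysed cells spawn debris that re-enters transport
  lysed0 <- lysis_rule(voltage, exposure, n = n0,
                       rate = control$lysis_rate,
                       threshold = control$lysis_threshold)
  arrivals0 <- sort(stats::runif(n0, 0, duration))

  cells <- data.frame(
    species = c(population$species,
                rep("debris", sum(lysed0))),
    diameter = c(population$diameter,
                 rep(control$debris_diameter, sum(lysed0))),
    lateral = c(population$lateral, population$lateral[lysed0]),
    arrival = c(arrivals0, arrivals0[lysed0]),
    transported = c(!lysed0, rep(TRUE, sum(lysed0))),
    fate = ifelse(c(lysed0, rep(FALSE, sum(lysed0))), "lysed", "transit"),
    stringsAsFactors = FALSE)

  min_cell_d <- if (n0 > 0) min(population$diameter) else Inf
  nb <- network$n_branches
  ns <- nb %/% 2L
  branches <- lapply(seq_len(nb),
                     function(i) new_branch_state(network$branch_width))
  widths <- rep(network$branch_width, nb)
  split <- flow_split(network, widths)
  v_branch0 <- mean(split$branch_flows) / (network$branch_width * network$depth)

  # per-cell static factors
  marg <- ifelse(cells$lateral == "plasma", 1,
                 unname(control$class_weights[cells$lateral]) *
                   exp(-cells$diameter / control$margination_d_ref))
  p_pass_gate <- 1 - dep_deflection_probability(cells$diameter, field, re_fcm,
                                                network, v_branch0)

  # adhesion-dominance height per cell (cached per nm of diameter): the
  # separation below which F_adh beats |F_DEP|, i.e. the capture window
  if (voltage == 0) {
    hx_all <- rep(control$h_capture, nrow(cells))
  } else {
    hx_cache <- new.env(parent = emptyenv())
    hx_all <- vapply(cells$diameter, function(d) {
      key <- sprintf("%.0f", d * 1e9)
      got <- hx_cache[[key]]
      if (is.null(got)) {
        got <- adhesion_dominance_height(d, field, adhesion, re_fcm,
                                         upper = control$h_capture)
        hx_cache[[key]] <- got
      }
      got
    }, numeric(1L))
  }

  vol_ul <- attr(population, "volume_ul")
  steps <- ceiling(duration / dt)
  plasma_vol_ul <- 0
  share_sum <- 0
  ts <- vector("list", steps %/% control$checkpoint_every + 1L)
  ts_i <- 0L
  all_clogged_time <- NA_real_
  cum_captured <- 0L

  for (s in seq_len(steps)) {
    t0 <- (s - 1L) * dt; t1 <- min(s * dt, duration)
    idx <- which(cells$fate == "transit" &
                   cells$arrival >= t0 & cells$arrival < t1 + (s == steps) * 1e-9)
    changed <- FALSE
    if (length(idx) > 0L) {
      in_main <- rep(TRUE, length(idx))
      phi <- split$station_local_fractions
      register_capture <- function(b, ci) {
        branches[[b]] <<- clog_update(branches[[b]], cells$diameter[ci],
                                      control$clog_fraction,
                                      control$aggregation_factor,
                                      min_cell_d, time = t1)
        widths[b] <<- if (branches[[b]]$clogged) 0
                      else branches[[b]]$effective_width
        cells$fate[ci] <<- "captured"
        cum_captured <<- cum_captured + 1L
        changed <<- TRUE
      }
      for (j in seq_len(ns)) {
        if (!any(in_main)) break
        i1 <- 2L * j - 1L; i2 <- 2L * j
        if (phi[j] > 0) {
          p <- pmin(phi[j] * marg[idx] * p_pass_gate[idx], 1)
          u <- stats::runif(length(idx))
          enter <- in_main & u < p
          if (any(enter)) {
            q1 <- split$branch_flows[i1]; q2 <- split$branch_flows[i2]
            side2 <- stats::runif(sum(enter)) < q2 / (q1 + q2)
            br <- ifelse(side2, i2, i1)
            ent <- idx[enter]
            for (k in seq_along(ent)) {
              b <- br[k]
              if (branches[[b]]$clogged) next  # clogged since split: stay in main
              ci <- ent[k]
              d <- cells$diameter[ci]
              in_main[match(ci, idx)] <- FALSE
              if (d >= branches[[b]]$effective_width) {
                captured <- TRUE            # sieving: cannot pass the neck
              } else {
                win <- control$approach_window * control$h_capture /
                  branches[[b]]$capture_multiplier
                h <- stats::runif(1, 0, win)
                captured <- h < min(control$h_capture, hx_all[ci])
              }
              if (captured) register_capture(b, ci)
              else cells$fate[ci] <- "plasma_out"
            }
          }
        }
        # cell-to-cell aggregation at the branch mouth: a seeded aggregate
        # grabs passing main-channel cells even when the branch throughput
        # has collapsed; nDEP suppresses it through the same force window
        if (control$attach_rate > 0) {
          for (b in c(i1, i2)) {
            st <- branches[[b]]
            if (st$clogged || st$captured_cells == 0L) next
            pas <- which(in_main)
            if (length(pas) == 0L) break
            ci <- idx[pas]
            p_inner <- pmin(1, pmin(control$h_capture, hx_all[ci]) *
                              st$capture_multiplier /
                              (control$approach_window * control$h_capture))
            u2 <- stats::runif(length(pas))
            att <- which(u2 < control$attach_rate * p_inner)
            for (k in att) {
              if (branches[[b]]$clogged) break
              register_capture(b, ci[k])
              in_main[pas[k]] <- FALSE
            }
          }
        }
      }
      cells$fate[idx[in_main]] <- "blood_out"
    }
    plasma_vol_ul <- plasma_vol_ul + split$plasma_share * vol_ul * (t1 - t0) / duration
    share_sum <- share_sum + split$plasma_share
    if (changed) {
      split <- flow_split(network, widths)
      if (is.na(all_clogged_time) && all(vapply(branches, `[[`, TRUE, "clogged")))
        all_clogged_time <- t1
    }
    if (s %% control$checkpoint_every == 0L || s == steps) {
      ts_i <- ts_i + 1L
      ts[[ts_i]] <- data.frame(
        time = t1,
        n_clogged = sum(vapply(branches, `[[`, TRUE, "clogged")),
        plasma_share = split$plasma_share,
        captured = cum_captured,
        lysed = sum(cells$fate == "lysed"),
        blood_out = sum(cells$fate == "blood_out"),
        plasma_out = sum(cells$fate == "plasma_out"))
    }
  }
  timeseries <- do.call(rbind, ts[seq_len(ts_i)])

  # any cell never processed (shouldn't happen) exits at the blood outlet
  cells$fate[cells$fate == "transit"] <- "blood_out"

  fates <- c("blood_out", "plasma_out", "captured", "lysed")
  counts <- t(vapply(species_levels, function(sp) {
    sel <- cells$species == sp
    vapply(fates, function(f) sum(sel & cells$fate == f), 0L)
  }, integer(length(fates))))
  inlet <- vapply(species_levels, function(sp) {
    if (sp == "debris") sum(cells$species == "debris")
    else sum(population$species == sp)
  }, 0L)
  counts <- cbind(inlet = inlet, counts)

  blood_vol_ul <- vol_ul - plasma_vol_ul
  conc <- function(cnt, v) if (v > 0) cnt / v else 0
  rbc_mean_vol <- mean(sphere_volume(
    cells$diameter[cells$species == "RBC"]))
  hct <- function(n_rbc, v_ul) {
    if (v_ul <= 0) return(NA_real_)
    min(100 * n_rbc * rbc_mean_vol / (v_ul * 1e-9), 100)
  }
  sp_main <- setdiff(species_levels, "debris")
  tab <- count_table(
    species = sp_main,
    c_in = vapply(sp_main, function(sp) conc(counts[sp, "inlet"], vol_ul), 0),
    c_blood_out = vapply(sp_main, function(sp)
      conc(counts[sp, "blood_out"], blood_vol_ul), 0),
    c_plasma_out = vapply(sp_main, function(sp)
      conc(counts[sp, "plasma_out"], plasma_vol_ul), 0),
    h_in = attr(population, "haematocrit_pct"),
    h_blood_out = hct(counts["RBC", "blood_out"], blood_vol_ul),
    h_plasma_out = hct(counts["RBC", "plasma_out"], plasma_vol_ul),
    q_in = 1, q_blood_out = 1 - share_sum / steps,
    q_plasma_out = share_sum / steps)

  branch_df <- data.frame(
    branch = seq_len(nb),
    effective_width = vapply(branches, `[[`, 0, "effective_width"),
    captured_cells = vapply(branches, `[[`, 0L, "captured_cells"),
    clogged = vapply(branches, `[[`, TRUE, "clogged"),
    clog_time = vapply(branches, `[[`, 0, "clog_time"))

  structure(list(counts = counts, cells = cells, branches = branch_df,
                 all_clogged_time = all_clogged_time,
                 plasma_volume_ul = plasma_vol_ul,
                 plasma_share_mean = share_sum / steps,
                 timeseries = timeseries, count_table = tab,
                 voltage = voltage, frequency = frequency,
                 duration = duration, dt = dt, seed = as.integer(seed),
                 control = control),
            class = "separation_outcome")
}

#' @export
print.separation_outcome <- function(x, ...) {
  cat(sprintf("<separation_outcome> V = %g V, %g s simulated, seed %d\n",
              x$voltage, x$duration, x$seed))
  print(x$counts)
  cat(sprintf("clogged branches: %d/%d%s; plasma share (mean): %.3f\n",
              sum(x$branches$clogged), nrow(x$branches),
              if (is.na(x$all_clogged_time)) ""
              else sprintf(" (all clogged at t = %g s)", x$all_clogged_time),
              x$plasma_share_mean))
  invisible(x)
}

#' Per-species conservation check
#'
#' Verifies the exact accounting identity inlet = blood_out + plasma_out +
#' captured + lysed for every species of an outcome.
#'
#' @param outcome A [simulate_separation()] result.
#' @return Logical scalar.
#' @export
conservation_holds <- function(outcome) {
  stopifnot(inherits(outcome, "separation_outcome"))
  all(outcome$counts[, "inlet"] ==
        rowSums(outcome$counts[, c("blood_out", "plasma_out",
                                   "captured", "lysed")]))
}
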