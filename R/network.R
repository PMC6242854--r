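#' Bifurcating separation channel network
#'
#' Geometry and operating parameters of the plasma-skimming network: a main
#' channel with paired narrow side branches (25 junction stations, two
#' branches each by default) that drain plasma to a common outlet, and a
#' tail segment leading to the blood outlet.
#'
#' @param main_width Main channel width in m (default 100 um).
#' @param depth Channel depth in m (default 80 um).
#' @param branch_width Branch channel width in m (default 15 um).
#' @param n_branches Number of branch channels, even (default 50, i.e. 25
#'   per side).
#' @param branch_length Branch channel length in m (default 5 mm).
#' @param main_segment_length Main-channel length between junction stations
#'   in m (default 200 um).
#' @param outlet_length Tail length from the last junction to the blood
#'   outlet in m (default 2 mm).
#' @param inlet_flow Inlet volumetric flow in m^3/s (default 1 ul/min).
#' @param fluid_viscosity Dynamic viscosity in Pa s (default 1.2e-3,
#'   PBS-diluted blood).
#' @return An object of class `channel_network`.
#' @export
channel_network <- function(main_width = 100e-6, depth = 80e-6,
                            branch_width = 15e-6, n_branches = 50L,
                            branch_length = 5e-3,
                            main_segment_length = 200e-6,
                            outlet_length = 2e-3,
                            inlet_flow = 1e-9 / 60,
                            fluid_viscosity = 1.2e-3) {
  stopifnot(main_width > 0, depth > 0, branch_width > 0, branch_length > 0,
            main_segment_length > 0, outlet_length > 0, inlet_flow > 0,
            fluid_viscosity > 0)
  n_branches <- as.integer(n_branches)
  if (n_branches < 2L || n_branches %% 2L != 0L)
    stop("`n_branches` must be a positive even integer (paired sides)")
  if (branch_width >= main_width)
    stop("`branch_width` must be smaller than `main_width`")
  structure(list(main_width = main_width, depth = depth,
                 branch_width = branch_width, n_branches = n_branches,
                 branch_length = branch_length,
                 main_segment_length = main_segment_length,
                 outlet_length = outlet_length, inlet_flow = inlet_flow,
                 fluid_viscosity = fluid_viscosity),
            class = "channel_network")
}

#' Hydraulic resistance of a rectangular duct
#'
#' Lumped Hagen-Poiseuille resistance with the standard wide-duct
#' aspect-ratio correction: R = 12 mu L / (a^3 b (1 - 0.63 a/b)), where a is
#' the shorter and b the longer cross-section side.
#'
#' @param length Duct length in m.
#' @param width,depth Cross-section sides in m.
#' @param viscosity Dynamic viscosity in Pa s.
#' @return Resistance in Pa s / m^3.
#' @export
duct_resistance <- function(length, width, depth, viscosity = 1.2e-3) {
  stopifnot(length > 0, width > 0, depth > 0, viscosity > 0)
  a <- pmin(width, depth); b <- pmax(width, depth)
  12 * viscosity * length / (a^3 * b * (1 - 0.63 * a / b))
}

#' Flow split across the branch network
#'
#' Solves the lumped hydraulic ladder: at each junction station the incoming
#' flow divides between the two local branches and the downstream equivalent
#' resistance, in proportion to conductance. Volume is conserved exactly by
#' construction. Branch conductances scale with the cube of the (possibly
#' fouling-reduced) effective width; a clogged branch (effective width 0)
#' carries no flow.
#'
#' @param network A [channel_network()].
#' @param effective_widths Optional per-branch effective widths in m
#'   (defaults to the nominal branch width); length `n_branches`.
#' @return List with `branch_flows` (m^3/s, per branch), `outlet_flow`
#'   (blood outlet, m^3/s), `branch_fractions` (branch flow / inlet flow),
#'   `station_local_fractions` (share of the local node flow entering the
#'   branch pair at each station), and `plasma_share` (total branch flow /
#'   inlet flow).
#' @export
flow_split <- function(network, effective_widths = NULL) {
  stopifnot(inherits(network, "channel_network"))
  n <- network$n_branches
  if (is.null(effective_widths)) effective_widths <- rep(network$branch_width, n)
  stopifnot(length(effective_widths) == n)
  effective_widths <- pmin(pmax(effective_widths, 0), network$branch_width)
  mu <- network$fluid_viscosity
  ns <- n %/% 2L

  # branch conductances; width^3 scaling through duct_resistance
  g_branch <- numeric(n)
  open <- effective_widths > 0
  g_branch[open] <- 1 / vapply(effective_widths[open], function(w)
    duct_resistance(network$branch_length, w, network$depth, mu), numeric(1L))
  r_seg <- duct_resistance(network$main_segment_length, network$main_width,
                           network$depth, mu)
  r_tail <- duct_resistance(network$outlet_length, network$main_width,
                            network$depth, mu)

  # downstream equivalent resistance seen at each station (backward pass)
  g_pair <- g_branch[seq(1L, n, by = 2L)] + g_branch[seq(2L, n, by = 2L)]
  r_eq <- numeric(ns + 1L)
  r_eq[ns + 1L] <- r_tail
  for (j in ns:1L) {
    g_down <- 1 / (r_seg + r_eq[j + 1L])
    r_eq[j] <- 1 / (g_pair[j] + g_down)
  }

  # forward pass: proportional split conserves volume exactly
  q <- network$inlet_flow
  branch_flows <- numeric(n)
  local_frac <- numeric(ns)
  for (j in seq_len(ns)) {
    g_down <- 1 / (r_seg + r_eq[j + 1L])
    tot <- g_pair[j] + g_down
    fb <- if (tot > 0) g_pair[j] / tot else 0
    local_frac[j] <- fb
    q_pair <- q * fb
    i1 <- 2L * j - 1L; i2 <- 2L * j
    gp <- g_branch[i1] + g_branch[i2]
    if (gp > 0) {
      branch_flows[i1] <- q_pair * g_branch[i1] / gp
      branch_flows[i2] <- q_pair * g_branch[i2] / gp
    }
    q <- q - q_pair
  }
  list(branch_flows = branch_flows,
       outlet_flow = q,
       branch_fractions = branch_flows / network$inlet_flow,
       station_local_fractions = local_frac,
       plasma_share = sum(branch_flows) / network$inlet_flow)
}

# Wetted main-channel volume (junction run + tail), used for residence time.
main_channel_volume <- function(network) {
  (network$n_branches / 2L * network$main_segment_length +
     network$outlet_length) * network$main_width * network$depth
}
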