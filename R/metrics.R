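#' Inlet/outlet count table for a separation run
#'
#' Per-species cell concentrations at the device inlet, blood outlet and
#' plasma outlet, plus the three haematocrit levels. The concentrations feed
#' the cell-loss and purity statistics; the haematocrits feed the plasma
#' yield.
#'
#' @param species Character vector of species labels (e.g. RBC, WBC, PLT).
#' @param c_in,c_blood_out,c_plasma_out Concentrations in cells/ul, one per
#'   species (>= 0).
#' @param h_in,h_blood_out,h_plasma_out Haematocrit percentages in
#'   \eqn{[0, 100]}.
#' @param q_in,q_blood_out,q_plasma_out Optional volumetric flow rates (any
#'   common unit) enabling the flow-weighted cell-loss variant.
#' @return An object of class `count_table` (a data.frame with haematocrit
#'   and flow attributes).
#' @export
count_table <- function(species, c_in, c_blood_out, c_plasma_out,
                        h_in = NA_real_, h_blood_out = NA_real_,
                        h_plasma_out = NA_real_,
                        q_in = NA_real_, q_blood_out = NA_real_,
                        q_plasma_out = NA_real_) {
  n <- length(species)
  stopifnot(length(c_in) == n, length(c_blood_out) == n,
            length(c_plasma_out) == n)
  if (any(c(c_in, c_blood_out, c_plasma_out) < 0))
    stop("concentrations must be nonnegative")
  h <- c(h_in, h_blood_out, h_plasma_out)
  if (any(!is.na(h) & (h < 0 | h > 100)))
    stop("haematocrits must be in [0, 100]")
  structure(
    data.frame(species = as.character(species), c_in = c_in,
               c_blood_out = c_blood_out, c_plasma_out = c_plasma_out,
               stringsAsFactors = FALSE),
    h_in = h_in, h_blood_out = h_blood_out, h_plasma_out = h_plasma_out,
    q_in = q_in, q_blood_out = q_blood_out, q_plasma_out = q_plasma_out,
    class = c("count_table", "data.frame"))
}

#' Cell loss percentage
#'
#' eta_L = (1 - (C_o + C_p) / C_i) * 100. Cells unaccounted for at either
#' outlet relative to the inlet; near zero when nothing adheres inside the
#' device. The flow-weighted variant uses cell fluxes C*Q instead of bare
#' concentrations, which removes the volume-split artefact when outlet flow
#' rates differ.
#'
#' @param c_in Inlet concentration (> 0).
#' @param c_blood_out,c_plasma_out Outlet concentrations (>= 0).
#' @param flows Optional numeric `c(q_in, q_blood_out, q_plasma_out)`
#'   enabling the flow-weighted variant.
#' @return Percentage (may fall outside \eqn{[0, 100]} for noisy data; values
#'   are reported, not clipped).
#' @examples
#' cell_loss(100, 50, 12)   # 38
#' @export
cell_loss <- function(c_in, c_blood_out, c_plasma_out, flows = NULL) {
  if (any(c_in <= 0)) stop("`c_in` must be positive")
  if (is.null(flows)) {
    (1 - (c_blood_out + c_plasma_out) / c_in) * 100
  } else {
    stopifnot(length(flows) == 3L, flows[1L] > 0)
    (1 - (c_blood_out * flows[2L] + c_plasma_out * flows[3L]) /
       (c_in * flows[1L])) * 100
  }
}

#' Purity efficiency percentage
#'
#' E_p = (1 - C_p / C_i) * 100: the fractional reduction of cell
#' concentration in the extracted plasma relative to the inlet; 100% means
#' cell-free plasma.
#'
#' @inheritParams cell_loss
#' @param c_plasma_out Plasma-outlet concentration (>= 0).
#' @return Percentage.
#' @examples
#' purity_efficiency(5e6, 1.4e5)   # 97.2
#' @export
purity_efficiency <- function(c_in, c_plasma_out) {
  if (any(c_in <= 0)) stop("`c_in` must be positive")
  (1 - c_plasma_out / c_in) * 100
}

#' Plasma yield percentage from haematocrit levels
#'
#' eta = 100 (100 - H_p)(H_o - H_i) / \[(100 - H_i)(H_o - H_p)\]: the
#' fraction of inlet plasma recovered at the plasma outlet, inferred from
#' the inlet, blood-outlet and plasma-outlet haematocrits via an RBC volume
#' balance.
#'
#' @param h_in,h_blood_out,h_plasma_out Haematocrit percentages; requires
#'   `h_in < 100` and `h_blood_out != h_plasma_out`.
#' @return Percentage.
#' @examples
#' plasma_yield(25, 45, 0)   # about 59.3
#' @export
plasma_yield <- function(h_in, h_blood_out, h_plasma_out) {
  if (any(h_in >= 100)) stop("`h_in` must be < 100")
  if (any(h_blood_out == h_plasma_out))
    stop("degenerate input: h_blood_out == h_plasma_out (no separation)")
  100 * (100 - h_plasma_out) * (h_blood_out - h_in) /
    ((100 - h_in) * (h_blood_out - h_plasma_out))
}

#' Per-species and aggregate performance report
#'
#' Applies [cell_loss()] and [purity_efficiency()] per species plus an
#' all-cells aggregate (summed concentrations), and [plasma_yield()] from
#' the table's haematocrits when present. Values outside \eqn{[0, 100]}
#' (possible with noisy counts) are reported unchanged and flagged.
#'
#' @param table A [count_table()].
#' @param flow_weighted Use the flow-weighted cell-loss variant (requires
#'   flow attributes on the table).
#' @return An object of class `performance_report`: data.frame with one row
#'   per species plus `"all"`, columns `cell_loss_pct`,
#'   `purity_efficiency_pct`, `out_of_range`; attribute `plasma_yield_pct`.
#' @export
performance_report <- function(table, flow_weighted = FALSE) {
  stopifnot(inherits(table, "count_table"))
  flows <- NULL
  if (flow_weighted) {
    flows <- c(attr(table, "q_in"), attr(table, "q_blood_out"),
               attr(table, "q_plasma_out"))
    if (any(is.na(flows)))
      stop("flow-weighted report requires flow attributes on the count table")
  }
  agg <- data.frame(species = "all",
                    c_in = sum(table$c_in),
                    c_blood_out = sum(table$c_blood_out),
                    c_plasma_out = sum(table$c_plasma_out))
  tab <- rbind(table[, c("species", "c_in", "c_blood_out", "c_plasma_out")], agg)
  loss <- cell_loss(tab$c_in, tab$c_blood_out, tab$c_plasma_out, flows)
  pur <- purity_efficiency(tab$c_in, tab$c_plasma_out)
  eps <- 1e-9  # ignore floating-point dust around the boundaries
  out_of_range <- loss < -eps | loss > 100 + eps | pur < -eps | pur > 100 + eps
  if (any(out_of_range))
    warning("some statistics fall outside [0, 100]; reported unchanged ",
            "(possible measurement noise: C_o + C_p > C_i)")
  hy <- c(attr(table, "h_in"), attr(table, "h_blood_out"),
          attr(table, "h_plasma_out"))
  yield <- if (any(is.na(hy)) || hy[2L] == hy[3L]) NA_real_
           else plasma_yield(hy[1L], hy[2L], hy[3L])
  structure(
    data.frame(species = tab$species, cell_loss_pct = loss,
               purity_efficiency_pct = pur, out_of_range = out_of_range,
               stringsAsFactors = FALSE),
    plasma_yield_pct = yield, flow_weighted = flow_weighted,
    class = c("performance_report", "data.frame"))
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report>",
      if (isTRUE(attr(x, "flow_weighted"))) "(flow-weighted cell loss)", "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  py <- attr(x, "plasma_yield_pct")
  cat(sprintf("plasma yield: %s\n",
              if (is.na(py)) "n/a (haematocrits not set)" else sprintf("%.2f%%", py)))
  invisible(x)
}
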