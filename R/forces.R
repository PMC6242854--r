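#' DLVO adhesion parameters for a cell near a channel wall
#'
#' Parameter set for the long-range cell/wall interaction: van der Waals
#' attraction scaled by the Hamaker constant, and the electrostatic double
#' layer (EDL) interaction controlled by the Debye parameter and the two
#' surface zeta potentials. Defaults are for an RBC near a PDMS wall in
#' PBS-diluted blood.
#'
#' @param hamaker_A Hamaker constant in J (default 5 zJ = 5e-21 J).
#' @param debye_kappa Debye parameter in 1/m (default 0.159 nm^-1).
#' @param temperature_T Absolute temperature in K (default 296.15).
#' @param valency_z Valency of the symmetric electrolyte (default 1,
#'   PBS being dominated by monovalent ions).
#' @param zeta_particle Particle zeta potential in V (RBC default -10.8 mV).
#' @param zeta_wall Wall zeta potential in V (PDMS default -13.825 mV).
#' @param eps_medium Relative permittivity of the medium (default 78).
#' @return An object of class `adhesion_params`.
#' @export
adhesion_params <- function(hamaker_A = 5e-21,
                            debye_kappa = 0.159e9,
                            temperature_T = 296.15,
                            valency_z = 1L,
                            zeta_particle = -10.8e-3,
                            zeta_wall = -13.825e-3,
                            eps_medium = 78) {
  stopifnot(hamaker_A > 0, debye_kappa > 0, temperature_T > 0,
            valency_z >= 1, eps_medium > 0)
  structure(list(hamaker_A = hamaker_A, debye_kappa = debye_kappa,
                 temperature_T = temperature_T, valency_z = as.integer(valency_z),
                 zeta_particle = zeta_particle, zeta_wall = zeta_wall,
                 eps_medium = eps_medium),
            class = "adhesion_params")
}

#' Electrode drive and field-gradient model
#'
#' Geometry and drive of the coplanar interdigitated (IDT) electrode array
#' that generates the non-uniform field for DEP. Printed drive values (e.g.
#' "20 V") are treated as the sinusoid peak amplitude; set
#' `voltage_is_rms = TRUE` if the amplitude is already an rms value.
#'
#' @param voltage_amplitude Drive amplitude in V (>= 0).
#' @param frequency Drive frequency in Hz (default 1 kHz).
#' @param electrode_gap_g Gap between electrode fingers in m (default 5 um).
#' @param electrode_pitch_p Finger pitch (spatial period) in m (default 10 um).
#' @param gradient_scale_model Field-gradient law; currently
#'   `"idt_exponential"` (see [field_gradient()]).
#' @param voltage_is_rms Logical; is `voltage_amplitude` an rms value?
#' @return An object of class `field_model`.
#' @export
field_model <- function(voltage_amplitude = 20,
                        frequency = 1e3,
                        electrode_gap_g = 5e-6,
                        electrode_pitch_p = 10e-6,
                        gradient_scale_model = "idt_exponential",
                        voltage_is_rms = FALSE) {
  stopifnot(voltage_amplitude >= 0, frequency > 0,
            electrode_gap_g > 0, electrode_pitch_p > 0)
  gradient_scale_model <- match.arg(gradient_scale_model, "idt_exponential")
  structure(list(voltage_amplitude = voltage_amplitude, frequency = frequency,
                 electrode_gap_g = electrode_gap_g,
                 electrode_pitch_p = electrode_pitch_p,
                 gradient_scale_model = gradient_scale_model,
                 voltage_is_rms = voltage_is_rms),
            class = "field_model")
}

v_rms <- function(field) {
  if (field$voltage_is_rms) field$voltage_amplitude
  else field$voltage_amplitude / sqrt(2)
}

#' Double-layer interaction factor gamma = tanh(z e zeta / 4 kB T)
#'
#' Dimensionless surface factor entering the EDL force once per surface;
#' odd in zeta and bounded in (-1, 1).
#'
#' @param zeta Surface zeta potential in V.
#' @param valency_z Electrolyte valency.
#' @param temperature_T Absolute temperature in K (> 0).
#' @return Dimensionless gamma, vectorized over `zeta`.
#' @examples
#' gamma_factor(-10.8e-3)   # RBC in PBS at 296 K, about -0.105
#' @export
gamma_factor <- function(zeta, valency_z = 1L, temperature_T = 296.15) {
  if (any(temperature_T <= 0)) stop("`temperature_T` must be positive")
  tanh(valency_z * phys_const[["e"]] * zeta /
         (4 * phys_const[["k_B"]] * temperature_T))
}

#' Van der Waals force between a sphere and a flat wall
#'
#' F_v = A d / (12 h^2), attractive, singular at contact. Linear in the
#' particle diameter, inverse-square in the separation.
#'
#' @param diameter_d Particle diameter in m (> 0).
#' @param distance_h Particle-wall separation in m (> 0).
#' @param hamaker_A Hamaker constant in J.
#' @return Force magnitude in N (vectorized over `distance_h`).
#' @export
van_der_waals_force <- function(diameter_d, distance_h, hamaker_A = 5e-21) {
  if (any(diameter_d <= 0)) stop("`diameter_d` must be positive")
  if (any(distance_h <= 0)) stop("`distance_h` must be positive (F_v is singular at h = 0)")
  hamaker_A * diameter_d / (12 * distance_h^2)
}

#' Electrostatic double layer force between a sphere and a flat wall
#'
#' F_EDL = 32 pi eps_m eps0 kappa d gamma_p gamma_w exp(-kappa h) (kB T / e)^2.
#' Decays exponentially with decay constant kappa; vanishes when either
#' surface is uncharged.
#'
#' @param diameter_d Particle diameter in m (> 0).
#' @param distance_h Particle-wall separation in m (>= 0).
#' @param params An [adhesion_params()].
#' @return Force in N (sign follows the product of the two gamma factors;
#'   positive for like-signed zeta potentials), vectorized over `distance_h`.
#' @export
edl_force <- function(diameter_d, distance_h, params = adhesion_params()) {
  if (any(diameter_d <= 0)) stop("`diameter_d` must be positive")
  if (any(distance_h < 0)) stop("`distance_h` must be nonnegative")
  g_p <- gamma_factor(params$zeta_particle, params$valency_z, params$temperature_T)
  g_w <- gamma_factor(params$zeta_wall, params$valency_z, params$temperature_T)
  kT_e <- phys_const[["k_B"]] * params$temperature_T / phys_const[["e"]]
  32 * pi * params$eps_medium * phys_const[["eps0"]] * params$debye_kappa *
    diameter_d * g_p * g_w * exp(-params$debye_kappa * distance_h) * kT_e^2
}

#' Total adhesive force on a cell near the wall
#'
#' Combines the van der Waals and EDL terms. The `"literal-sum"` convention
#' (default) adds the two terms, F_adh = F_v + F_EDL; the `"signed"`
#' convention treats the EDL term as a repulsion and subtracts it,
#' F_adh = F_v - F_EDL.
#'
#' @inheritParams edl_force
#' @param distance_h Particle-wall separation in m (> 0).
#' @param convention `"literal-sum"` or `"signed"`.
#' @return Force in N, vectorized over `distance_h`.
#' @export
adhesive_force <- function(diameter_d, distance_h, params = adhesion_params(),
                           convention = c("literal-sum", "signed")) {
  convention <- match.arg(convention)
  fv <- van_der_waals_force(diameter_d, distance_h, params$hamaker_A)
  fe <- edl_force(diameter_d, distance_h, params)
  if (convention == "literal-sum") fv + fe else fv - fe
}

#' Field-gradient magnitude |grad(E_rms^2)| above an IDT array
#'
#' Characteristic-scale law for a periodic coplanar interdigitated array:
#' |grad(E_rms^2)|(h) = (V_rms/g)^2 * (4 pi / p) * exp(-4 pi h / p),
#' where g is the finger gap and p the pitch. Captures the correct
#' voltage-squared scaling and the exponential decay of the field
#' non-uniformity with height (decay length p / 4 pi).
#'
#' @param field A [field_model()].
#' @param height_h Height above the electrode plane in m (>= 0).
#' @return |grad(E_rms^2)| in V^2/m^3, vectorized over `height_h`.
#' @export
field_gradient <- function(field, height_h) {
  stopifnot(inherits(field, "field_model"))
  if (any(height_h < 0)) stop("`height_h` must be nonnegative")
  vr <- v_rms(field)
  (vr / field$electrode_gap_g)^2 * (4 * pi / field$electrode_pitch_p) *
    exp(-4 * pi * height_h / field$electrode_pitch_p)
}

#' Time-averaged DEP force on a spherical particle
#'
#' F_DEP = 2 pi r^3 eps_m eps0 Re(f_CM) |grad(E_rms^2)|. The sign follows
#' Re(f_CM): negative values (nDEP) give a force directed away from the
#' high-field electrode plane, i.e. a wall repulsion.
#'
#' @param radius_r Particle radius in m (> 0).
#' @param re_fcm Real part of the Clausius-Mossotti factor.
#' @param grad_e2 Field-gradient magnitude in V^2/m^3 (e.g. from
#'   [field_gradient()]).
#' @param eps_medium_rel Relative permittivity of the medium (default 78).
#' @return Signed force in N; vectorized.
#' @export
dep_force <- function(radius_r, re_fcm, grad_e2, eps_medium_rel = 78) {
  if (any(radius_r <= 0)) stop("`radius_r` must be positive")
  2 * pi * radius_r^3 * eps_medium_rel * phys_const[["eps0"]] * re_fcm * grad_e2
}

dep_force_at <- function(diameter_d, height_h, field, re_fcm,
                         eps_medium_rel = 78) {
  dep_force(diameter_d / 2, re_fcm, field_gradient(field, height_h),
            eps_medium_rel)
}

#' Adhesion / DEP force balance over a height grid
#'
#' Samples the adhesive force magnitude and the DEP force magnitude over a
#' grid of cell-wall separations, locates the crossover distance (where the
#' two magnitudes are equal, found by bisection to 1e-12 m), and reports
#' whether the cell is protected, i.e. |F_DEP| > F_adh at every sampled
#' height at or above a floor distance.
#'
#' @param diameter_d Cell diameter in m.
#' @param field A [field_model()].
#' @param adhesion An [adhesion_params()].
#' @param re_fcm Real part of the Clausius-Mossotti factor at the drive
#'   frequency.
#' @param h_grid Ascending positive vector of separations in m.
#' @param h_floor Protection floor distance in m (default 0.5 nm).
#' @param convention Adhesive-force convention, see [adhesive_force()].
#' @return An object of class `force_balance`: list with `h`, `f_adh`,
#'   `f_dep` (magnitudes, N), `crossover_h` (m or `NA_real_`), and
#'   `protected` (logical).
#' @export
force_balance <- function(diameter_d, field = field_model(),
                          adhesion = adhesion_params(), re_fcm = -0.5,
                          h_grid = 10^seq(log10(1e-11), log10(1e-7), length.out = 200),
                          h_floor = 0.5e-9,
                          convention = c("literal-sum", "signed")) {
  convention <- match.arg(convention)
  if (length(h_grid) < 1L) stop("`h_grid` must be non-empty")
  if (any(h_grid <= 0) || is.unsorted(h_grid, strictly = TRUE))
    stop("`h_grid` must be positive and strictly increasing")
  f_adh <- abs(adhesive_force(diameter_d, h_grid, adhesion, convention))
  f_dep <- abs(dep_force_at(diameter_d, h_grid, field, re_fcm,
                            adhesion$eps_medium))
  gap <- function(h) {
    abs(adhesive_force(diameter_d, h, adhesion, convention)) -
      abs(dep_force_at(diameter_d, h, field, re_fcm, adhesion$eps_medium))
  }
  d_grid <- f_adh - f_dep
  crossover <- NA_real_
  sgn <- sign(d_grid)
  flips <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  if (length(flips) > 0L) {
    i <- flips[1L]
    crossover <- stats::uniroot(gap, lower = h_grid[i], upper = h_grid[i + 1L],
                                tol = 1e-12)$root
  } else if (any(d_grid == 0)) {
    crossover <- h_grid[which(d_grid == 0)[1L]]
  }
  above <- h_grid >= h_floor
  protected <- any(above) && all(f_dep[above] > f_adh[above])
  structure(list(h = h_grid, f_adh = f_adh, f_dep = f_dep,
                 crossover_h = crossover, protected = protected,
                 diameter_d = diameter_d, h_floor = h_floor),
            class = "force_balance")
}

#' @export
print.force_balance <- function(x, ...) {
  cat(sprintf("<force_balance> d = %g um; crossover h = %s; protected (h >= %g nm): %s\n",
              x$diameter_d * 1e6,
              if (is.na(x$crossover_h)) "none" else sprintf("%.3g nm", x$crossover_h * 1e9),
              x$h_floor * 1e9, x$protected))
  invisible(x)
}

#' Smallest protected cell diameter
#'
#' The smallest diameter at which the DEP repulsion matches or exceeds the
#' adhesive force at a given evaluation height. Because the adhesive force
#' is linear in diameter while the DEP force is cubic, the threshold is
#' unique; it is located by bisection to 1e-9 m.
#'
#' @inheritParams force_balance
#' @param h_eval Evaluation height in m (> 0).
#' @param d_range Diameter search range in m.
#' @return Threshold diameter in m, or `NA_real_` (with a warning) when no
#'   threshold lies in `d_range` (e.g. zero field or Re(f_CM) = 0).
#' @export
protected_diameter_threshold <- function(field = field_model(),
                                         adhesion = adhesion_params(),
                                         re_fcm = -0.5, h_eval = 0.5e-9,
                                         d_range = c(1e-8, 1e-4),
                                         convention = c("literal-sum", "signed")) {
  convention <- match.arg(convention)
  if (h_eval <= 0) stop("`h_eval` must be positive")
  gap <- function(d) {
    abs(dep_force_at(d, h_eval, field, re_fcm, adhesion$eps_medium)) -
      abs(adhesive_force(d, h_eval, adhesion, convention))
  }
  lo <- gap(d_range[1L]); hi <- gap(d_range[2L])
  if (is.na(lo) || is.na(hi) || lo * hi > 0 || (lo == 0 && hi == 0)) {
    warning("no protected-diameter threshold in `d_range` (DEP never exceeds adhesion)")
    return(NA_real_)
  }
  stats::uniroot(gap, lower = d_range[1L], upper = d_range[2L], tol = 1e-9)$root
}

# Separation below which adhesion beats |F_DEP| for a given cell; equals
# `upper` when adhesion still dominates there (e.g. zero voltage).
adhesion_dominance_height <- function(diameter_d, field, adhesion, re_fcm,
                                      upper = 1e-8) {
  gap <- function(h) {
    abs(adhesive_force(diameter_d, h, adhesion)) -
      abs(dep_force_at(diameter_d, h, field, re_fcm, adhesion$eps_medium))
  }
  if (gap(upper) >= 0) return(upper)
  stats::uniroot(gap, lower = 1e-13, upper = upper, tol = 1e-13)$root
}
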