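#' Homogeneous dielectric material
#'
#' A dielectric phase (suspending medium, cytoplasm, membrane, ...) described
#' by its relative permittivity and DC conductivity. These two numbers fully
#' determine the complex permittivity at any drive frequency.
#'
#' @param epsilon_r Relative permittivity (dimensionless, > 0).
#' @param sigma Electrical conductivity in S/m (>= 0).
#' @param name Optional label used in printing.
#' @return An object of class `dielectric_material`.
#' @examples
#' blood_plasma()
#' dielectric_material(63, 1.0e-6, "blood cell")
#' @export
dielectric_material <- function(epsilon_r, sigma, name = NULL) {
  stopifnot(is.numeric(epsilon_r), length(epsilon_r) == 1L,
            is.numeric(sigma), length(sigma) == 1L)
  if (!is.finite(epsilon_r) || epsilon_r <= 0)
    stop("`epsilon_r` must be a positive finite number")
  if (!is.finite(sigma) || sigma < 0)
    stop("`sigma` must be a nonnegative finite number")
  structure(list(epsilon_r = epsilon_r, sigma = sigma, name = name),
            class = "dielectric_material")
}

#' @export
print.dielectric_material <- function(x, ...) {
  cat(sprintf("<dielectric_material%s> eps_r = %g, sigma = %g S/m\n",
              if (is.null(x$name)) "" else paste0(": ", x$name),
              x$epsilon_r, x$sigma))
  invisible(x)
}

#' Reference materials: blood plasma and a homogeneous blood cell
#'
#' Literature dielectric parameters for human blood plasma (relative
#' permittivity 78, conductivity 60 mS/m) and for a blood cell treated as a
#' homogeneous sphere (63, 1.0 uS/m). The very low effective cell
#' conductivity reflects the insulating membrane dominating the low-frequency
#' response; it is what makes blood cells experience negative DEP below
#' ~10 kHz in plasma.
#'
#' @return A `dielectric_material`.
#' @export
blood_plasma <- function() dielectric_material(78, 60e-3, "blood plasma")

#' @rdname blood_plasma
#' @export
blood_cell_material <- function() dielectric_material(63, 1.0e-6, "blood cell")

#' Complex permittivity of a material at a given frequency
#'
#' eps* = eps_r * eps0 - j * sigma / omega with omega = 2*pi*f. The real part
#' is the stored (capacitive) response, the (nonpositive) imaginary part the
#' conductive loss.
#'
#' @param material A [dielectric_material()].
#' @param frequency Drive frequency in Hz (> 0); may be a vector.
#' @return Complex permittivity in F/m, same length as `frequency`.
#' @examples
#' complex_permittivity(blood_plasma(), 1e3)
#' @export
complex_permittivity <- function(material, frequency) {
  stopifnot(inherits(material, "dielectric_material"))
  if (!is.numeric(frequency) || length(frequency) < 1L || any(frequency <= 0))
    stop("`frequency` must be positive (Hz)")
  omega <- 2 * pi * frequency
  complex(real = rep(material$epsilon_r * phys_const[["eps0"]], length(omega)),
          imaginary = -material$sigma / omega)
}

#' Clausius-Mossotti factor
#'
#' f_CM = (eps_p* - eps_m*) / (eps_p* + 2 eps_m*). Its real part sets the
#' sign and strength of the DEP force: positive values (up to 1.0) give
#' positive DEP toward high field, negative values (down to -0.5) give
#' negative DEP toward low field. Inputs are complex permittivities, so any
#' particle model (homogeneous or core-shell effective) can be used.
#'
#' @param eps_particle Complex permittivity of the particle (F/m).
#' @param eps_medium Complex permittivity of the medium (F/m); recycled
#'   against `eps_particle`.
#' @return Complex f_CM (dimensionless).
#' @examples
#' f <- 1e3
#' clausius_mossotti(complex_permittivity(blood_cell_material(), f),
#'                   complex_permittivity(blood_plasma(), f))
#' @export
clausius_mossotti <- function(eps_particle, eps_medium) {
  denom <- eps_particle + 2 * eps_medium
  if (any(Mod(denom) == 0))
    stop("degenerate input: eps_particle + 2*eps_medium = 0")
  (eps_particle - eps_medium) / denom
}

#' Core-shell particle dielectric model
#'
#' A spherical particle with an inner core (cytoplasm) and a single outer
#' shell (membrane), each a homogeneous dielectric. Used by
#' [effective_shell_permittivity()] to collapse the two phases into one
#' effective complex permittivity.
#'
#' @param r_inner Core radius in m (0 < r_inner < r_outer).
#' @param r_outer Total (core + shell) radius in m.
#' @param core,shell [dielectric_material()] objects.
#' @return An object of class `shelled_particle`.
#' @export
shelled_particle <- function(r_inner, r_outer, core, shell) {
  stopifnot(is.numeric(r_inner), is.numeric(r_outer),
            inherits(core, "dielectric_material"),
            inherits(shell, "dielectric_material"))
  if (!(r_inner > 0 && r_inner < r_outer))
    stop("need 0 < r_inner < r_outer")
  structure(list(r_inner = r_inner, r_outer = r_outer,
                 core = core, shell = shell),
            class = "shelled_particle")
}

#' Effective complex permittivity of a core-shell particle
#'
#' Single-shell mixing rule: with q = (r_outer/r_inner)^3 and
#' F = (eps_in* - eps_out*)/(eps_in* + 2 eps_out*),
#' eps_eff* = eps_out* (q + 2F)/(q - F). A vanishing shell (r_inner ->
#' r_outer) recovers the core permittivity; a dominant shell (r_inner -> 0)
#' recovers the shell permittivity.
#'
#' @param model A [shelled_particle()].
#' @param frequency Drive frequency in Hz (> 0); may be a vector.
#' @return Effective complex permittivity in F/m.
#' @export
effective_shell_permittivity <- function(model, frequency) {
  stopifnot(inherits(model, "shelled_particle"))
  if (!is.numeric(frequency) || any(frequency <= 0))
    stop("`frequency` must be positive (Hz)")
  eps_in <- complex_permittivity(model$core, frequency)
  eps_out <- complex_permittivity(model$shell, frequency)
  q <- (model$r_outer / model$r_inner)^3
  f <- (eps_in - eps_out) / (eps_in + 2 * eps_out)
  eps_out * (q + 2 * f) / (q - f)
}

particle_eps <- function(particle, frequency) {
  if (inherits(particle, "dielectric_material")) {
    complex_permittivity(particle, frequency)
  } else if (inherits(particle, "shelled_particle")) {
    effective_shell_permittivity(particle, frequency)
  } else {
    stop("`particle` must be a dielectric_material or shelled_particle")
  }
}

#' Clausius-Mossotti spectrum over a frequency grid
#'
#' Evaluates Re(f_CM) for a particle (homogeneous material or core-shell
#' model) in a medium over an ascending frequency grid, and locates a sign
#' crossover, if any, by bisection between the first pair of adjacent grid
#' points with opposite sign (relative frequency tolerance 1e-6). An exact
#' zero at a grid point reports that grid frequency.
#'
#' @param particle A [dielectric_material()] or [shelled_particle()].
#' @param medium A [dielectric_material()].
#' @param frequencies Strictly increasing vector of frequencies in Hz.
#' @return An object of class `cm_spectrum`: list with `frequencies`,
#'   `re_fcm`, and `sign_crossover` (Hz, or `NA_real_` when Re(f_CM) does
#'   not change sign on the grid).
#' @examples
#' sp <- cm_spectrum(blood_cell_material(), blood_plasma(), 10^seq(1, 4, by = 0.5))
#' sp$re_fcm
#' @export
cm_spectrum <- function(particle, medium, frequencies) {
  if (!is.numeric(frequencies) || length(frequencies) < 1L)
    stop("`frequencies` must be a non-empty numeric vector (Hz)")
  if (any(frequencies <= 0) || is.unsorted(frequencies, strictly = TRUE))
    stop("`frequencies` must be positive and strictly increasing")
  re_at <- function(f) {
    Re(clausius_mossotti(particle_eps(particle, f),
                         complex_permittivity(medium, f)))
  }
  re_fcm <- re_at(frequencies)

  crossover <- NA_real_
  zero_idx <- which(re_fcm == 0)
  if (length(zero_idx) > 0L) {
    crossover <- frequencies[zero_idx[1L]]
  } else {
    sgn <- sign(re_fcm)
    flips <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
    if (length(flips) > 0L) {
      i <- flips[1L]
      lo <- frequencies[i]; hi <- frequencies[i + 1L]
      crossover <- stats::uniroot(re_at, lower = lo, upper = hi,
                                  tol = 1e-6 * lo)$root
    }
  }
  structure(list(frequencies = frequencies, re_fcm = re_fcm,
                 sign_crossover = crossover),
            class = "cm_spectrum")
}

#' @export
print.cm_spectrum <- function(x, ...) {
  cat(sprintf("<cm_spectrum> %d frequencies, %g Hz .. %g Hz\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  cat(sprintf("  Re(f_CM) in [%.4f, %.4f]; sign crossover: %s\n",
              min(x$re_fcm), max(x$re_fcm),
              if (is.na(x$sign_crossover)) "none"
              else sprintf("%g Hz", x$sign_crossover)))
  invisible(x)
}

#' @export
as.data.frame.cm_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequencies, re_fcm = x$re_fcm)
}
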