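#' Default blood-cell species table
#'
#' Diameter ranges (WBC 10-15 um, RBC 7-8 um, PLT 2-3 um), zeta potentials
#' and whole-blood concentration ratios (per ul: RBC 5e6, PLT 3e5, WBC 7e3 -
#' standard physiology) used by [generate_population()]. Zeta potentials
#' other than the RBC value reuse the RBC default, the only printed cell
#' value; all entries are overridable.
#'
#' @return data.frame with columns `species`, `d_min`, `d_max` (m),
#'   `zeta` (V), `ratio_per_ul` (whole-blood concentration).
#' @export
default_species <- function() {
  data.frame(
    species = c("RBC", "WBC", "PLT"),
    d_min = c(7e-6, 10e-6, 2e-6),
    d_max = c(8e-6, 15e-6, 3e-6),
    zeta = c(-10.8e-3, -10.8e-3, -10.8e-3),
    ratio_per_ul = c(5e6, 7e3, 3e5),
    stringsAsFactors = FALSE
  )
}

sphere_volume <- function(d) pi * d^3 / 6

#' Generate a synthetic blood-cell population
#'
#' Draws individual cells (species, diameter, lateral position class) for a
#' given sample volume. Cell diameters are uniform within each species
#' range. The RBC count is set so that the RBC volume fraction (spherical
#' equivalent volumes) matches the target haematocrit; WBC and PLT counts
#' follow their physiological ratios to the RBC count. Each cell is
#' assigned a lateral class: `"core"` (migrated to the channel axis) or
#' `"wall"` (residing in the near-wall region), standing in for margination.
#'
#' @param haematocrit_pct Target haematocrit percentage in (0, 100);
#'   25 for PBS-diluted blood, 45 for whole blood.
#' @param volume_ul Sample volume in ul; at desk scale, fractions of a ul.
#' @param species_specs Species table as from [default_species()].
#' @param seed Integer RNG seed (mandatory: populations are reproducible).
#' @param near_wall_fraction Probability a cell occupies the near-wall
#'   class (default 0.3).
#' @return An object of class `cell_population`: data.frame with columns
#'   `species`, `diameter` (m), `lateral` (`"core"`/`"wall"`); attributes
#'   `haematocrit_pct`, `volume_ul`, `species_specs`.
#' @examples
#' pop <- generate_population(25, volume_ul = 0.001, seed = 1)
#' table(pop$species)
#' @export
generate_population <- function(haematocrit_pct = 25, volume_ul = 0.02,
                                species_specs = default_species(), seed,
                                near_wall_fraction = 0.3) {
  if (missing(seed)) stop("`seed` is required for a reproducible population")
  if (!(haematocrit_pct > 0 && haematocrit_pct < 100))
    stop("`haematocrit_pct` must be in (0, 100)")
  stopifnot(volume_ul > 0,
            all(c("species", "d_min", "d_max", "ratio_per_ul") %in%
                  names(species_specs)))
  if (any(species_specs$d_min <= 0 | species_specs$d_min >= species_specs$d_max))
    stop("species diameter ranges must be positive and ordered (d_min < d_max)")
  if (!"RBC" %in% species_specs$species)
    stop("impossible haematocrit target: species table has no RBC entry")

  set.seed(as.integer(seed))
  rbc <- species_specs[species_specs$species == "RBC", ]
  mean_rbc_vol <- sphere_volume((rbc$d_min + rbc$d_max) / 2)  # m^3
  vol_m3 <- volume_ul * 1e-9
  n_rbc <- round(haematocrit_pct / 100 * vol_m3 / mean_rbc_vol)
  if (n_rbc < 1)
    stop("impossible haematocrit target: sample volume too small for one RBC")

  counts <- round(n_rbc * species_specs$ratio_per_ul /
                    rbc$ratio_per_ul)
  counts[species_specs$species == "RBC"] <- n_rbc

  sp <- rep(species_specs$species, counts)
  d <- stats::runif(length(sp),
                    min = rep(species_specs$d_min, counts),
                    max = rep(species_specs$d_max, counts))
  lateral <- ifelse(stats::runif(length(sp)) < near_wall_fraction,
                    "wall", "core")
  ord <- sample.int(length(sp))  # shuffle arrival order across species
  structure(
    data.frame(species = sp[ord], diameter = d[ord], lateral = lateral[ord],
               stringsAsFactors = FALSE),
    haematocrit_pct = haematocrit_pct, volume_ul = volume_ul,
    species_specs = species_specs, seed = as.integer(seed),
    class = c("cell_population", "data.frame"))
}

#' Achieved haematocrit of a population
#'
#' RBC spherical-equivalent volume fraction of the sample, in percent; used
#' to check consistency with the generation target.
#'
#' @param population A [generate_population()] result.
#' @return Percentage.
#' @export
population_haematocrit <- function(population) {
  stopifnot(inherits(population, "cell_population"))
  v <- sum(sphere_volume(population$diameter[population$species == "RBC"]))
  100 * v / (attr(population, "volume_ul") * 1e-9)
}

#' Emulate replicate haemocytometer counting of a separation outcome
#'
#' Applies multiplicative lognormal measurement noise with a given
#' coefficient of variation to every concentration of a count table,
#' producing replicate tables and their mean +/- SD summary, the way bench
#' counts are reported. The lognormal is mean-preserving and can never
#' produce negative concentrations.
#'
#' @param table A [count_table()] (e.g. from [simulate_separation()]).
#' @param cv_noise Coefficient of variation of the counting noise (>= 0;
#'   default 0.1).
#' @param replicates Number of replicate counts (default 3).
#' @param seed Integer RNG seed.
#' @return List with `replicates` (list of `count_table`s), `mean` and `sd`
#'   (data.frames of per-species concentration summaries).
#' @export
emulate_count_experiment <- function(table, cv_noise = 0.1, replicates = 3L,
                                     seed) {
  stopifnot(inherits(table, "count_table"), cv_noise >= 0, replicates >= 1L)
  if (missing(seed)) stop("`seed` is required")
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + cv_noise^2))
  noisy_one <- function() {
    jitter <- function(x) {
      if (cv_noise == 0) return(x)
      x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    count_table(table$species, jitter(table$c_in), jitter(table$c_blood_out),
                jitter(table$c_plasma_out),
                h_in = attr(table, "h_in"),
                h_blood_out = attr(table, "h_blood_out"),
                h_plasma_out = attr(table, "h_plasma_out"),
                q_in = attr(table, "q_in"),
                q_blood_out = attr(table, "q_blood_out"),
                q_plasma_out = attr(table, "q_plasma_out"))
  }
  reps <- replicate(replicates, noisy_one(), simplify = FALSE)
  cols <- c("c_in", "c_blood_out", "c_plasma_out")
  arr <- vapply(reps, function(r) as.matrix(r[, cols]),
                matrix(0, nrow(table), length(cols)))
  mean_df <- data.frame(species = table$species,
                        apply(arr, c(1, 2), mean))
  sd_df <- data.frame(species = table$species,
                      apply(arr, c(1, 2), stats::sd))
  list(replicates = reps, mean = mean_df, sd = sd_df)
}
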