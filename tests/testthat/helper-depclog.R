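# shared fixtures built in code

eps0 <- depclog::phys_const[["eps0"]]

# independent one-line oracles for the separation statistics
oracle_loss <- function(ci, co, cp) (1 - (co + cp) / ci) * 100
oracle_purity <- function(ci, cp) (1 - cp / ci) * 100
oracle_yield <- function(hi, ho, hp)
  100 * (100 - hp) * (ho - hi) / ((100 - hi) * (ho - hp))

# low-frequency (conductivity-dominated) limit of the CM factor
oracle_fcm_lowfreq <- function(sig_p, sig_m) (sig_p - sig_m) / (sig_p + 2 * sig_m)

random_count_table <- function() {
  ci <- stats::runif(3, 1e3, 1e7)
  count_table(c("RBC", "WBC", "PLT"),
              c_in = ci,
              c_blood_out = ci * stats::runif(3, 0, 1.2),
              c_plasma_out = ci * stats::runif(3, 0, 0.3),
              h_in = stats::runif(1, 10, 40),
              h_blood_out = stats::runif(1, 41, 70),
              h_plasma_out = stats::runif(1, 0, 9))
}

tiny_population <- function(seed, volume_ul = 0.002, hct = 25)
  generate_population(hct, volume_ul = volume_ul, seed = seed)

# flow-weighted aggregate cell loss of a simulation outcome (counts basis)
outcome_loss_fw <- function(outcome) {
  tab <- outcome$count_table
  cell_loss(sum(tab$c_in), sum(tab$c_blood_out), sum(tab$c_plasma_out),
            flows = c(attr(tab, "q_in"), attr(tab, "q_blood_out"),
                      attr(tab, "q_plasma_out")))
}

outcome_purity <- function(outcome) {
  tab <- outcome$count_table
  purity_efficiency(sum(tab$c_in), sum(tab$c_plasma_out))
}
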