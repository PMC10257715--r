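# Shared pipeline configurations for the ensemble-level tests.

wt_config <- function(out_dir = NULL) {
  list(seed = 3, out_dir = out_dir,
       simulate = list(n_molecules = 20, k_open = 0.01, k_close = 0.5,
                       donor_bleach_rate = 0.003,
                       acceptor_bleach_rate = 0.003),
       acquisition = list(movie_duration = 90),
       qc = list(min_frames = 20))
}

mutant_config <- function() {
  cfg <- wt_config()
  cfg$simulate$k_open <- 0.5
  cfg$simulate$k_close <- 0.01
  cfg
}

three_state_config <- function() {
  Q <- matrix(c(0, 0.15, 0,
                0.15, 0, 0.15,
                0, 0.15, 0), 3, 3, byrow = TRUE)
  list(seed = 5,
       simulate = list(n_molecules = 24,
                       rate_matrix = Q,
                       fe_means = c(0.25, 0.55, 0.85),
                       fe_sds = rep(0.07, 3),
                       total_intensity = 500,
                       donor_bleach_rate = 0.002,
                       acceptor_bleach_rate = 0.002,
                       fraction_double_acceptor = 0,
                       fraction_donor_only = 0,
                       fraction_acceptor_only = 0),
       acquisition = list(movie_duration = 90),
       hmm = list(K = 3), mixture = list(K = 3))
}
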