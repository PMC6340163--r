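# Small tissue configurations used across tests; everything is generated
# in code at test time.

small_regions <- function(L, avn_k = 3) {
  node_regions(L,
               san_rows = 2:5, san_cols = 2:3,
               avn_rows = (L - 1):L,
               avn_cols = (floor(L / 2) - 1):(floor(L / 2) + 2),
               avn_k = avn_k)
}

small_config <- function(L = 40, p_H = 1, p_L = 1, p_refuse = 0,
                         r_noise = 0, total_steps = 2000, seed = 1,
                         avn_k = 3, ...) {
  sim_config(lattice = lattice_spec(L = L, p_H = p_H, p_L = p_L),
             regions = small_regions(L, avn_k = avn_k),
             timers = default_timers(atrial_r_noise = r_noise),
             p_refuse = p_refuse, total_steps = total_steps, seed = seed,
             ...)
}

T_SAN_DEFAULT <- 115 # f = 5, r = 70, a = 40
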