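# shared parameter sets used across test files

# the standard sweep setting: N = 1e8 cells, founding clone of 1000 cells
p_mig <- function(s = 0.04, r = 1e-6, m = 0.02)
  sweep_params(N = 1e8, s = s, r = r, m = m, C0 = 1e-5)

p_nomig <- function(s = 0.025, r = 1e-6)
  sweep_params(N = 1e8, s = s, r = r, m = 0, C0 = 1e-5)

# interior steady state for r ~ 0: migration-selection balance
balance_root <- function(s, m) (s - m) / ((m + 1) * s)
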