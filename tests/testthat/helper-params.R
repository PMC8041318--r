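# shared fixture builders

# mixed-type conjugate-like mechanism (apparent Km 15, Ki 38, Ki' 44)
conjugate_params <- function(Vmax = 1)
  params_from_apparent(Km_app = 15, Ki = 38, Kip = 44, Vmax = Vmax)

# competitive peptide-like mechanism (apparent Km 15, Ki 90)
peptide_params <- function(Vmax = 1)
  params_from_apparent(Km_app = 15, Ki = 90, Vmax = Vmax)

# the fixed-dUMP assay grids
S_GRID <- c(5, 10, 20, 50, 100)
I_PEPTIDE <- c(0, 25, 50, 100)
I_CONJ <- c(0, 20, 40)
DECAY_TIMES <- c(20, 40, 60, 120, 240)

random_mechanism <- function() {
  mechanism_params(K1 = runif(1, 1, 50), K2 = runif(1, 1, 50),
                   K3 = runif(1, 50, 500), K4 = runif(1, 50, 500),
                   K5 = runif(1, 5, 50), K6 = runif(1, 1, 100),
                   Vmax = runif(1, 0.5, 2))
}
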