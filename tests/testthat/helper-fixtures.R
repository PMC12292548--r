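# Case-study constants used across tests (frozen from the bundled preset)
cs <- list(Omega1 = 0.22, Omega2 = 0.38, alpha = 10, beta = 0.836)
cs_traits <- function() protist_traits(Omega1 = cs$Omega1, Omega2 = cs$Omega2)

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
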