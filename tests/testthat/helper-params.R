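# Illustrative response-parameter triplets (shared fixtures built in code).
# All use alpha0 = 10, tau = 5; beta is irrelevant for rate-only checks.

demo_adaptive <- function(beta = 1)
  response_params("adaptive", alpha0 = 10, beta = beta, B = 20, tau = 5)

demo_inverted <- function(beta = 1)
  response_params("inverted", alpha0 = 10, beta = beta, A = 20, tau = 5)

demo_speculator <- function(beta = 1)
  response_params("speculator", alpha0 = 10, beta = beta, A = 20, B = -18,
                  tau = 5)

# Generating truth of the synthetic tumbling-probability series
# (speculator response in seconds / mM units)
series_truth <- function()
  response_params("speculator", alpha0 = 0.074, beta = 0.034, A = 1300,
                  B = -1000, tau = 71)

# Optimized-parameter sets used by the oscillating two-Gaussian world
gauss_adaptive <- function()
  response_params("adaptive", alpha0 = 0.0084, beta = 54, B = 1526,
                  tau = 0.020)

gauss_speculator <- function()
  response_params("speculator", alpha0 = 0.0089, beta = 0.056, A = 74,
                  B = -67, tau = 33)
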