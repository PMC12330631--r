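# Small configurations and generators shared across tests.

# short network: 0.5 s (5,000 steps), stimulation 0.1-0.25 s
tinyConfig <- function(...) {
  networkConfig(durationS = 0.5, stimWindowS = c(0.1, 0.25), ...)
}

# drive with every stochastic input silenced
silentConfig <- function(...) {
  tinyConfig(stimRateHz = 0, vhpcNoiseRateHz = 0,
             neuronNoise = list(rate_hz = 0,
                                amplitude = c(VIP = 1, SST = 1, PV = 1.2,
                                              PYR = 1),
                                tau_ms = 8, length_steps = 40), ...)
}

# brute-force truncated-kernel convolution (independent oracle)
convOracle <- function(x, amplitude, tauMs, lengthSteps, dtMs) {
  k <- amplitude * exp(-(0:(lengthSteps - 1)) * dtMs / tauMs)
  n <- length(x)
  y <- numeric(n)
  for (t in seq_len(n)) {
    j <- 0:min(lengthSteps - 1, t - 1)
    y[t] <- sum(k[j + 1] * x[t - j])
  }
  y
}
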