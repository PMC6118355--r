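# Small builders used across the suite.

# Toy sequence from explicit cs / us vectors (cs: "+"/"-" shorthand).
toy_seq <- function(cs, us, id = "toy") {
  as_trial_sequence(data.frame(
    trial = seq_along(cs),
    cs = ifelse(cs == "+", "CS+", "CS-"),
    us = as.integer(us)), participant_id = id)
}

default_seq <- function(seed = 1, id = "P1") {
  generate_design(design_config(), seed = seed, participant_id = id)
}

# Independent reference recursions, deliberately re-derived here so package
# traces are checked against a second implementation.
ref_rw <- function(u, eta, x0 = 0.5) {
  x <- numeric(length(u)); cur <- x0
  for (i in seq_along(u)) { x[i] <- cur; cur <- cur + eta * (u[i] - cur) }
  x
}
ref_hybrid <- function(u, k, eta0 = 0.5, x0 = 0.5) {
  n <- length(u); x <- e <- numeric(n); cx <- x0; ce <- eta0
  for (i in seq_len(n)) {
    x[i] <- cx; e[i] <- ce
    pe <- u[i] - cx
    cx <- cx + ce * pe
    ce <- k * abs(pe) + (1 - k) * ce
  }
  list(x = x, eta = e)
}
# Brute-force Beta-count accumulation per CS (prior convention).
ref_beta_prior <- function(u) {
  n <- length(u); a <- b <- numeric(n); ca <- 1; cb <- 1
  for (i in seq_len(n)) {
    a[i] <- ca; b[i] <- cb
    ca <- ca + u[i]; cb <- cb + 1 - u[i]
  }
  list(alpha = a, beta = b, prior_mean = a / (a + b), v = -log(a + b))
}
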