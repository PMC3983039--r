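# Reference parameter sets used throughout the suite: continuous low-dose
# exposure at alpha = 0.1 with 5% repair failure, protection lasting 1/eta =
# 100 time units, and (for the communication variant) strong bystander
# signalling from repairing cells.
mem_ref <- function() memory_model(alpha = 0.1, p = 0.05, c = 1, eta = 0.01)

comm_ref <- function(beta0 = 10, beta1 = 0) {
  communication_model(alpha = 0.1, p = 0.05, c = 1, eta = 0.01,
                      beta0 = beta0, beta1 = beta1)
}

# Dose axis equal to the dose rate: exposure duration fixed at 150 time
# units with dose_scale = 1/150, failure probability 0.4 + 0.55 * dose.
hrs_mapping <- function(p1 = 0.55) {
  dose_mapping("linear", p0 = 0.4, p1 = p1, mode = "fixed_duration",
               duration = 150, dose_scale = 1 / 150)
}

hrs_doses <- function(n = 60) 10^seq(-3, 0, length.out = n)

# Recovery-study conditions: identifiable truth on a 3-decade dose grid.
recovery_truth <- function() c(alpha = 0.5, eta = 0.02, p0 = 0.3, p1 = 0.95)

recovery_mapping <- function() {
  dose_mapping("saturating", p0 = 0.3, p1 = 0.95, mode = "fixed_rate",
               alpha = 0.5)
}

recovery_doses <- function() 10^seq(log10(0.05), log10(50), length.out = 12)

# random valid parameter set for property-style tests
random_params <- function() {
  variant <- sample(c("memory", "communication", "full"), 1)
  alpha <- 10^runif(1, -1.5, 1.5)
  p <- runif(1, 0.01, 0.9)
  c_ <- 10^runif(1, -0.5, 0.5)
  eta <- 10^runif(1, -2.5, 0)
  b0 <- 10^runif(1, -1, 1)
  b1 <- 10^runif(1, -2, 0)
  switch(variant,
    memory = memory_model(alpha, p, c_, eta),
    communication = communication_model(alpha, p, c_, eta, b0, b1),
    full = full_model(alpha, p, c_, eta, b0, b1))
}
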