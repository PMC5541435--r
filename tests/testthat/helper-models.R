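# shared model fixtures, all built in code

# the binary example used throughout the docs: partial + full agonist with
# well-separated potencies and different slopes
binary_example <- function() {
  mixture_model(data.frame(
    label = c("A", "B"), emax = c(0.7, 1.0), d50 = c(100, 1), slope = c(1, 2)
  ))
}

# n identical full agonists (the sham / equal-parameter workhorse)
equal_model <- function(n = 2, emax = 1, d50 = 1, slope = 1) {
  mixture_model(data.frame(
    emax = rep(emax, n), d50 = rep(d50, n), slope = rep(slope, n)
  ))
}

# randomized mixtures for property tests (call under a fixed seed)
random_model <- function(n = 2, emax_range = c(0.3, 1), slope_range = c(0.5, 5)) {
  mixture_model(data.frame(
    emax = runif(n, emax_range[1], emax_range[2]),
    d50 = 10^runif(n, -1, 2),
    slope = runif(n, slope_range[1], slope_range[2])
  ))
}

# random strictly-positive dose matrix around the model's d50s
random_doses <- function(model, rows = 5, decades = 1) {
  d50 <- vapply(model$components, function(c) c$d50, numeric(1))
  sweep(matrix(10^runif(rows * n_agents(model), -decades, decades),
               nrow = rows), 2, d50, "*")
}
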