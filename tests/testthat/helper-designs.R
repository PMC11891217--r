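# Shared builders for synthetic designs and true surfaces.

three_factors <- function() {
  rbind(
    factor_spec("x1", "", 0, 10),
    factor_spec("x2", "", -1, 1),
    factor_spec("x3", "", 100, 300)
  )
}

# an arbitrary but fixed true quadratic in coded units
true_coded_model <- function(factors) {
  k <- nrow(factors)
  quadratic_model(
    intercept = 3,
    linear = seq(0.5, by = 0.25, length.out = k),
    interaction = seq(-0.2, by = 0.1, length.out = k * (k - 1) / 2),
    quadratic = seq(0.3, by = -0.15, length.out = k),
    units = "coded", factors = factors
  )
}

# independent polynomial evaluator: explicit term-by-term summation,
# sharing no code with predict.quadratic_model()
brute_force_predict <- function(model, x) {
  co <- model$coef
  k <- model$k
  total <- co[[1]]
  pos <- 1
  for (i in seq_len(k)) total <- total + co[[pos + i]] * x[i]
  pos <- pos + k
  t <- 0
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    t <- t + 1
    total <- total + co[[pos + t]] * x[i] * x[j]
  }
  pos <- pos + k * (k - 1) / 2
  for (i in seq_len(k)) total <- total + co[[pos + i]] * x[i]^2
  total
}

fixture_training_data <- function() {
  d <- prac_design()
  list(x = design_settings(d), y = d$runs$response)
}
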