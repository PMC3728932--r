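# shared fixture builders for the test suite

# small landscape with uniform favorability
unit_substrate <- function(n = 50, value = 1) {
  g <- grid_spec(n, n)
  s <- draw_substrate_field(g, value, 0)
  s
}

# juvenile grid with given pools in one cell
one_cell_grid <- function(n = 5, i = 3, j = 3, n_new = 0, n1 = 0, n2 = 0,
                          cap_k = 50) {
  jg <- juvenile_grid(grid_spec(n, n), cap_k)
  jg$n_new[i, j] <- as.integer(n_new)
  jg$n1[i, j] <- as.integer(n1)
  jg$n2[i, j] <- as.integer(n2)
  jg
}

# closed-form truncated-normal mean, written independently of the
# package (oracle for the sampler)
tn_mean_oracle <- function(mu, sd, low = 0, high = 1) {
  a <- (low - mu) / sd; b <- (high - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}
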