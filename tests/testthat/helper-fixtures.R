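# Shared small fixtures, built in code.

table_dists <- function() population_distributions()

small_stageIII_cohort <- function(n = 500, seed = 101) {
  sample_cohort(table_dists(), c(IIIA = 0.5, IIIB = 0.5), n, seed = seed)
}

fig8_cohort <- function(diameter = 5) {
  data.frame(id = 1L, stage = "IIIA", diameter = diameter, rho = 0.008,
             alpha = 0.3, beta_c = 0.03, delay = 14)
}

# Classic fourth-order Runge-Kutta on dN/dt = f(N): the independent numeric
# oracle for the closed-form growth solutions.
rk4_integrate <- function(f, n0, t_end, h = 0.01) {
  n <- n0
  steps <- ceiling(t_end / h)
  h <- t_end / steps
  for (i in seq_len(steps)) {
    k1 <- f(n)
    k2 <- f(n + h / 2 * k1)
    k3 <- f(n + h / 2 * k2)
    k4 <- f(n + h * k3)
    n <- n + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  n
}
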