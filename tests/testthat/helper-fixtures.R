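# Shared fixtures built in code.

paper_fit <- function() {
  rsm_quad(activity ~ cs + ga + time, amylase_bbd())
}

# Second-order equation coefficients at printing precision, and the
# study's reported fit/ANOVA quantities used across tests.
reported_coefs <- c(238, 812, -393, -72.6, -133, 164.0, 2.999,
                    -91.0, -13.66, 12.42)

# Random 10-coefficient quadratics with moderate curvature, for
# property-style tests.
random_quadratic <- function() {
  c(runif(1, -5, 5), runif(3, -3, 3), runif(3, -2, 2), runif(3, -1, 1))
}

unit_box_factors <- function() {
  bbd_factors(bbd_factor("x1", -1, 0, 1), bbd_factor("x2", -1, 0, 1),
              bbd_factor("x3", -1, 0, 1))
}
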