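# Shared small fixtures, built in code.

h2o_sch <- h2o_schedule()
fdg_sch <- fdg_schedule()

h2o_cp <- synth_aif("h2o_bolus", onset = 1, t_end = schedule_end(h2o_sch))
h2o_inj <- injection(h2o_cp, window = c(0, schedule_end(h2o_sch)),
                     label = "h2o")

# a strictly positive smooth 1-D source for scanner tests
smooth_source_1d <- function(N = 128) {
  x <- seq_len(N)
  0.2 + exp(-((x - 50) / 10)^2) + 0.5 * exp(-((x - 90) / 15)^2)
}

# random valid piecewise-linear residue on a geometric knot grid
random_residue <- function(T_E = 10, n = 8) {
  kn <- residue_knots(T_E, n)
  delta <- stats::rexp(n)
  residue_fn(kn, rev(cumsum(rev(delta))))
}
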