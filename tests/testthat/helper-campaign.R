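# shared scaled-down acceptance campaign (computed once per test run).
#
# Scaling relative to the reference study design (documented in the
# methods vignette): desk mesh 400 x 100 x 100 um at 10 um elements,
# runs start at the substrate midpoint (the equilibrium plane is an
# attractor and does not depend on the start), 3 repeats per condition
# instead of 10, 220 steps per run.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_campaign <- function() {
  if (!is.null(.acceptance_cache$camp)) return(.acceptance_cache$camp)
  sc <- default_scenarios("desk", cell_center = c(200, 50, 50),
                          n_steps = 220L)
  camp <- run_campaign(sc, n_runs = 3L, base_seed = 1L)
  .acceptance_cache$camp <- camp
  camp
}
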