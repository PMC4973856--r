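# Shared fixtures: the Alzheimer's-style worked-example design (SIB score
# outcome, sd 13.2, 200 patients per stage, prevalence one half) and the
# four observed-data scenarios exercised throughout the suite.
worked_design <- function(b = 0, B = NULL) {
  asd_design(n1 = 200, n2 = 200, sigma = 13.2, p_S = 0.5, b = b, B = B)
}

scenario <- function(i) {
  switch(i,
    `1` = list(x = 6.5, y = 5.6, u = 7.42),
    `2` = list(x = 6.5, y = 3.8, u = 7.42),
    `3` = list(x = 5.4, y = 6.0, v = 7.42, w = 3.82),
    `4` = list(x = 5.7, y = 5.7, v = 7.42, w = 3.82))
}

estimate_scenario <- function(i, design = worked_design()) {
  s <- scenario(as.character(i))
  estimate_trial(design, do.call(stage_summaries, c(list(design), s)))
}
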