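# Desk-scale scenario runs shared by the acceptance checks. Each scenario is
# computed once per test session and cached; all runs share one base seed so
# that mitigation contrasts are paired on identical replicate data.

.scenario_cache <- new.env(parent = emptyenv())

scenario_run <- function(name) {
  if (!exists(name, envir = .scenario_cache)) {
    cfgs <- list(
      epi_none = scenario_preset("epistatic", base_seed = 11L),
      add_jt_none = scenario_preset("additive", joint_tagging = TRUE,
                                    base_seed = 11L),
      add_jt_wt = scenario_preset("additive", joint_tagging = TRUE,
                                  mitigation = "snp_dosage_weighting",
                                  base_seed = 11L),
      mix21_wt = scenario_preset("mixed", mix_ratio = c(2, 1),
                                 mitigation = "snp_dosage_weighting",
                                 base_seed = 11L),
      mix12_wt = scenario_preset("mixed", mix_ratio = c(1, 2),
                                 mitigation = "snp_dosage_weighting",
                                 base_seed = 11L),
      epi_wt = scenario_preset("epistatic", mitigation = "snp_dosage_weighting",
                               base_seed = 11L))
    assign(name, run_scenario(cfgs[[name]]), envir = .scenario_cache)
  }
  get(name, envir = .scenario_cache)
}
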