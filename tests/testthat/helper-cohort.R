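# Reduced study configurations used across tests: same generative structure
# as the default study, smaller where a test only needs the mechanics.

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_nodes = 20L, n_volumes = 64L, n_modules = 4L,
         n_controls = 6L, n_cases = 5L, random_seed = 11L),
    list(...))
  do.call(generator_config, args)
}

# Complete-null configuration: case couplings equal control couplings.
null_config <- function(base = generator_config(), random_seed = base$random_seed) {
  base$global_coupling_case <- base$global_coupling_control
  base$longrange_coupling_case <- base$longrange_coupling_control
  base$random_seed <- as.integer(random_seed)
  base
}
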