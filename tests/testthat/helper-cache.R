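# Shared fixtures, computed lazily and memoised across test files.
# Everything is generated by the package itself; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# the four steady-state condition columns: chest wall {high, low} x
# upper airway {normal, braked}, at the published muscle amplitudes
condition_grid <- list(
  high_normal = list(dw = 0.48, A_mus = 1.85, brake = 1),
  high_braked = list(dw = 0.48, A_mus = 3.2,  brake = 10),
  low_normal  = list(dw = 2.4,  A_mus = 2.78, brake = 1),
  low_braked  = list(dw = 2.4,  A_mus = 3.8,  brake = 10))

steady_condition <- function(name) {
  cc <- condition_grid[[name]]
  cached(paste0("steady_", name),
         steady_state_breath(resp_params(dw = cc$dw), recruitment_state(),
                             A_mus = cc$A_mus, brake = cc$brake))
}

sim_cached <- function(name, ...) {
  key <- paste0("sim_", name, "_", paste(deparse(substitute(list(...))),
                                         collapse = ""))
  cached(key, run_simulation(load_scenario(name, ...)))
}
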