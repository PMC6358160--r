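# Developed networks are expensive; several acceptance checks share them.
# Cache one development run per (scene, seed, steps, aim) within a session.

.dev_cache <- new.env(parent = emptyenv())

cached_development <- function(scene, seed, n_steps = 130,
                               param_overrides = list()) {
  key <- paste(scene, seed, n_steps,
               paste(names(param_overrides), unlist(param_overrides),
                     collapse = "_"), sep = "|")
  if (!exists(key, envir = .dev_cache)) {
    cfg <- experiment_config(scene, seed = seed, n_steps = n_steps,
                             param_overrides = param_overrides)
    assign(key, run_development(cfg), envir = .dev_cache)
  }
  get(key, envir = .dev_cache)
}
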