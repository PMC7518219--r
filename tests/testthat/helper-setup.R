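# shared fixtures: the standard individual and small config constructors

std_individual <- function() standard_parameters()$individual

std_config <- function(...) {
  args <- list(...)
  do.call(learning_config, args)
}

# individual with selected parameters overridden, starting from standard
modified_individual <- function(sensory = list(), reward = list(),
                                motivation = list()) {
  ind <- std_individual()
  for (nm in names(sensory)) ind$sensory[[nm]] <- sensory[[nm]]
  for (nm in names(reward)) ind$reward[[nm]] <- reward[[nm]]
  for (nm in names(motivation)) ind$motivation[[nm]] <- motivation[[nm]]
  ind
}
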