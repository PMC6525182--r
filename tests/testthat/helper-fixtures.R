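# shared fixtures: canonical parameter sets and a small dataset builder

woodyParams <- function() AllometryParams(k = 0.43, c = -0.016)
nonWoodyParams <- function() AllometryParams(k = 0.32, c = 0.011)

# compact dataset for pipeline-level tests: every species carries anatomy
smallConfig <- function(seed = 7, ...) {
  generatorConfig(seed = seed, nWoody = 120, nNonWoody = 80,
                  anatomyWoody = 120, anatomyNonWoody = 80, ...)
}

# a balanced cherry-pair tree with unit branches, handy for closed forms
cherryTree <- function() readNewick("((a:1,b:1):1,(c:1,d:1):1);")
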