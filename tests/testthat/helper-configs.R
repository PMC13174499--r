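# shared fixtures: small deterministic configurations used across tests

testNet <- buildDefaultNetwork()
testTracers <- standardTracers()

# pyruvate wholly glycolytic, lactate wholly LDH-derived: a pass-through
# chain where the tracer pattern reaches lactate unchanged
passThroughLactateConfig <- function() {
  cfg <- defaultFluxConfig()
  cfg <- setSourceFraction(cfg, "pyruvate", "glycolysis_tracer", 1)
  setSourceFraction(cfg, "lactate", "ldh_from_pyruvate", 1)
}

# glutamine -> aKG -> succinate, fully oxidative
oxidativeOnlyConfig <- function() {
  cfg <- defaultFluxConfig()
  cfg <- setSourceFraction(cfg, "glutamine", "exogenous_tracer", 1)
  cfg <- setSourceFraction(cfg, "aKG", "glutamine", 1)
  setSourceFraction(cfg, "succinate", "akgdh", 1)
}

# citrate wholly from reductive carboxylation of glutamine-derived aKG,
# chromatin acetyl-CoA and oxaloacetate wholly from ACLY cleavage
reductiveOnlyConfig <- function() {
  cfg <- defaultFluxConfig()
  cfg <- setSourceFraction(cfg, "glutamine", "exogenous_tracer", 1)
  cfg <- setSourceFraction(cfg, "aKG", "glutamine", 1)
  cfg <- setSourceFraction(cfg, "citrate", "idh1_reductive", 1)
  cfg <- setSourceFraction(cfg, "acetylCoA_chromatin", "acly_acetyl_arm", 1)
  setSourceFraction(cfg, "oxaloacetate", "acly_oaa_arm", 1)
}

# citrate fed only through PDH-derived acetyl on unlabeled oxaloacetate
pdhOnlyCitrateConfig <- function() {
  cfg <- defaultFluxConfig()
  cfg <- setSourceFraction(cfg, "acetylCoA_mito", "pdh", 1)
  cfg <- setSourceFraction(cfg, "citrate", "cs_oxidative", 1)
  cfg <- setSourceFraction(cfg, "oxaloacetate", "mdh_from_malate", 1)
  setSourceFraction(cfg, "malate", "unlabeled", 1)
}

# every pool fed only by unlabeled carbon
allUnlabeledConfig <- function() {
  cfg <- defaultFluxConfig()
  for (pool in c("pyruvate", "lactate", "alanine", "glutamine",
                 "acetylCoA_mito", "aKG", "glutamate", "succinate",
                 "malate", "aspartate", "acetylCoA_chromatin")) {
    cfg <- setSourceFraction(cfg, pool, "unlabeled", 1)
  }
  cfg
}

randomSimplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}
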