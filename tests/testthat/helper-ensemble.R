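# The trained C-Net + R-Net ensemble is expensive to fit, so it is trained
# once per test run (first use) and shared by the end-to-end tests.

ensembleCache <- new.env(parent = emptyenv())

trainedEnsemble <- function() {
  if (is.null(ensembleCache$nets)) {
    cfg <- pipelineConfig(seed = 1)
    ensembleCache$cfg <- cfg
    ensembleCache$nets <- trainPipelineNetworks(cfg)
  }
  list(nets = ensembleCache$nets, cfg = ensembleCache$cfg)
}

# Confounder fixture for the masking ablation: stromal histocytes are all
# PD-L1 positive (macrophage-like DAB mimics outside tumor nests).
confounderSpec <- function(seed, tps = 50) {
  synthSpec(tileWidth = 128, tileHeight = 128, plannedTPS = tps,
            plannedIPS = 50, nTumorCells = 20, nImmuneCells = 12,
            nFibrocytes = 5, icTumorFraction = 0.25,
            stromalHistPosProb = 1, seed = seed)
}

# Adjacent-cell fixture: a high fraction of close/adhesive tumor-cell
# pairs at 0.8 x nuclear diameter.
adjacentSpec <- function(seed, tps = 50) {
  synthSpec(tileWidth = 64, tileHeight = 64, plannedTPS = tps,
            plannedIPS = 0, nTumorCells = 8, nImmuneCells = 0,
            nFibrocytes = 0, adjacentFraction = 0.6,
            minSeparation = 10, seed = seed)
}
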