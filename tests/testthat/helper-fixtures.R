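## Shared fixtures. Expensive objects (the desk-scale paired dataset and the
## trained stacked model) are built once per test run and memoised, because
## several files exercise them.

.fixtures <- new.env(parent = emptyenv())

## small deterministic phantom set
fixturePhantoms <- function(n = 4L, size = 96L, seedBase = 1L) {
  key <- sprintf("ph_%d_%d_%d", n, size, seedBase)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- lapply(seq_len(n), function(s)
      generatePhantom(phantomSpec(size = size, nStructures = 5,
                                  seed = seedBase + s)))
  .fixtures[[key]]
}

## the desk-scale study corpus: 16 pairs, 64 px, 10% dose
deskData <- function() {
  if (is.null(.fixtures$deskData))
    .fixtures$deskData <- generatePairedDataset(
      phantomSpec(size = 64, nStructures = 5), 16,
      acquisitionModel(doseFraction = 0.1), seed = 100)
  .fixtures$deskData
}

deskSplit <- function() splitDataset(16, c(0.5, 0.3, 0.2), 2L)

## the proposed model trained on the desk corpus (about 2.5 min, once)
deskTrained <- function() {
  if (is.null(.fixtures$deskTrained)) {
    net <- buildNetwork(networkConfig("stacked_modified_unet",
                                      inputSize = 64, filters = 32,
                                      seed = 1))
    .fixtures$deskTrained <- trainNetwork(net, deskData(),
                                          deskTrainConfig(epochs = 20,
                                                          seed = 2),
                                          split = deskSplit())
  }
  .fixtures$deskTrained
}

## NIQE model fitted on clean phantoms (small patches for 96 px fixtures)
fixtureNIQE <- function() {
  if (is.null(.fixtures$niqe))
    .fixtures$niqe <- fitNIQEModel(fixturePhantoms(4L, 96L), patchSize = 24)
  .fixtures$niqe
}
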