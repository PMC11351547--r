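# Shared fixtures, generated once per test run and memoized.  Everything is
# produced in code under tempdir(); nothing binary ships with the package.

.fx <- new.env(parent = emptyenv())

.memo <- function(key, make) {
  if (is.null(.fx[[key]])) .fx[[key]] <- make()
  .fx[[key]]
}

# Small labeled dataset (4 calcified / 6 healthy) at desk resolution.
smallDataset <- function() {
  .memo("small", function() {
    generateDataset(4, 6, SceneParams(imageSize = 192), seed = 101,
                    dir = file.path(tempdir(), "echocalc-small"))
  })
}

# One easy noiseless calcified scene plus its params.
easyScene <- function() {
  .memo("easyScene", function() {
    p <- SceneParams(imageSize = 256, speckleSD = 0)
    blobs <- data.frame(x = p@valveCenter[1L] +
                          (p@valveInnerRadius + p@valveOuterRadius) / 2,
                        y = p@valveCenter[2L], radius = 4, intensity = 255)
    p@calciumBlobs <- blobs
    list(params = p, scene = generateScene(p))
  })
}

# A small detector trained on easy scenes, reused by unit/pipeline tests.
smokeDetector <- function() {
  .memo("smokeDetector", function() {
    m <- generateDataset(3, 5, SceneParams(imageSize = 256, speckleSD = 15),
                         seed = 33,
                         dir = file.path(tempdir(), "echocalc-det"))
    trainDetector(m, config = DetectorConfig(epochs = 40, seed = 1))
  })
}
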