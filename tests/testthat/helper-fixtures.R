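# Shared fixtures, generated once per test run and cached. Grids are
# desk-scale: large enough for the anatomy model (axial extent must hold
# the full layer stack) and the lesions under test, small enough to keep
# the suite fast.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), .fixtures)
  get(name, envir = .fixtures)
}

smallGeom <- function() VolumeGeometry(96, 96, 256)

# control scene + rendered volume + segmented surfaces + plexus masks
controlFixture <- function() cached("control", function() {
  g <- VolumeGeometry(128, 128, 320)
  scene <- simulateScene(g, "control", 0, seed = 2)
  volume <- renderVolume(scene, 1, NoiseModel(seed = 2))
  surfaces <- segmentSurfaces(volume)
  list(geom = g, scene = scene, volume = volume, surfaces = surfaces,
       masks = plexusMasksAt(scene, 0))
})

# single CNV lesion at reduced scale: rupture, void and dome phenotypes
cnvFixture <- function() cached("cnv", function() {
  g <- VolumeGeometry(288, 288, 320)
  scene <- simulateScene(g, "cnv", 1, seed = 6, dispersion = FALSE,
                         dimScale = 0.35)
  volume <- renderVolume(scene, 1, NoiseModel(seed = 6))
  surfaces <- segmentSurfaces(volume)
  list(geom = g, scene = scene, volume = volume, surfaces = surfaces)
})

# full angiography chain on the control fixture, with per-plexus Dice
octaFixture <- function() cached("octa", function() {
  fx <- controlFixture()
  vness <- enhanceVessels(fx$volume, fx$surfaces)
  angiogram <- segmentAngiogram(vness)
  rejected <- suppressProjectionArtifacts(angiogram, vness, fx$surfaces)
  bands <- list(SVP = c(0, 40), IVP = c(35, 60), DVP = c(60, 100))
  dice <- vapply(names(bands), function(pl)
    bandDice(rejected, fx$masks[[pl]] * 1, fx$surfaces, bands[[pl]]),
    numeric(1))
  list(fx = fx, vness = vness, angiogram = angiogram, rejected = rejected,
       dice = dice)
})

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# band-restricted Dice of an angiogram against a ground-truth plexus mask
bandDice <- function(angiogram, trueMask, surfaces, bandUm) {
  sa <- extractSlab(angiogram, surfaces, "ILM", bandUm[1],
                    bandUm[2] - bandUm[1])
  st <- extractSlab(trueMask, surfaces, "ILM", bandUm[1],
                    bandUm[2] - bandUm[1])
  diceCoef(sa@voxels > 0, st@voxels > 0)
}
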