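# Shared phantom analyses, computed once per test run.

.phantomCache <- new.env(parent = emptyenv())

# full-size default two-region phantom: render, retrieve, tile, analyze
defaultPhantomAnalysis <- function() {
  if (is.null(.phantomCache$full)) {
    ph <- makePhantom(phantomSpec(), seed = 20L)
    stack <- renderStack(ph, seed = 20L)
    ret <- retrieveMaps(stack)
    grid <- tileGrid(dim(thetaMap(ret$maps)), 150,
                     pixelSize(ret$maps))
    an <- analyzeSection(ret$maps, grid)
    .phantomCache$full <- list(
      phantom = ph, maps = ret$maps, grid = grid, analysis = an
    )
  }
  .phantomCache$full
}

# small noiseless single-region phantom for exact round trips
noiselessPhantom <- function() {
  if (is.null(.phantomCache$noiseless)) {
    spec <- phantomSpec(
      imageShape = c(64L, 64L), pixelSizeUm = 1,
      orderedThetaModes = data.frame(mean = 30, sd = 0, weight = 1),
      disorderedThetaModes = data.frame(mean = 30, sd = 0, weight = 1),
      orderedGamma = c(2, 0), disorderedGamma = c(2, 0),
      backgroundFraction = 0, kSdLog = 0,
      noise = "none"
    )
    ph <- makePhantom(spec, seed = 5L)
    .phantomCache$noiseless <- list(
      phantom = ph, stack = renderStack(ph, seed = 5L)
    )
  }
  .phantomCache$noiseless
}
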