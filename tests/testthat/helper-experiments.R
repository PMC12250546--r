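# shared 64^2 study fixture for the end-to-end experiment tests
studyFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- 64L
      cache <<- list(
        g = g,
        phantom = makeBinaryPhantom("nonconvex_blob", g),
        dict = buildDictionary(g),
        cfg = levelSetConfig(grayLevels = c(0, 1)),
        opts = owlqnOptions(maxIterations = 700))
    }
    cache
  }
})
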