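# Small in-code model builders shared across test files.

# linear uptake -> transport -> biomass chain, Z = uptake
chainModel <- function(uptake = 10) {
  metabolicModel(data.frame(
    id = c("EX_A", "T_A", "GROWTH"),
    name = c("A exchange", "A transport", "biomass"),
    equation = c("A[e] <=>", "A[e] -> A[c]", "A[c] ->"),
    gpr = c("", "gA", ""),
    subsystem = c("exchange", "transport", "biomass"),
    lower = c(-uptake, NA, NA), upper = c(1000, NA, NA),
    stringsAsFactors = FALSE), objective = "GROWTH")
}

# two identical irreversible parallel paths jointly carrying the uptake flux
parallelPathsModel <- function(uptake = 6) {
  metabolicModel(data.frame(
    id = c("EX_A", "P1", "P2", "GROWTH"),
    name = "",
    equation = c("A[e] <=>", "A[e] -> B[c]", "A[e] -> B[c]", "B[c] ->"),
    gpr = c("", "g1", "g2", ""),
    subsystem = c("exchange", "transport", "transport", "biomass"),
    lower = c(-uptake, NA, NA, NA), upper = c(1000, NA, NA, NA),
    stringsAsFactors = FALSE), objective = "GROWTH")
}

# the fixture, built once per test run
fixtureOnce <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildThermophileFixture()
    cache
  }
})
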