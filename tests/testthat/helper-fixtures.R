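# Shared synthetic fixture, built once per test run at reduced depth so the
# module tests stay fast; the acceptance tests build their own full-depth
# fixture.

.fixture_cache <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    cfg <- sim_config(seed = 7, read_depth = 2e5, degradome_depth = 2e4)
    dir <- file.path(tempdir(), "srnapipe_small_fixture")
    pcfg <- make_fixture(cfg, dir = dir)
    res <- suppressWarnings(suppressMessages(run_pipeline(pcfg)))
    .fixture_cache$fx <- list(config = cfg, pipeline_config = pcfg,
                              sim = attr(pcfg, "sim"), result = res)
  }
  .fixture_cache$fx
}

# a clean planted-style hairpin precursor for structure tests: mature on the
# 5' arm, fully complementary star region, short A/C terminal loop
planted_hairpin <- function(mature = "GGCAGCTGCAGTACGATCGGA",
                            e5 = "ACGTGCGATCGG", loop = "ACCAACACCAAC") {
  paste0(e5, mature, loop, revcomp(mature), revcomp(e5))
}
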