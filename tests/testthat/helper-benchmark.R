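# The scaled-down end-to-end benchmark is expensive (five trained
# variants), so it runs once per test session and is shared by every
# assertion that needs it.

benchmark_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_benchmark(seed = 1L, config = benchmark_config())
    }
    cache
  }
})

mean_mcc_of <- function(res, variant, configuration) {
  s <- res$summary
  s$mean_mcc[s$variant == variant & s$configuration == configuration]
}
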