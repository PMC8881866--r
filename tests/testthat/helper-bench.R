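# Trained benchmark models are expensive; train each (dataset, seed) pair
# once per test run and share it across test files via this cache.
.bench_cache <- new.env(parent = emptyenv())

bench_run_cached <- function(name, seed, n = 40000L) {
  key <- paste(name, seed, n, sep = "_")
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- run_benchmark(name, seed = seed, n = n)
  .bench_cache[[key]]
}

bench_seeds <- function() c(1L, 2L, 3L)
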