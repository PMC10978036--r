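# Shared fixtures.  Expensive objects (trained models, corpora) are built
# once per test run and memoized here; everything is generated in code from
# fixed seeds.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Small geometries for unit tests: 32x32 grid, strongly under-sampled
# few-view scan (16 views) vs an adequately sampled full scan (96 views).
tiny_few <- function() geometry(16, 32, image_size = 32)
tiny_full <- function() geometry(96, 32, image_size = 32)
tiny_phantom_config <- function() phantom_config(image_size = 32, seed = 9L)

tiny_corpus <- function() memo("tiny_corpus", function() {
  build_corpus(tiny_phantom_config(), 40, tiny_few(), tiny_full())
})

tiny_test_corpus <- function() memo("tiny_test_corpus", function() {
  build_corpus(tiny_phantom_config(), 20, tiny_few(), tiny_full(),
               start_index = 5000L)
})

# A small trained classifier shared by the score-separation and
# reconstruction tests.  Few Adam steps are available at this scale, so the
# learning rate is raised accordingly (see the methods vignette).
tiny_trained <- function() memo("tiny_trained", function() {
  m <- build_cnn(cnn_config(input_size = 32), seed = 101L)
  train_classifier(m, tiny_corpus(),
                   train_config(epochs = 40, learning_rate = 3e-2,
                                batch_size = 8, seed = 202L))
})

# A smooth radial test image (no sharp edges), used where FBP accuracy
# itself is under test.
smooth_blob <- function(N, sigma = N / 6) {
  cc <- (N - 1) / 2
  d2 <- outer((seq_len(N) - 1 - cc)^2, (seq_len(N) - 1 - cc)^2, "+")
  exp(-d2 / (2 * sigma^2))
}
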