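# Desk-scale end-to-end benchmark shared by the test suite and the
# acceptance script.

#' Tiny end-to-end training benchmark
#'
#' Generates synthetic leaf-lesion scenes under the package's default
#' study conditions, trains the desk-scale model (64x64 inputs, width 32,
#' depth 2, 4 coarse + 3 fine experts, top-2 routing, attention sparsity
#' rho = 0.25) for a short curriculum, and evaluates on held-out scenes.
#'
#' @param seed master seed; scene seeds, weight initialization and every
#'   noise stream derive from it.
#' @param n_train,n_val scene counts (defaults 200 and 30).
#' @param epochs training epochs (default 5).
#' @param batch minibatch size.
#' @param verbose print per-epoch progress.
#' @return list(checkpoint, eval, sparsity = observed and expected
#'   attention sparsity on a held-out scene, utilization_entropy).
#' @export
run_tiny_benchmark <- function(seed = 1L, n_train = 200L, n_val = 30L,
                               epochs = 5L, batch = 2L, verbose = FALSE) {
  seed <- as.integer(seed)
  train_scenes <- lapply(seq_len(n_train), function(i)
    generate_scene(scene_config(seed = seed * 1000L + i)))
  val_scenes <- lapply(seq_len(n_val), function(i)
    generate_scene(scene_config(seed = seed * 1000L + n_train + i)))
  model <- build_model(model_config(rho = 0.25, seed = seed))
  schedule <- train_schedule(
    epochs = epochs, batch = batch, warmup_epochs = 1L,
    phase_boundaries = c(1L, max(2L, epochs - 1L)), seed = seed)
  ck <- train_model(model, train_scenes, schedule, verbose = verbose)
  ev <- evaluate_model(ck$model, val_scenes)
  # routing statistics and attention sparsity on held-out scenes
  decisions <- lapply(val_scenes[seq_len(min(10L, n_val))], function(s)
    forward(s$image, ck$model, mode = "eval")$aux$s1_decision)
  ustats <- utilization(decisions)
  fw <- forward(val_scenes[[1]]$image, ck$model, mode = "eval")
  list(checkpoint = ck, eval = ev,
       sparsity = c(observed = fw$aux$observed_attention_sparsity,
                    expected = fw$aux$expected_attention_sparsity),
       utilization_entropy = ustats$entropy_bits,
       utilization = ustats)
}
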