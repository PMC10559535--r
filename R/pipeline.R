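#' Run the full screening pipeline on a synthetic cohort
#'
#' Convenience wrapper chaining the whole chain: [simulate_cohort()] (unless
#' a cohort directory is supplied), [build_instances()], [split_by_patient()],
#' [enose_mlp()] on the training side and [metrics()] on the held-out
#' patients.
#'
#' @param synth a [synthetic_config()].
#' @param n_per_class_per_side patients of each class on each split side.
#' @param config an [mlp_config()].
#' @param split_seed seed of the patient split.
#' @param dir cohort directory; created via [simulate_cohort()] when missing.
#' @param circuit a [divider_circuit()].
#' @return list with `split`, `model`, `confusion`, `metrics` and the run
#'   metadata (`synth`, `circuit`, seeds).
#' @export
run_pipeline <- function(synth = synthetic_config(),
                         n_per_class_per_side = 10L,
                         config = mlp_config(),
                         split_seed = synth$seed,
                         dir = tempfile("cohort"),
                         circuit = divider_circuit()) {
  if (!dir.exists(dir) || !file.exists(file.path(dir, "manifest.csv"))) {
    manifest <- simulate_cohort(synth, dir)
  } else {
    manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                                stringsAsFactors = FALSE)
  }
  instances <- build_instances(manifest, dir, circuit = circuit)
  split <- split_by_patient(instances, n_per_class_per_side, seed = split_seed)
  model <- enose_mlp(split$train, split$train$label, config = config)
  pred <- predict(model, split$test, type = "class")
  cm <- confusion(split$test$label, pred)
  list(split = split, model = model, confusion = cm, metrics = metrics(cm),
       synth = synth, circuit = circuit, split_seed = split_seed)
}
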