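# Shared setup for the numbered analysis scripts: the study conditions
# (generator settings, split sizes, training hyperparameters) and the on-disk
# locations results are written to. Every script can be run on its own from
# the repository root; expensive artifacts (the pre-trained leaf classifier)
# are cached under results/checkpoints/.

library(rapidcat)

RESULTS <- "results"
CHECKPOINTS <- file.path(RESULTS, "checkpoints")
dir.create(CHECKPOINTS, recursive = TRUE, showWarnings = FALSE)

MASTER_SEED <- 2023

# study conditions at desk scale: 64-px images, 16-px cue scale,
# 200/80/120 splits, the published training hyperparameters
study_spec <- function(...) synthetic_spec(side = 64, cue_scale = 16, ...)
study_config <- function(tag) {
  build_config(200, 80, 120, seed = derive_seed(MASTER_SEED, tag))
}
study_hp <- function(tag) hyperparams(seed = derive_seed(MASTER_SEED, tag))
PREPROC <- list(mean = rep(0.5, 3), sd = rep(0.25, 3))

study_source <- function(spec, tag = "source", images_per_label = 120) {
  make_source(spec, seed = derive_seed(MASTER_SEED, tag), images_per_label)
}

# pre-trained K-class leaf classifier (the transfer-learning starting point
# and the LUT backbone); trained once and cached
get_pretrained_checkpoint <- function(rotation_invariant = FALSE) {
  tag <- if (rotation_invariant) "ri" else "std"
  path <- file.path(CHECKPOINTS, paste0("pretrained_", tag, ".rds"))
  spec <- study_spec(rotation_invariant = rotation_invariant)
  graph <- generate_hierarchy(spec)
  src <- study_source(spec, paste0("source_", tag))
  if (file.exists(path)) {
    pre <- readRDS(path)
  } else {
    base <- make_backbone(small_backbone_config(K = n_labels(graph)),
                          seed = derive_seed(MASTER_SEED, "init"),
                          preprocess = PREPROC)
    pre <- train_multiclass(base, src, images_per_label = 30,
                            hp = hyperparams(lr = 0.01, momentum = 0.9, epochs = 15,
                                             seed = derive_seed(MASTER_SEED, "pre")))
    saveRDS(pre, path)
  }
  list(spec = spec, graph = graph, source = src, pretrain = pre)
}

save_table <- function(df, name) {
  path <- file.path(RESULTS, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  message("  -> ", path)
  invisible(path)
}
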