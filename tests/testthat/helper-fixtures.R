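# Shared fixtures.  Everything is generated in code; the smoke-trained GAN
# pair is built once per test session and reused by the inpainting,
# de-artifact, pipeline and acceptance tests.

make_disk <- function(n, radius = n / 4, value = 0.8,
                      center = c(0, 0)) {
  ctr <- (n - 1) / 2
  xs <- matrix(rep(seq_len(n) - 1 - ctr, each = n), n)
  ys <- matrix(rep(seq_len(n) - 1 - ctr, times = n), n)
  img <- matrix(0, n, n)
  img[(xs - center[1])^2 + (ys - center[2])^2 <= radius^2] <- value
  img
}

smoke_env <- new.env(parent = emptyenv())

# Study conditions of the desk-scale smoke benchmark: 64 x 64 phantoms
# (library seeds 1..40), a 4-degree tilt grid (45 angles), a 45-degree
# missing wedge; 16 training + 4 validation + 20 held-out phantoms; a
# 2-RRDB-block generator (depth 16) trained for 400 generator steps with a
# snapshot at step 200 (epoch 50); a depth-3, base-8 U-net trained for 20
# epochs on a 54-sample recipe mix.
smoke_conditions <- function() {
  list(n = 64, grid = angle_grid(4), wedge = wedge_spec(45),
       n_train = 16, n_val = 4, n_heldout = 20, seed = 7L)
}

smoke_phantoms <- function() {
  if (is.null(smoke_env$phantoms)) {
    sc <- smoke_conditions()
    total <- sc$n_train + sc$n_val + sc$n_heldout
    smoke_env$phantoms <- lapply(seq_len(total), function(i)
      unclass(generate_phantom(sc$n, seed = i)))
  }
  smoke_env$phantoms
}

smoke_pairs <- function() {
  if (is.null(smoke_env$pairs)) {
    sc <- smoke_conditions()
    smoke_env$pairs <- make_sinogram_pairs(smoke_phantoms(), sc$grid,
                                           sc$wedge)
  }
  smoke_env$pairs
}

smoke_idx <- function() {
  sc <- smoke_conditions()
  list(train = seq_len(sc$n_train),
       val = sc$n_train + seq_len(sc$n_val),
       heldout = sc$n_train + sc$n_val + seq_len(sc$n_heldout))
}

smoke_inpaint_fit <- function() {
  if (is.null(smoke_env$inpaint_fit)) {
    sc <- smoke_conditions()
    ix <- smoke_idx()
    gcfg <- inpaint_generator_config(n_rrdb_blocks = 2, feature_depth = 16,
                                     growth_channels = 8,
                                     n_dense_per_block = 1,
                                     n_growth_layers = 2)
    dcfg <- inpaint_discriminator_config(feature_depth = 16,
                                         slow_path_depth = 4,
                                         fast_path_depth = 2)
    # 100 scheduled epochs of 4 steps, capped at 400 generator steps; the
    # decay epochs scale with the run length (2/3 and 14/15 of it, the same
    # proportions as 20 and 28 of a 30-epoch run).  The epoch-50 checkpoint
    # is exactly the 200-step model (training is deterministic), so the
    # 200-step smoke quantities are measured on it.
    tcfg <- train_config(epochs = 100, batch_size = 4, seed = sc$seed,
                         decay_epochs = c(67, 93))
    smoke_env$inpaint_fit <- train_inpainting(
      smoke_pairs()[ix$train], smoke_pairs()[ix$val], tcfg,
      checkpoint_epochs = c(17, 50, 100), gcfg = gcfg, dcfg = dcfg,
      max_steps = 400)
  }
  smoke_env$inpaint_fit
}

# The generator state after exactly 200 updates (epoch-50 snapshot).
smoke_inpaint_200 <- function() {
  checkpoint_model(smoke_inpaint_fit()$checkpoints, 50)
}

tiny_experiment_config <- function(out_root, seed = 1) {
  experiment_config(
    n_phantoms = 14, image_size = 64, angle_step = 6, missing_total = 45,
    inpaint_gcfg = inpaint_generator_config(n_rrdb_blocks = 1,
                                            feature_depth = 8,
                                            growth_channels = 4,
                                            n_dense_per_block = 1,
                                            n_growth_layers = 1),
    inpaint_dcfg = inpaint_discriminator_config(feature_depth = 8,
                                                slow_path_depth = 3,
                                                fast_path_depth = 2),
    unet_gcfg = unet_config(depth = 2, base_channels = 4),
    deartifact_dcfg = deartifact_discriminator_config(feature_depth = 8,
                                                      depth = 2),
    inpaint_tcfg = train_config(epochs = 2, batch_size = 4, seed = seed),
    deartifact_tcfg = train_config(epochs = 2, batch_size = 6, seed = seed),
    checkpoint_epochs = c(1, 2),
    deartifact_total = 12, n_eval = 4, seed = seed, out_root = out_root)
}

smoke_deartifact_fit <- function() {
  if (is.null(smoke_env$deartifact_fit)) {
    sc <- smoke_conditions()
    ix <- smoke_idx()
    fit <- smoke_inpaint_fit()
    ds <- assemble_deartifact_dataset(smoke_phantoms()[ix$train],
                                      fit$checkpoints, total = 54,
                                      seed = sc$seed, grid = sc$grid,
                                      wedge = sc$wedge)
    vs <- assemble_deartifact_dataset(smoke_phantoms()[ix$val],
                                      fit$checkpoints, total = 12,
                                      seed = sc$seed + 1, grid = sc$grid,
                                      wedge = sc$wedge)
    tcfg <- train_config(epochs = 20, batch_size = 8, seed = sc$seed,
                         decay_epochs = c(14, 19))
    smoke_env$deartifact_fit <- train_deartifact(
      ds, vs, tcfg, checkpoint_epochs = 20,
      gcfg = unet_config(depth = 3, base_channels = 8),
      dcfg = deartifact_discriminator_config(feature_depth = 8, depth = 3))
  }
  smoke_env$deartifact_fit
}
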