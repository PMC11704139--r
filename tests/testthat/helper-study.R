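# Scaled-down study conditions shared by the heavier acceptance checks.
# Training happens once per test session and is cached; both the parameter-
# recovery and the restoration-gain checks reuse the same sequentially
# trained models (identification first, then deblurring).  The conditions
# are those documented in the methods vignette: p = 3 Zernike family
# (Noll 7-9, amplitude 0.15), 2000 bead phantoms of 64 x 64, noiseless
# training, 10 epochs at batch size 2 with symmetry augmentation and
# weight averaging.

study_cache <- new.env(parent = emptyenv())

study_family <- function() zernike_family(p = 3)   # Noll (7,8,9), c_max 0.15

study_phantom <- function() phantom_spec("beads", size = 64L)

study_margin <- 15L   # PSF half-width of the 31x31 default grid

trained_identification <- function() {
  if (!is.null(study_cache$identification)) return(study_cache$identification)
  set.seed(421)
  fam <- study_family()
  imgs <- lapply(seq_len(2000), function(i) generate_phantom(study_phantom()))
  model <- init_identification_model(3, "tiny", seed = 1)
  fit <- train_identification(model, imgs, fam, ranges = NULL,
                              train_config(lr = 3e-3, lr_final = 2e-4,
                                           epochs = 10L, batch_size = 2L,
                                           ema = 0.998, seed = 1))
  study_cache$identification <- fit
  fit
}

trained_deblurring <- function() {
  if (!is.null(study_cache$deblurring)) return(study_cache$deblurring)
  infit <- trained_identification()
  set.seed(422)
  fam <- study_family()
  imgs <- lapply(seq_len(300), function(i) generate_phantom(study_phantom()))
  solver <- solver_config(K = 4L, sigma = 1e-3, cg_iters = 20L)
  prox_list <- lapply(seq_len(solver$K), function(k)
    init_prox_network("tiny_unet", seed = 100 + k))
  fit <- train_deblurring(prox_list, infit$model, imgs, fam,
                          noise_ranges(),
                          train_config(lr = 1e-3, epochs = 3L,
                                       batch_size = 4L, seed = 2),
                          solver)
  fit$solver <- solver
  study_cache$deblurring <- fit
  fit
}

# Held-out identification errors (relative kernel and parameter error) at a
# given test noise level.
study_holdout_errors <- function(model, eta2, n = 200L, seed = 33) {
  fam <- study_family()
  set.seed(seed)
  t(vapply(seq_len(n), function(i) {
    u <- generate_phantom(study_phantom())
    op <- sample_operator(fam)
    obs <- degrade(u, op, noise_params(0, eta2), margin = study_margin)
    gh <- predict_params(model, obs$b)
    c(kernel = relative_error(family_operator(fam, gh)$kernel, op$kernel),
      param = relative_error(gh, op$gamma))
  }, numeric(2)))
}
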