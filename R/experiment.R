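#' Train and evaluate the two-stage pipeline on synthetic phantoms
#'
#' The package's end-to-end benchmark at desk scale: generates a jittered
#' phantom cohort (64^3 voxels at 0.4 mm, half the samples with a mucosal
#' lining of 2-4 mm, Gaussian noise), splits it into train / validation /
#' held-out test sets, trains the coarse (fixed 32^3 input) and fine (32^3
#' patch) networks with the weighted BCE loss, ADAM (lr 1.25e-4) and early
#' stopping on the validation subset, then runs the full inference pipeline
#' on every test phantom and evaluates it against the ground truth.
#'
#' @param seed Integer; drives phantom generation, weight initialization,
#'   patch sampling and augmentation.
#' @param n_train,n_val,n_test Cohort sizes (defaults 50/10/20).
#' @param base_spec Phantom family; default [phantom_spec()].
#' @param coarse_epochs,fine_epochs Epoch caps for the two stages. The
#'   coarse stage only has to propose a region of interest and converges in a
#'   few epochs; the fine stage determines the final boundary and gets the
#'   larger budget.
#' @param patience Early-stopping patience (epochs), both stages.
#' @param patches_per_sample Fine patches drawn per training scan per epoch
#'   budget (the fine dataset is sampled once).
#' @param cfg [pipeline_config()] used for inference.
#' @param verbose Print per-stage progress.
#' @return List with `mean_dsc`, `per_case` / `summary` (from
#'   [evaluate_batch()]), `coarse` and `fine` (trained nets + histories) and
#'   `n_test`.
#' @export
run_headline_experiment <- function(seed = 1L, n_train = 50, n_val = 10,
                                    n_test = 20, base_spec = phantom_spec(),
                                    coarse_epochs = 8, fine_epochs = 14,
                                    patience = 3, patches_per_sample = 4,
                                    cfg = pipeline_config(),
                                    verbose = interactive()) {
  n <- n_train + n_val + n_test
  say <- function(...) if (verbose) message(...)
  say("generating ", n, " phantoms")
  parts <- generate_dataset(n, base_spec, seed = derive_seed(seed, 11),
                            split = c(train = n_train / n, val = n_val / n,
                                      test = n_test / n))
  say("building training pairs")
  tp <- make_training_pairs(parts$train, fixed_size = cfg$coarse_fixed_size,
                            patch_size = cfg$patch_size,
                            patches_per_sample = patches_per_sample,
                            seed = derive_seed(seed, 12))
  vp <- make_training_pairs(parts$val, fixed_size = cfg$coarse_fixed_size,
                            patch_size = cfg$patch_size,
                            patches_per_sample = 2,
                            seed = derive_seed(seed, 13))
  tcfg <- function(k, ep) train_config(max_epochs = ep, patience = patience,
                                       seed = as.integer(derive_seed(seed, k)))
  say("training coarse network")
  coarse <- train_network(build_network(network_spec(), derive_seed(seed, 21)),
                          tp$coarse, vp$coarse, tcfg(31, coarse_epochs))
  say("training fine network")
  fine <- train_network(build_network(network_spec(), derive_seed(seed, 22)),
                        tp$fine, vp$fine, tcfg(32, fine_epochs))
  say("evaluating on ", n_test, " held-out phantoms")
  pairs <- lapply(parts$test, function(s) {
    res <- run_pipeline(s$volume, coarse$net, fine$net, cfg)
    list(pred = res$mask_native, truth = s$truth)
  })
  ev <- evaluate_batch(pairs)
  list(mean_dsc = mean(ev$per_case$dsc), per_case = ev$per_case,
       summary = ev$summary, coarse = coarse, fine = fine, n_test = n_test)
}
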