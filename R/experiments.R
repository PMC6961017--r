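# End-to-end experiment drivers at desk scale. Both experiments generate
# their own synthetic inputs, so they run offline and reproducibly from a
# single seed.

#' Oriented-edge verification experiment
#'
#' Generates `n_masks` smooth random blob masks, builds their superpixel
#' graphs (defaults `A = 400`, `D = 1`), labels nodes with the oriented-edge
#' soft targets at `theta = 0`, and trains the 2-layer verification network
#' (MSE, Adam, full batch). The trained network `Phi_0` is then rotated
#' analytically to each angle in `thetas` and evaluated against the
#' re-targeted datasets `D_theta`: a rotated network should beat the
#' unrotated one on every rotated target set, on every split.
#'
#' @param seed master seed (masks, initialization, training).
#' @param n_masks number of blob masks (>= 100; the first 100 are used).
#' @param size mask frame size `c(H, W)`.
#' @param thetas rotation angles (radians) to evaluate besides 0.
#' @param epochs,learning_rate,eval_interval training protocol.
#' @param config graph construction parameters.
#' @return a list with `fit` (the [gmmnet_train()] result) and `table`, a
#'   data frame with one row per (theta, split): columns `theta`, `split`,
#'   `n`, `mse_base` (`Phi_0` on `D_theta`) and `mse_rotated` (`Phi_theta`
#'   on `D_theta`).
#' @export
run_verification_experiment <- function(seed = 1, n_masks = 100,
                                        size = c(96, 128),
                                        thetas = c(3 * pi / 4, -pi / 2),
                                        epochs = 2000, learning_rate = 1e-3,
                                        eval_interval = 50,
                                        config = graph_config(A = 400, D = 1,
                                                              W = 1,
                                                              downscale = 1)) {
  masks <- lapply(seq_len(n_masks), function(i)
    gen_blob_mask(child_seed(seed, i, 6L), size))
  ds <- make_verification_dataset(masks, theta = 0, config = config)
  net <- init_glorot(build_architecture("verification"),
                     child_seed(seed, 0L, 7L))
  fit <- gmmnet_train(net, ds$graphs[ds$splits$train],
                      ds$graphs[ds$splits$val],
                      train_config(learning_rate = learning_rate,
                                   epochs = epochs,
                                   eval_interval = eval_interval,
                                   seed = child_seed(seed, 0L, 8L)))
  rows <- list()
  for (th in c(0, thetas)) {
    dth <- retarget_verification_dataset(ds, th)
    phi_th <- rotate_network(fit$network, th)
    for (sp in names(ds$splits)) {
      gs <- dth$graphs[dth$splits[[sp]]]
      rows[[length(rows) + 1]] <- data.frame(
        theta = th, split = sp, n = length(gs),
        mse_base = network_mse(fit$network, gs),
        mse_rotated = network_mse(phi_th, gs))
    }
  }
  list(fit = fit, table = do.call(rbind, rows))
}

#' Synthetic ear-detection experiment
#'
#' Generates a person-disjoint synthetic scene dataset with the target in
#' its basic orientation, trains the 4-layer main architecture on
#' mask-derived node targets (`W`-scaled), and evaluates argmax-node
#' detection against the enlarged ground-truth bounding box on each split.
#' The trained network is then applied to rotated versions of the test
#' scenes, alone and through an 11-angle rotation bank under the `max` and
#' `any` decision rules.
#'
#' @param seed master seed.
#' @param n_subjects,scenes_per_subject dataset size (default 50 x 3 = 150
#'   scenes).
#' @param size scene size `c(H, W)`.
#' @param config graph construction parameters (defaults `A = 256`, `D = 2`,
#'   `W = 100`, no downscaling: the scenes are already small).
#' @param iterations,learning_rate,batch_size,eval_interval training
#'   protocol (defaults: 2000 Adam steps at 1e-4 on mini-batches of 8
#'   graphs).
#' @param bank_count number of rotation-bank networks.
#' @param enlargement bounding-box enlargement in pixels (default
#'   `sqrt(A)`).
#' @return a list with `fit`, `accuracy` (data frame split/accuracy/n on
#'   unrotated scenes), `rotated` (data frame rule/accuracy/n on rotated
#'   test scenes, rules `phi0`, `max`, `any`), and `bank`.
#' @export
run_detection_experiment <- function(seed = 1, n_subjects = 50,
                                     scenes_per_subject = 3,
                                     size = c(96, 128),
                                     config = graph_config(A = 256, D = 2,
                                                           W = 100,
                                                           downscale = 1),
                                     iterations = 2000,
                                     learning_rate = 1e-4, batch_size = 8,
                                     eval_interval = 50, bank_count = 11,
                                     enlargement = sqrt(config$A)) {
  data <- gen_dataset(n_subjects, scenes_per_subject,
                      rotation_range = c(0, 0), seed = seed, size = size)
  graphs <- lapply(data$scenes, function(s)
    build_graph(s$image, s$mask, config))

  net <- init_glorot(build_architecture("main"), child_seed(seed, 0L, 9L))
  fit <- gmmnet_train(net, graphs[data$splits$train],
                      graphs[data$splits$val],
                      train_config(learning_rate = learning_rate,
                                   epochs = iterations,
                                   eval_interval = eval_interval,
                                   seed = child_seed(seed, 0L, 10L),
                                   batch_size = batch_size))

  hit_of <- function(net0, graph, scene)
    isTRUE(evaluate_hit(detect_node(network_forward(net0, graph), graph),
                        scene$bbox, enlargement))
  accuracy <- do.call(rbind, lapply(names(data$splits), function(sp) {
    idx <- data$splits[[sp]]
    hits <- vapply(idx, function(i)
      hit_of(fit$network, graphs[[i]], data$scenes[[i]]), logical(1))
    data.frame(split = sp, accuracy = detection_accuracy(hits),
               n = length(idx))
  }))

  # rotated test scenes: same subjects/specs, target rotated in-plane
  test_idx <- data$splits$test
  rot_angles <- with_seed(child_seed(seed, 0L, 11L),
                          runif(length(test_idx), -pi, pi))
  rot_scenes <- Map(function(i, a) {
    sp <- data$scenes[[i]]$spec
    sp$rotation <- a
    gen_scene(sp)
  }, test_idx, rot_angles)
  rot_graphs <- lapply(rot_scenes, function(s) build_graph(s$image, s$mask, config))

  bank <- rotation_bank(fit$network, bank_count)
  phi0_hits <- mapply(function(g, s) hit_of(fit$network, g, s),
                      rot_graphs, rot_scenes)
  max_hits <- mapply(function(g, s)
    isTRUE(evaluate_hit(ensemble_detect_max(bank, g), s$bbox, enlargement)),
    rot_graphs, rot_scenes)
  any_hits <- mapply(function(g, s)
    ensemble_detect_any(bank, g, s$bbox, enlargement),
    rot_graphs, rot_scenes)
  rotated <- data.frame(
    rule = c("phi0", "max", "any"),
    accuracy = c(detection_accuracy(phi0_hits),
                 detection_accuracy(max_hits),
                 detection_accuracy(any_hits)),
    n = length(test_idx))

  list(fit = fit, accuracy = accuracy, rotated = rotated, bank = bank,
       config = config, seed = seed)
}
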