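#' Easy-scene configuration for smoke-scale training
#'
#' A deliberately easy rendering regime — two large well-separated flowers
#' and one large bud per 160 px scene, plain canopy, no occlusion — used as
#' the functionality floor for end-to-end training: a correct
#' implementation should learn these scenes quickly, and failure indicates
#' a pipeline defect rather than a hard vision problem.
#'
#' @param seed Integer seed.
#' @param size Scene side in pixels (default 160).
#' @return A [scene_config()].
#' @export
easy_scene_config <- function(seed = 0L, size = 160L) {
  scene_config(
    width = size, height = size, n_flowers = 2, n_buds = 1,
    flower_size_range = c(0.375, 0.5625) * size,
    bud_size_range = c(0.2125, 0.3) * size,
    occlusion_prob = 0, background = "simple", seed = seed
  )
}

#' End-to-end smoke training benchmark
#'
#' Generates easy synthetic scenes, splits them 7:2:1, trains the
#' lightweight two-head variant from scratch at reduced scale, and scores
#' mAP@0.5 on the validation split. This exercises scene generation,
#' anchor clustering, the runtime, the loss, decoding, NMS and evaluation
#' in one pass.
#'
#' @param seed Master seed (scenes, split, initialisation, sampling).
#' @param n_images Number of scenes (default 40).
#' @param iterations Training iterations (default 300).
#' @param input_size Network input (default 160).
#' @param batch_size Batch size (default 2).
#' @param initial_lr Peak learning rate for the cosine schedule.
#' @param verbose Print training progress.
#' @return List with `map`, `f1`, `report` (the validation `eval_report`),
#'   `fit` (the `train_result`) and `val_images`.
#' @export
smoke_benchmark <- function(seed = 0L, n_images = 40L, iterations = 300L,
                            input_size = 160L, batch_size = 2L,
                            initial_lr = 0.003, verbose = FALSE) {
  cfg <- easy_scene_config(seed = seed, size = input_size)
  imgs <- lapply(seq_len(n_images), function(i) {
    ci <- cfg
    ci$seed <- (cfg$seed + i * 977L) %% 2147483647L
    s <- generate_scene(ci)
    s$image_id <- sprintf("scene_%03d", i)
    s
  })
  names(imgs) <- map_chr(imgs, "image_id")
  split <- split_dataset(names(imgs), seed = seed)
  tc <- train_config(input_size = input_size, batch_size = batch_size,
                     iterations = iterations, initial_lr = initial_lr,
                     mosaic = FALSE, seed = seed)
  graph <- build_architecture("yolov4_tiny_dw", num_classes = 2L,
                              input_size = input_size)
  fit <- train_detector(graph, imgs[split$train], tc,
                        gains = c(box = 3, obj = 1, cls = 1),
                        verbose = verbose)
  val <- imgs[split$val]
  dets <- detect_images(fit$model, val, fit$anchors, conf_threshold = 0.1,
                        nms_iou = 0.45)
  report <- evaluate_detections(dets, val)
  list(map = report$map, f1 = report$f1, report = report, fit = fit,
       val_images = val)
}
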