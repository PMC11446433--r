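# The packaged synthetic benchmark: fixed study conditions under which the
# pipeline's teacher-vs-student comparison is run and reported.

#' Scene parameters of the packaged benchmark
#'
#' 640 x 640 frames, 1-12 piglets per scene concentrated behind the sow,
#' 30% occlusion, mixed day/night illumination.
#'
#' @return a [scene_params()] object.
#' @export
benchmark_scene_params <- function() {
  scene_params(piglet_count_range = c(1, 12))
}

#' Generate the packaged benchmark corpus
#'
#' Three disjoint seeded synthetic datasets: 100 teacher training scenes,
#' 100 unlabeled pool scenes (their labels are withheld from the pipeline and
#' only used as evaluation ground truth would be), and 100 evaluation scenes.
#'
#' @param dir output directory.
#' @param master_seed integer master seed.
#' @param n_train,n_unlabeled,n_eval dataset sizes.
#' @return list of manifests `teacher`, `unlabeled`, `eval`.
#' @export
benchmark_corpus <- function(dir, master_seed = 1L,
                             n_train = 100L, n_unlabeled = 100L, n_eval = 100L) {
  p <- benchmark_scene_params()
  list(teacher = generate_dataset(p, n_train, derive_seed(master_seed, 101),
                                  file.path(dir, "teacher"), split = "train"),
       unlabeled = generate_dataset(p, n_unlabeled, derive_seed(master_seed, 202),
                                    file.path(dir, "unlabeled"), split = "train"),
       eval = generate_dataset(p, n_eval, derive_seed(master_seed, 303),
                               file.path(dir, "eval"), split = "eval"))
}

#' Pipeline configuration of the packaged benchmark
#'
#' Default stage settings: 0.9 pseudo-label confidence threshold, factor-four
#' flip expansion, student-side dropout and mixup noise at rate 0.5 each,
#' region-restricted evaluation at IoU 0.5.
#'
#' @param corpus output of [benchmark_corpus()].
#' @param out_dir pipeline output root.
#' @param master_seed integer master seed.
#' @return a [pipeline_config()].
#' @export
benchmark_config <- function(corpus, out_dir, master_seed = 1L) {
  pipeline_config(teacher_manifest = corpus$teacher,
                  unlabeled_manifest = corpus$unlabeled,
                  eval_manifest = corpus$eval,
                  out_dir = out_dir,
                  master_seed = master_seed)
}
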