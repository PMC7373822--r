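# End-to-end orchestration: histogram matching -> similarity graph ->
# template selection -> (optionally) network training with transfer ->
# mean-inverse initialization -> evaluation.

#' Pipeline configuration
#'
#' @param rho strong-connection threshold for graph coarsening.
#' @param template_mode `"coarsening"` (exemplars from
#'   [coarsen_multilevel()]), `"random"` (random exemplars, count matched to
#'   what coarsening yields) or `"single"` (only the central template).
#' @param backend `"oracle"` (ground-truth fields of a synthetic cohort),
#'   `"network"` (train the prediction network and use it), or a
#'   user-supplied `function(image_id, template_id) -> dispfield`.
#' @param regnet a [regnet_config()] used when `backend = "network"`.
#' @param train_ratio train fraction for [split_dataset()] (default 0.75).
#' @param structures named label map for evaluation.
#' @param histogram_levels quantile anchors for [histogram_match()].
#' @param max_iter,tol displacement inversion parameters.
#' @param transfer_epochs epochs for transfer-trained templates (defaults
#'   to the network config's epochs; `0` clones the central network's
#'   weights without fine-tuning).
#' @param transfer_n_pairs optional cap on the number of training pairs
#'   used per transfer-trained template. A few dozen optimizer steps
#'   suffice to adapt the batch-norm statistics to the new template (the
#'   weights barely move at the transfer learning rate), so reduced
#'   studies can transfer on a subset of pairs.
#' @param seed master seed for split/template randomness.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(rho = 0.95,
                            template_mode = c("coarsening", "random", "single"),
                            backend = "oracle", regnet = NULL,
                            train_ratio = 0.75,
                            structures = c(csf = 1, gm = 2, wm = 3,
                                           hippocampus = 4),
                            histogram_levels = 256,
                            max_iter = 30, tol = 0.01,
                            transfer_epochs = NULL, transfer_n_pairs = NULL,
                            seed = 1) {
  template_mode <- match.arg(template_mode)
  stop_if(!(rho > 0 && rho <= 1), "rho must lie in (0, 1]")
  if (is.character(backend)) {
    stop_if(!backend %in% c("oracle", "network"),
            "backend must be 'oracle', 'network' or a function")
  } else {
    stop_if(!is.function(backend), "backend must be a string or a function")
  }
  if (identical(backend, "network") && is.null(regnet)) regnet <- regnet_config()
  structure(list(rho = rho, template_mode = template_mode, backend = backend,
                 regnet = regnet, train_ratio = train_ratio,
                 structures = structures, histogram_levels = histogram_levels,
                 max_iter = max_iter, tol = tol,
                 transfer_epochs = transfer_epochs,
                 transfer_n_pairs = transfer_n_pairs, seed = as.integer(seed)),
            class = "pipeline_config")
}

# training pairs for one template from a synthetic cohort's true fields:
# guidance u_ij = compose(invert(f_i), f_j)
cohort_training_pairs <- function(images, template_id, ids, backend_fn) {
  lapply(ids, function(i) {
    training_pair(images[[i]], images[[template_id]], backend_fn(i, template_id))
  })
}

#' Run the full deformation-initialization pipeline on a cohort
#'
#' Stages: (1) histogram-match every image to the cohort's most central
#' image; (2) build the NCC similarity graph; (3) select exemplar templates
#' according to `cfg$template_mode`; (4) split the non-template images into
#' train/test; (5) for the network backend, train the central-template
#' network and transfer-train one network per remaining exemplar, using the
#' cohort's ground-truth fields as coarse guidance; (6) warp every image by
#' its mean-inverse initialization field; (7) evaluate alignment before and
#' after. Deterministic for a fixed config and cohort.
#'
#' @param cohort a `"phantom_cohort"` (or a list with named `images`,
#'   `labels`, `true_fields` entries of the same structure).
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory: warped images, reports and a run
#'   manifest are written there.
#' @return list with `report_before`, `report_after` ([evaluate_cohort()]
#'   reports), `exemplar_ids`, `central_id`, `coarsening`, `split`,
#'   `init` (the [initialize_cohort()] result) and `fits` (network
#'   backend only).
#' @export
run_pipeline <- function(cohort, cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  images <- cohort$images
  labels <- cohort$labels
  stop_if(length(images) < 2, "cohort must contain at least 2 images")
  ids <- names(images)
  log <- list()
  stage <- function(.stage_name, ...) {
    log[[length(log) + 1L]] <<- list(stage = .stage_name,
                                     time = format(Sys.time()), ...)
  }

  # 1. histogram matching to the most central raw image
  raw_graph <- build_graph(images, ids)
  central_raw <- select_central_template(raw_graph)
  matched <- lapply(images, histogram_match, reference = images[[central_raw]],
                    n_levels = cfg$histogram_levels)
  names(matched) <- ids
  stage("histogram_match", reference = central_raw)

  # 2. similarity graph on the matched cohort
  graph <- build_graph(matched, ids)
  stage("graph", n = length(ids))

  # 3. template selection
  coars <- coarsen_multilevel(graph, rho = cfg$rho)
  exemplars <- switch(cfg$template_mode,
    coarsening = coars$exemplar_ids,
    random = random_exemplars(ids, length(coars$exemplar_ids),
                              seed = cfg$seed + 17L),
    single = select_central_template(graph, coars$exemplar_ids))
  central <- select_central_template(graph, exemplars)
  stage("templates", mode = cfg$template_mode, exemplars = exemplars,
        central = central)

  # 4. train/test split of the non-template images
  non_templates <- setdiff(ids, exemplars)
  split <- if (length(non_templates) >= 2) {
    split_dataset(non_templates, ratio = cfg$train_ratio, seed = cfg$seed)
  } else {
    list(train = non_templates, test = character(0))
  }
  stage("split", train = length(split$train), test = length(split$test))

  # 5. registration backend
  truth <- oracle_backend(cohort$true_fields, max_iter = cfg$max_iter,
                          tol = cfg$tol)
  fits <- NULL
  backend <- if (is.function(cfg$backend)) {
    cfg$backend
  } else if (identical(cfg$backend, "oracle")) {
    truth
  } else {
    rcfg <- cfg$regnet
    pairs_central <- cohort_training_pairs(matched, central, split$train, truth)
    fits <- list()
    fits[[central]] <- train_regnet(pairs_central, rcfg)
    transfer_ids <- if (is.null(cfg$transfer_n_pairs)) split$train else
      head(split$train, cfg$transfer_n_pairs)
    for (j in setdiff(exemplars, central)) {
      pairs_j <- cohort_training_pairs(matched, j, transfer_ids, truth)
      fits[[j]] <- transfer_train(fits[[central]], pairs_j, rcfg,
                                  epochs = cfg$transfer_epochs)
    }
    stage("train", templates = exemplars, epochs = rcfg$epochs)
    regnet_backend(fits, matched)
  }

  # 6. mean-inverse initialization of the whole cohort
  init <- initialize_cohort(matched, backend, exemplars, labels = labels,
                            max_iter = cfg$max_iter, tol = cfg$tol)
  stage("initialize", n = length(init$warped))

  # 7. evaluation before and after
  report_before <- evaluate_cohort(matched, labels, cfg$structures)
  report_after <- evaluate_cohort(init$warped, init$warped_labels, cfg$structures)
  stage("evaluate")

  res <- list(report_before = report_before, report_after = report_after,
              exemplar_ids = exemplars, central_id = central,
              coarsening = coars, split = split, init = init, fits = fits,
              log = log, cfg = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in ids) {
      write_volume(init$warped[[id]], file.path(out_dir, paste0(id, "_warped.nii.gz")))
      write_field(init$init_fields[[id]], file.path(out_dir, paste0(id, "_init.nii.gz")))
    }
    write_report(report_after, file.path(out_dir, "report_after.csv"),
                 file.path(out_dir, "report_after.json"))
    write_report(report_before, file.path(out_dir, "report_before.csv"),
                 file.path(out_dir, "report_before.json"))
    jsonlite::write_json(list(exemplars = exemplars, central = central,
                              template_mode = cfg$template_mode,
                              rho = cfg$rho, seed = cfg$seed, log = log),
                         file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  }
  res
}

#' Cross-cohort generalization experiment
#'
#' Trains the registration network on one cohort and evaluates
#' initialization on a second, unseen cohort; then repeats with the union
#' of both cohorts as training data. Mirrors a train-on-A / test-on-B
#' design with shared latent anatomy but disjoint individuals.
#'
#' @param train_cohort,test_cohort `"phantom_cohort"` objects on one grid
#'   (typically sharing prototypes via equal specs but different seeds).
#' @param cfg a [pipeline_config()] with a network backend configuration in
#'   `cfg$regnet`.
#' @return list of two experiment results, each with the test cohort's
#'   evaluation report after initialization and the mean held-out endpoint
#'   error of the predicted fields, under `train_A` and `train_AB`.
#' @export
run_generalization <- function(train_cohort, test_cohort, cfg = pipeline_config(
                                 backend = "network", regnet = tiny_regnet_config())) {
  rcfg <- cfg$regnet %||% tiny_regnet_config()
  run_one <- function(train_images, train_fields, tag) {
    graph <- build_graph(train_images)
    central <- select_central_template(graph)
    truth <- oracle_backend(train_fields, max_iter = cfg$max_iter, tol = cfg$tol)
    train_ids <- setdiff(names(train_images), central)
    pairs <- cohort_training_pairs(train_images, central, train_ids, truth)
    fit <- train_regnet(pairs, rcfg)
    # evaluate on the unseen cohort: predict toward the trained template
    test_truth <- oracle_backend(
      c(test_cohort$true_fields, train_fields[central]),
      max_iter = cfg$max_iter, tol = cfg$tol)
    epe <- vapply(names(test_cohort$images), function(i) {
      pred <- predict_field(fit, test_cohort$images[[i]])
      endpoint_error(pred, test_truth(i, central),
                     mask = interior_mask(pred$reference_shape, 6))
    }, 0)
    zero_epe <- vapply(names(test_cohort$images), function(i) {
      endpoint_error(zero_field(dim(test_cohort$images[[i]]$data)),
                     test_truth(i, central),
                     mask = interior_mask(dim(test_cohort$images[[i]]$data), 6))
    }, 0)
    backend <- function(image_id, template_id) predict_field(fit, test_cohort$images[[image_id]])
    init <- initialize_cohort(test_cohort$images, backend, central,
                              labels = test_cohort$labels,
                              max_iter = cfg$max_iter, tol = cfg$tol)
    report <- evaluate_cohort(init$warped, init$warped_labels, cfg$structures)
    list(tag = tag, central = central, mean_epe = mean(epe),
         zero_field_epe = mean(zero_epe), report = report)
  }
  a <- run_one(train_cohort$images, train_cohort$true_fields, "train_A")
  ab_images <- c(train_cohort$images, test_cohort$images)
  ab_fields <- c(train_cohort$true_fields, test_cohort$true_fields)
  names(ab_images) <- make.unique(names(ab_images))
  names(ab_fields) <- names(ab_images)
  b <- run_one(ab_images, ab_fields, "train_AB")
  list(train_A = a, train_AB = b)
}
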