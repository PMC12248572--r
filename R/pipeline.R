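# End-to-end workflow: generate (or ingest) images -> condition -> extract
# multifractal descriptors -> cross-validated classification report.

#' Generate a balanced set of two-class phantom images
#'
#' @param n_per_class phantoms per class.
#' @param image_side phantom side in pixels.
#' @param seed base seed; phantom i of each class uses `seed + i` (DR) or
#'   `seed + n_per_class + i` (Normal), keeping every image reproducible.
#' @param out_dir optional directory to write `DR_<i>.png` /
#'   `Normal_<i>.png` files.
#' @return named list of grayscale matrices (names `DR_1`, ..,
#'   `Normal_1`, ..), invisibly written to `out_dir` when given.
#' @export
generate_phantoms <- function(n_per_class, image_side = 256, seed = 42,
                              out_dir = NULL) {
  images <- list()
  for (cl in c("DR", "Normal")) {
    off <- if (cl == "DR") 0L else n_per_class
    for (i in seq_len(n_per_class)) {
      sp <- phantom_spec(cl, image_side = image_side,
                         seed = seed + off + i)
      images[[paste0(cl, "_", i)]] <- make_retina_phantom(sp)
    }
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(images))
      write_gray_image(images[[nm]], file.path(out_dir, paste0(nm, ".png")))
  }
  images
}

#' Run the full synthetic demonstration study
#'
#' Generates `n_per_class` phantoms per class, conditions each image
#' (Gaussian blur + CLAHE), binarizes, extracts the nine multifractal
#' descriptors and evaluates the requested classifiers under stratified
#' k-fold cross-validation.
#'
#' @param n_per_class phantoms per class (default 100, i.e. a 200-image
#'   study).
#' @param image_side phantom side in pixels.
#' @param seed seed controlling phantom generation and fold assignment.
#' @param models forwarded to [run_experiment()] (default `"mlp"`).
#' @param k folds.
#' @param out_dir optional directory for artifacts (`features.csv`,
#'   `report.json`, tables, resolved config).
#' @return list with `features` (the feature table) and `report` (an
#'   `evaluation_report`).
#' @export
run_demo <- function(n_per_class = 100, image_side = 256, seed = 42,
                     models = "mlp", k = 5, out_dir = NULL) {
  config <- preprocess_config()
  images <- generate_phantoms(n_per_class, image_side = image_side,
                              seed = seed)
  labels <- ifelse(grepl("^DR", names(images)), "DR", "Normal")
  features <- analyze_images(images, labels = labels, config = config)
  report <- run_experiment(features, models = models, k = k, seed = seed,
                           out_dir = out_dir)
  if (!is.null(out_dir)) {
    write_feature_table(features, file.path(out_dir, "features.csv"))
    resolved <- list(n_per_class = n_per_class, image_side = image_side,
                     seed = seed, models = names(report), k = k,
                     preprocess = unclass(config))
    writeLines(jsonlite::toJSON(resolved, auto_unbox = TRUE, pretty = TRUE,
                                null = "null"),
               file.path(out_dir, "config.json"))
  }
  list(features = features, report = report)
}

#' Run a configured pipeline
#'
#' Executes the workflow stages in order — generate, preprocess, analyze,
#' evaluate — as driven by a configuration list (or JSON/YAML-like file
#' readable by [jsonlite::read_json()]). Supported fields: `seed`,
#' `out_dir`, `generate` (`n_per_class`, `image_side`), `in_dir` (existing
#' images instead of generation), `preprocess` (arguments of
#' [preprocess_config()]), `analyze` (`q_min`, `q_max`, `q_step`,
#' `min_box`, `alpha_center_mode`), `evaluate` (`models`, `k`). Every run
#' writes the resolved configuration next to its outputs.
#'
#' @param config list or path to a JSON config file.
#' @return list with `features` and `report` (when the evaluate stage ran).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  seed <- config$seed %||% 42
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must provide `out_dir`", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pc <- do.call(preprocess_config, as.list(config$preprocess))

  t0 <- Sys.time()
  if (!is.null(config$generate)) {
    g <- config$generate
    images <- generate_phantoms(g$n_per_class %||% 100,
                                image_side = g$image_side %||% 256,
                                seed = seed,
                                out_dir = file.path(out_dir, "phantoms"))
    labels <- ifelse(grepl("^DR", names(images)), "DR", "Normal")
  } else if (!is.null(config$in_dir)) {
    if (!dir.exists(config$in_dir))
      stop("input directory not found: ", config$in_dir, call. = FALSE)
    images <- config$in_dir
    labels <- NULL
  } else stop("config must provide either `generate` or `in_dir`",
              call. = FALSE)
  message(sprintf("[generate/ingest] %.1fs", difftime(Sys.time(), t0,
                                                      units = "secs")))

  az <- as.list(config$analyze)
  q_grid <- default_qgrid(az$q_min %||% -5, az$q_max %||% 5,
                          az$q_step %||% 0.25)
  t1 <- Sys.time()
  features <- analyze_images(images, labels = labels, config = pc,
                             q_grid = q_grid,
                             alpha_center_mode = az$alpha_center_mode %||%
                               "argmax_f")
  write_feature_table(features, file.path(out_dir, "features.csv"))
  message(sprintf("[analyze] %d images, %.1fs", nrow(features),
                  difftime(Sys.time(), t1, units = "secs")))

  report <- NULL
  if (!is.null(config$evaluate) || is.null(config$skip_evaluate)) {
    ev <- as.list(config$evaluate)
    t2 <- Sys.time()
    report <- run_experiment(features, models = ev$models %||% "all",
                             k = ev$k %||% 5, seed = seed, out_dir = out_dir)
    message(sprintf("[evaluate] %d models, %.1fs", length(report),
                    difftime(Sys.time(), t2, units = "secs")))
  }
  resolved <- config
  resolved$seed <- seed
  resolved$preprocess <- unclass(pc)
  writeLines(jsonlite::toJSON(resolved, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             file.path(out_dir, "config.json"))
  list(features = features, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
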