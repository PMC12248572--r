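# Feature-table I/O. The canonical on-disk format is a CSV with the exact
# header ID,Db,Di,Dc,alpha_min,alpha_max,alpha_center,f_alpha_max,
# spectrum_width,symmetric_shift,class — shared by the synthetic sampler,
# the batch analyzer and the evaluation stage.

#' Write a feature table to CSV
#'
#' @param tab data.frame with the canonical columns (`ID`, the nine
#'   descriptors, `class`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tab, path) {
  validate_feature_table(tab)
  utils::write.csv(tab[, .octmf_table_header], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path with the canonical header.
#' @return validated data.frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(tab), .octmf_table_header))
    stop("malformed feature CSV: expected header ",
         paste(.octmf_table_header, collapse = ","), call. = FALSE)
  validate_feature_table(tab)
  tab
}

#' Validate a feature table
#'
#' Checks column presence, absence of missing values, unique IDs and at
#' least two rows per class.
#'
#' @param tab data.frame.
#' @return `tab`, invisibly.
#' @export
validate_feature_table <- function(tab) {
  missing_cols <- setdiff(.octmf_table_header, names(tab))
  if (length(missing_cols))
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad <- which(!stats::complete.cases(tab[, .octmf_table_header]))
  if (length(bad))
    stop("feature table has missing values in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$ID))
    stop("feature table IDs must be unique", call. = FALSE)
  counts <- table(tab$class)
  if (length(counts) < 2 || any(counts < 2))
    stop("feature table needs >= 2 rows in each of two classes", call. = FALSE)
  invisible(tab)
}

#' Analyze a directory (or list) of images into a feature table
#'
#' Each image is conditioned with [preprocess_image()] (unless
#' `preprocess = FALSE`, for images already processed), binarized, and passed
#' through [extract_features()]. Class labels are taken from the `labels`
#' argument or guessed from filenames containing `DR`/`Normal`.
#'
#' @param images either a directory path or a named list of matrices.
#' @param labels optional character vector of class labels per image.
#' @param config a [preprocess_config()].
#' @param preprocess apply blur + CLAHE before binarization (default `TRUE`;
#'   binary inputs are analyzed as-is either way).
#' @param scales,q_grid,alpha_center_mode forwarded to [extract_features()].
#' @return feature table data.frame with the canonical columns.
#' @export
analyze_images <- function(images, labels = NULL,
                           config = preprocess_config(), preprocess = TRUE,
                           scales = NULL, q_grid = NULL,
                           alpha_center_mode = "argmax_f") {
  if (is.character(images) && length(images) == 1) {
    files <- sort(list.files(images, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no image files found in ", images, call. = FALSE)
    ids <- sub("\\.[^.]*$", "", basename(files))
    images <- lapply(files, read_gray_image)
    names(images) <- ids
  }
  ids <- names(images)
  if (is.null(ids)) ids <- as.character(seq_along(images))
  if (is.null(labels)) {
    labels <- ifelse(grepl("dr", ids, ignore.case = TRUE), "DR",
                     ifelse(grepl("normal", ids, ignore.case = TRUE),
                            "Normal", NA_character_))
    if (anyNA(labels))
      stop("cannot infer class labels from image names; supply `labels`",
           call. = FALSE)
  }
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (!all(img %in% c(0, 1)) && preprocess)
      img <- preprocess_image(img, config)
    ft <- extract_features(img, config = config, scales = scales,
                           q_grid = q_grid,
                           alpha_center_mode = alpha_center_mode, id = ids[i])
    rows[[i]] <- as.data.frame(ft)
  }
  tab <- do.call(rbind, rows)
  tab <- cbind(ID = ids, tab, class = labels)
  rownames(tab) <- NULL
  tab
}
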