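SCHEMA_VERSION <- 1L

#' The pelvic fracture taxonomy
#'
#' The seven fracture patterns with saliency for Tile AO/OTA grading:
#' pubic symphysis diastasis (`psd`), anteriorly divergent and parallel
#' sacroiliac joint diastasis, non-diastatic and diastatic sacral fracture,
#' ischial spine avulsion, and remaining pelvic ring fractures (`ring_fx`).
#' The ordering is fixed and used for deterministic tie-breaking throughout.
#'
#' @return Character vector of the 7 fracture type codes, in canonical order.
#' @export
fracture_types <- function() {
  c("psd", "si_anterior_divergent", "si_parallel", "sacral_nondiastatic",
    "sacral_diastatic", "isp_avulsion", "ring_fx")
}

detection_columns <- function() {
  c("patient_id", "augmentation_id", "slice_index",
    "x_min", "y_min", "x_max", "y_max", "fracture_type", "network_score")
}

empty_detections <- function() {
  data.frame(patient_id = character(), augmentation_id = integer(),
             slice_index = integer(), x_min = numeric(), y_min = numeric(),
             x_max = numeric(), y_max = numeric(), fracture_type = character(),
             network_score = numeric(), stringsAsFactors = FALSE)
}

#' Assemble and validate a table of 2D detections
#'
#' One row per detector box on one MIP slice of one augmented scan. Boxes are
#' 0-based half-open pixel rectangles; a box on slice `s` occupies
#' `z in [s, s + 1)` so adjacency and 3D intersection tests are uniform.
#'
#' @param df data.frame with columns `patient_id`, `augmentation_id`,
#'   `slice_index`, `x_min`, `y_min`, `x_max`, `y_max`, `fracture_type`,
#'   `network_score`.
#' @return The validated data.frame (canonical column order and types).
#' @export
as_detections <- function(df) {
  miss <- setdiff(detection_columns(), names(df))
  if (length(miss))
    stop("missing detection columns: ", paste(miss, collapse = ", "))
  df <- df[detection_columns()]
  df$patient_id <- as.character(df$patient_id)
  df$augmentation_id <- as.integer(df$augmentation_id)
  df$slice_index <- as.integer(df$slice_index)
  df$fracture_type <- as.character(df$fracture_type)
  bad <- !(df$fracture_type %in% fracture_types())
  if (any(bad))
    stop("unknown fracture_type: ", paste(unique(df$fracture_type[bad]), collapse = ", "))
  if (any(df$slice_index < 0L)) stop("negative slice_index")
  if (any(df$augmentation_id < 0L)) stop("negative augmentation_id")
  if (any(df$x_min >= df$x_max) || any(df$y_min >= df$y_max))
    stop("degenerate box: need x_min < x_max and y_min < y_max")
  if (any(df$network_score < 0 | df$network_score > 1))
    stop("network_score outside [0, 1]")
  rownames(df) <- NULL
  df
}

#' Read and write detection records as JSON-lines
#'
#' One JSON object per line with a `schema_version` field; a leading
#' provenance record (config hash, seed) may be embedded by the pipeline and
#' is skipped on read. Round-trips are lossless, including bit-exact box
#' coordinates.
#'
#' @param path file path.
#' @return `read_detections()` returns a validated detections data.frame.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines_idx <- which(nzchar(trimws(lines)))
  if (!length(lines_idx)) return(empty_detections())
  recs <- vector("list", length(lines_idx))
  keep <- logical(length(lines_idx))
  for (i in seq_along(lines_idx)) {
    ln <- lines_idx[i]
    rec <- tryCatch(jsonlite::fromJSON(lines[ln]),
                    error = function(e) stop("malformed detection record at line ",
                                             ln, ": ", conditionMessage(e)))
    if (identical(rec$record, "provenance")) next
    miss <- setdiff(detection_columns(), names(rec))
    if (length(miss))
      stop("malformed detection record at line ", ln,
           ": missing field(s) ", paste(miss, collapse = ", "))
    if (!rec$fracture_type %in% fracture_types())
      stop("unknown fracture_type at line ", ln, ": ", rec$fracture_type)
    recs[[i]] <- rec[detection_columns()]
    keep[i] <- TRUE
  }
  if (!any(keep)) return(empty_detections())
  df <- do.call(rbind, lapply(recs[keep], function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  as_detections(df)
}

#' @rdname read_detections
#' @param detections a detections data.frame (see [as_detections()]).
#' @param provenance optional named list (e.g. config hash and seed) written
#'   as a leading provenance record.
#' @export
write_detections <- function(detections, path, provenance = NULL) {
  detections <- as_detections(detections)
  con <- file(path, open = "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(jsonlite::toJSON(
      c(list(record = "provenance", schema_version = SCHEMA_VERSION), provenance),
      auto_unbox = TRUE, digits = I(17)), con)
  }
  if (nrow(detections)) {
    detections$schema_version <- SCHEMA_VERSION
    # stream_out writes ndjson; 17 significant digits keep coordinates bit-exact
    jsonlite::stream_out(detections, con, verbose = FALSE, digits = I(17))
  }
  invisible(path)
}

patient_truth_columns <- function() {
  c(paste0("truth_", fracture_types()), "truth_R", "truth_T")
}

#' Read and write the patient table
#'
#' CSV with columns `patient_id`, `age_years`, and optionally the boolean
#' ground-truth columns `truth_<fracture type>`, `truth_R`, `truth_T`
#' (present for labeled or synthetic patients, absent otherwise). Lines
#' starting with `#` are treated as provenance comments.
#'
#' @param path CSV file path.
#' @return `read_patients()` returns a data.frame of patient records.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("patient_id", "age_years") %in% names(df)))
    stop("patient CSV must have `patient_id` and `age_years` columns")
  df$patient_id <- as.character(df$patient_id)
  df$age_years <- suppressWarnings(as.integer(df$age_years))
  if (any(is.na(df$age_years))) stop("non-integer age_years")
  if (any(df$age_years < 0L)) stop("negative age_years")
  for (col in intersect(patient_truth_columns(), names(df))) {
    v <- df[[col]]
    if (!all(v %in% c(0L, 1L, NA)))
      stop("label column ", col, " must be 0/1")
    df[[col]] <- as.integer(v)
  }
  df$schema_version <- NULL
  df
}

#' @rdname read_patients
#' @param patients a patient data.frame.
#' @param provenance optional named list written as a `#` comment header.
#' @export
write_patients <- function(patients, path, provenance = NULL) {
  if (!all(c("patient_id", "age_years") %in% names(patients)))
    stop("patient table must have `patient_id` and `age_years`")
  con <- file(path, open = "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# provenance: ",
                      paste(names(provenance), unlist(provenance),
                            sep = "=", collapse = " ")), con)
  patients$schema_version <- SCHEMA_VERSION
  write.csv(patients, con, row.names = FALSE)
  invisible(path)
}
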