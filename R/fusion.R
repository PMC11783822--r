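#' Confidence thresholds governing detection sets and refinement
#'
#' @param keep_2d 2D detections with network score strictly above this are
#'   kept before fusion (default 0.5).
#' @param z_high high operating point on the frequency score defining the
#'   high-specificity finding set `FXhigh` (default 0.8).
#' @param z_low lower threshold defining the candidate set `FXlow`;
#'   `z_low <= z_high` (default 0.5).
#' @param z_star acceptance threshold on the Bayesian model's conditional
#'   probability for adding a low-confidence fracture during refinement
#'   (default 0.5).
#' @return A `thresholds` object.
#' @export
thresholds <- function(keep_2d = 0.5, z_high = 0.8, z_low = 0.5, z_star = 0.5) {
  if (z_low < 0 || z_high > 1 || z_low > z_high)
    stop("need 0 <= z_low <= z_high <= 1")
  if (z_star < 0)
    stop("z_star must be >= 0")
  structure(list(keep_2d = keep_2d, z_high = z_high,
                 z_low = z_low, z_star = z_star),
            class = "thresholds")
}

# half-open interval overlap: [a1, a2) and [b1, b2)
intervals_overlap <- function(a1, a2, b1, b2) a1 < b2 & b1 < a2

# connected component membership from an edge list over n vertices
component_membership <- function(n, edges) {
  if (n == 0L) return(integer())
  if (!nrow(edges)) return(seq_len(n))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(as.matrix(edges)))
  igraph::components(g)$membership
}

fracture3d_columns <- function() {
  c("patient_id", "augmentation_id", "x_min", "y_min", "z_min",
    "x_max", "y_max", "z_max", "fracture_type", "score", "n_constituents")
}

# order components deterministically by (type order, z_min, y_min, x_min)
order_findings <- function(df) {
  order(match(df$fracture_type, fracture_types()),
        df$z_min, df$y_min, df$x_min)
}

#' Fuse 2D detections of one augmented scan into 3D fractures
#'
#' Discards detections with network score at or below `keep_2d`, then links
#' two kept detections when they share a fracture type, their in-plane boxes
#' intersect (nonempty half-open overlap), and they lie on the same or
#' adjacent slices. Each connected component becomes one 3D fracture: its
#' cuboid is the minimal axis-aligned box containing all constituent boxes
#' (a box on slice `s` spans `z in [s, s + 1)`) and its score the maximum
#' constituent network score.
#'
#' @param detections detections of a single patient and single augmented
#'   scan (see [as_detections()]).
#' @param keep_2d strict keep threshold on the 2D network score.
#' @return A data.frame of 3D fractures, deterministically ordered by
#'   (fracture type order, z_min, y_min, x_min), with a `constituents`
#'   list-column of row indices into `detections`.
#' @export
fuse_2d_to_3d <- function(detections, keep_2d = 0.5) {
  detections <- as_detections(detections)
  if (length(unique(detections$augmentation_id)) > 1L)
    stop("detections mix several augmentation_ids; fuse one augmented scan at a time")
  if (length(unique(detections$patient_id)) > 1L)
    stop("detections mix several patient_ids")
  fuse_2d_grouped(detections, keep_2d)
}

# shared worker: edge rule additionally requires equal augmentation_id, so a
# whole patient (all augmented scans) can be fused in one components pass
fuse_2d_grouped <- function(detections, keep_2d) {
  keep <- which(detections$network_score > keep_2d)
  d <- detections[keep, , drop = FALSE]
  n <- nrow(d)
  empty <- cbind(empty_fracture3d(), data.frame(constituents = I(list())))
  if (n == 0L) return(empty)
  # candidate pairs within (augmentation, type) groups only
  grp <- paste(d$augmentation_id, d$fracture_type)
  idx_by_grp <- split(seq_len(n), grp)
  edges <- do.call(rbind, lapply(idx_by_grp, function(idx) {
    m <- length(idx)
    if (m < 2L) return(NULL)
    pr <- t(utils::combn(m, 2L))
    i <- idx[pr[, 1]]; j <- idx[pr[, 2]]
    ok <- abs(d$slice_index[i] - d$slice_index[j]) <= 1L &
      intervals_overlap(d$x_min[i], d$x_max[i], d$x_min[j], d$x_max[j]) &
      intervals_overlap(d$y_min[i], d$y_max[i], d$y_min[j], d$y_max[j])
    cbind(i[ok], j[ok])
  }))
  if (is.null(edges)) edges <- matrix(integer(), ncol = 2)
  memb <- component_membership(n, as.data.frame(edges))
  comp <- split(seq_len(n), memb)
  out <- data.frame(
    patient_id = vapply(comp, function(ii) d$patient_id[ii[1]], character(1)),
    augmentation_id = vapply(comp, function(ii) d$augmentation_id[ii[1]], integer(1)),
    x_min = vapply(comp, function(ii) min(d$x_min[ii]), numeric(1)),
    y_min = vapply(comp, function(ii) min(d$y_min[ii]), numeric(1)),
    z_min = vapply(comp, function(ii) min(d$slice_index[ii]), numeric(1)),
    x_max = vapply(comp, function(ii) max(d$x_max[ii]), numeric(1)),
    y_max = vapply(comp, function(ii) max(d$y_max[ii]), numeric(1)),
    z_max = vapply(comp, function(ii) max(d$slice_index[ii]) + 1, numeric(1)),
    fracture_type = vapply(comp, function(ii) d$fracture_type[ii[1]], character(1)),
    score = vapply(comp, function(ii) max(d$network_score[ii]), numeric(1)),
    n_constituents = lengths(comp),
    stringsAsFactors = FALSE)
  out$constituents <- I(lapply(comp, function(ii) keep[ii]))
  out <- out[order_findings(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_fracture3d <- function() {
  data.frame(patient_id = character(), augmentation_id = integer(),
             x_min = numeric(), y_min = numeric(), z_min = numeric(),
             x_max = numeric(), y_max = numeric(), z_max = numeric(),
             fracture_type = character(), score = numeric(),
             n_constituents = integer(), stringsAsFactors = FALSE)
}

#' Fuse 3D fractures across augmented scans
#'
#' Links two 3D fractures (possibly from different augmented scans) when
#' they share a fracture type and their cuboids intersect on all three axes
#' (half-open). Each connected component becomes one fused finding whose
#' cuboid is the smallest cuboid containing all member cuboids, and whose
#' confidence is the frequency score: the number of distinct augmented scans
#' contributing at least one member, divided by `K`.
#'
#' @param fractures 3D fracture data.frame (rows as from [fuse_2d_to_3d()],
#'   possibly concatenated over augmentations) of one patient.
#' @param K total number of augmented scans (scans with no detections count
#'   in the denominator).
#' @return A data.frame of fused findings with columns `fracture_type`,
#'   cuboid bounds, `frequency`, `n_augmentations`, and list-columns
#'   `augmentations` (sorted distinct contributing scan ids) and `members`
#'   (row indices into `fractures`).
#' @export
fuse_across_scans <- function(fractures, K) {
  if (!is.numeric(K) || length(K) != 1L || K <= 0 || K != round(K))
    stop("`K` must be a positive integer")
  K <- as.integer(K)
  n <- nrow(fractures)
  if (n && (any(fractures$augmentation_id < 0L) ||
            any(fractures$augmentation_id >= K)))
    stop("augmentation_id outside [0, K)")
  if (n == 0L) {
    out <- data.frame(patient_id = character(), fracture_type = character(),
                      x_min = numeric(), y_min = numeric(), z_min = numeric(),
                      x_max = numeric(), y_max = numeric(), z_max = numeric(),
                      frequency = numeric(), n_augmentations = integer(),
                      stringsAsFactors = FALSE)
    out$augmentations <- I(list()); out$members <- I(list())
    return(out)
  }
  idx_by_type <- split(seq_len(n), fractures$fracture_type)
  edges <- do.call(rbind, lapply(idx_by_type, function(idx) {
    m <- length(idx)
    if (m < 2L) return(NULL)
    pr <- t(utils::combn(m, 2L))
    i <- idx[pr[, 1]]; j <- idx[pr[, 2]]
    ok <- intervals_overlap(fractures$x_min[i], fractures$x_max[i],
                            fractures$x_min[j], fractures$x_max[j]) &
      intervals_overlap(fractures$y_min[i], fractures$y_max[i],
                        fractures$y_min[j], fractures$y_max[j]) &
      intervals_overlap(fractures$z_min[i], fractures$z_max[i],
                        fractures$z_min[j], fractures$z_max[j])
    cbind(i[ok], j[ok])
  }))
  if (is.null(edges)) edges <- matrix(integer(), ncol = 2)
  memb <- component_membership(n, as.data.frame(edges))
  comp <- split(seq_len(n), memb)
  augs <- lapply(comp, function(ii) sort(unique(fractures$augmentation_id[ii])))
  out <- data.frame(
    patient_id = vapply(comp, function(ii) fractures$patient_id[ii[1]], character(1)),
    fracture_type = vapply(comp, function(ii) fractures$fracture_type[ii[1]], character(1)),
    x_min = vapply(comp, function(ii) min(fractures$x_min[ii]), numeric(1)),
    y_min = vapply(comp, function(ii) min(fractures$y_min[ii]), numeric(1)),
    z_min = vapply(comp, function(ii) min(fractures$z_min[ii]), numeric(1)),
    x_max = vapply(comp, function(ii) max(fractures$x_max[ii]), numeric(1)),
    y_max = vapply(comp, function(ii) max(fractures$y_max[ii]), numeric(1)),
    z_max = vapply(comp, function(ii) max(fractures$z_max[ii]), numeric(1)),
    frequency = vapply(augs, function(a) frequency_score(a, K), numeric(1)),
    n_augmentations = lengths(augs),
    stringsAsFactors = FALSE)
  out$augmentations <- I(augs)
  out$members <- I(comp)
  out <- out[order_findings(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Frequency confidence score of a fused finding
#'
#' The fraction of augmented scans in which a fused 3D finding appears:
#' distinct contributing scans divided by `K`. Several member fractures in
#' the same augmented scan count once.
#'
#' @param augmentation_ids scan ids of the finding's member 3D fractures.
#' @param K total number of augmented scans.
#' @return The frequency in `{0/K, 1/K, ..., K/K}`.
#' @export
frequency_score <- function(augmentation_ids, K) {
  if (K <= 0) stop("`K` must be positive")
  length(unique(augmentation_ids)) / K
}

#' Per-type existence confidence
#'
#' The confidence that each fracture type is present in the scan: the
#' maximum frequency score over fused findings of that type, 0 for types
#' with no finding.
#'
#' @param fused fused findings from [fuse_across_scans()].
#' @return Named numeric vector over all 7 fracture types.
#' @export
type_confidence <- function(fused) {
  conf <- setNames(numeric(length(fracture_types())), fracture_types())
  if (nrow(fused)) {
    mx <- tapply(fused$frequency, fused$fracture_type, max)
    conf[names(mx)] <- mx
  }
  conf
}

#' High- and low-confidence detection sets
#'
#' Thresholds the per-type confidences: `FXhigh` holds types with confidence
#' at least `z_high`, `FXlow` those at least `z_low`. Since
#' `z_low <= z_high`, `FXhigh` is always a subset of `FXlow`.
#'
#' @param confidences named per-type confidence vector ([type_confidence()]).
#' @param th a [thresholds()] object.
#' @return List with character vectors `high` and `low` (canonical type order).
#' @export
detect_sets <- function(confidences, th = thresholds()) {
  stopifnot(inherits(th, "thresholds"))
  types <- fracture_types()
  conf <- confidences[types]
  conf[is.na(conf)] <- 0
  list(high = types[conf >= th$z_high],
       low = types[conf >= th$z_low])
}

#' Fuse all detections of one patient end to end
#'
#' Runs the per-scan 2D-to-3D fusion for every augmented scan and then the
#' cross-scan fusion, in a single grouped pass (equivalent to looping
#' [fuse_2d_to_3d()] over scans and calling [fuse_across_scans()]).
#'
#' @param detections all detections of one patient across its `K` scans.
#' @param K number of augmented scans.
#' @param keep_2d strict 2D keep threshold.
#' @return Fused findings as from [fuse_across_scans()].
#' @export
fuse_patient <- function(detections, K, keep_2d = 0.5) {
  detections <- as_detections(detections)
  if (length(unique(detections$patient_id)) > 1L)
    stop("detections mix several patient_ids")
  if (nrow(detections) && any(detections$augmentation_id >= K))
    stop("augmentation_id outside [0, K)")
  f3d <- fuse_2d_grouped(detections, keep_2d)
  fuse_across_scans(f3d, K)
}

#' Export fused findings as JSON-lines
#'
#' Writes one record per fused finding: cuboid, type, frequency, and the
#' per-augmentation constituent counts, for downstream visualization and
#' audit.
#'
#' @param fused fused findings from [fuse_across_scans()].
#' @param path output file.
#' @param provenance optional named list written as a leading record.
#' @export
write_fused <- function(fused, path, provenance = NULL) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(jsonlite::toJSON(
      c(list(record = "provenance", schema_version = SCHEMA_VERSION), provenance),
      auto_unbox = TRUE, digits = I(17)), con)
  for (i in seq_len(nrow(fused))) {
    counts <- table(fused$augmentations[[i]])
    writeLines(jsonlite::toJSON(list(
      schema_version = SCHEMA_VERSION,
      patient_id = fused$patient_id[i],
      fracture_type = fused$fracture_type[i],
      cuboid = unlist(fused[i, c("x_min", "y_min", "z_min",
                                 "x_max", "y_max", "z_max")]),
      frequency = fused$frequency[i],
      augmentations = as.integer(names(counts)),
      constituents_per_augmentation = as.integer(counts)
    ), auto_unbox = TRUE, digits = I(17)), con)
  }
  invisible(path)
}
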