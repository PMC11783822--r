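#' Default generator CPDs for synthetic cohorts
#'
#' Clinically oriented conditional probabilities over the default structure:
#' instability is more common in older patients; anterior lesions (pubic
#' symphysis diastasis, parallel SI diastasis, diastatic sacral fracture)
#' load on translational instability, anteriorly divergent SI diastasis on
#' purely rotational injury, and ring fractures are common in any unstable
#' pelvis. These are configuration values for the simulator, not estimates
#' from any real cohort.
#'
#' @param spec a `bn_spec`; defaults to [default_structure()].
#' @return Named list of [cpd_table()]s.
#' @export
default_generator_cpds <- function(spec = default_structure()) {
  # rows for fracture nodes are (R=0,T=0), (R=1,T=0), (R=0,T=1), (R=1,T=1)
  fx_rows <- list(
    psd                   = c(0.05, 0.45, 0.60, 0.80),
    si_anterior_divergent = c(0.02, 0.60, 0.15, 0.55),
    si_parallel           = c(0.03, 0.20, 0.60, 0.75),
    sacral_nondiastatic   = c(0.15, 0.45, 0.35, 0.55),
    sacral_diastatic      = c(0.02, 0.10, 0.55, 0.75),
    isp_avulsion          = c(0.02, 0.35, 0.25, 0.50),
    ring_fx               = c(0.30, 0.60, 0.65, 0.85))
  cpds <- list()
  for (nd in spec$nodes) {
    pa <- spec$parents[[nd]]
    cpds[[nd]] <- if (nd == "age60") {
      cpd_table(nd, character(), 0.35)
    } else if (nd == "R") {
      if (length(pa)) cpd_table(nd, pa, c(0.35, 0.55)) else cpd_table(nd, pa, 0.42)
    } else if (nd == "T") {
      if (length(pa)) cpd_table(nd, pa, c(0.25, 0.40)) else cpd_table(nd, pa, 0.30)
    } else {
      stopifnot(identical(pa, c("R", "T")))
      cpd_table(nd, pa, fx_rows[[nd]])
    }
  }
  cpds
}

#' Synthetic cohort parameters
#'
#' @param n_patients cohort size (> 0).
#' @param p_age60 probability a patient is aged 60+ (used only when the
#'   generator network lacks an explicit `age60` CPD).
#' @param spec generating network structure.
#' @param cpds generating CPDs over `spec`.
#' @param seed integer RNG seed.
#' @export
cohort_params <- function(n_patients, p_age60 = 0.35,
                          spec = default_structure(),
                          cpds = default_generator_cpds(spec),
                          seed = 1L) {
  if (n_patients <= 0) stop("`n_patients` must be positive")
  structure(list(n_patients = as.integer(n_patients), p_age60 = p_age60,
                 spec = spec, cpds = cpds, seed = as.integer(seed)),
            class = "cohort_params")
}

#' Generate a synthetic patient cohort by ancestral sampling
#'
#' Samples every network node in topological order from the generator CPDs
#' (age flag, then rotational and translational instability, then each
#' fracture type), and attaches an integer age consistent with the age
#' flag (uniform 18-59 or 60-95).
#'
#' @param params a [cohort_params()] object.
#' @return Patient data.frame with `patient_id`, `age_years`, one
#'   `truth_<type>` column per fracture type, and `truth_R`, `truth_T`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_patients
  spec <- params$spec; cpds <- params$cpds
  samp <- matrix(0L, nrow = n, ncol = length(spec$nodes),
                 dimnames = list(NULL, spec$nodes))
  for (nd in spec$nodes) {
    cpd <- cpds[[nd]]
    idx <- cpd_row_index(samp[, cpd$parents, drop = FALSE])
    samp[, nd] <- as.integer(runif(n) < cpd$p1[idx])
  }
  age60 <- if ("age60" %in% spec$nodes) samp[, "age60"] else
    as.integer(runif(n) < params$p_age60)
  age <- ifelse(age60 == 1L, sample(60:95, n, replace = TRUE),
                sample(18:59, n, replace = TRUE))
  out <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                    age_years = as.integer(age),
                    stringsAsFactors = FALSE)
  for (t in fracture_types())
    out[[paste0("truth_", t)]] <- if (t %in% spec$nodes) samp[, t] else 0L
  out$truth_R <- if ("R" %in% spec$nodes) samp[, "R"] else NA_integer_
  out$truth_T <- if ("T" %in% spec$nodes) samp[, "T"] else NA_integer_
  out
}

#' Synthetic detector parameters
#'
#' Emulates a 2D fracture detector run over `K` augmented copies of a scan:
#' each true fracture is detected in an augmented scan with per-type
#' probability `d[type]`; a detected fracture emits one 2D box per cuboid
#' slice, each independently dropped with probability `m` (never all of
#' them, so `d` stays the sole per-scan detection probability), with small
#' coordinate jitter. True-positive scores are drawn from a Beta
#' distribution truncated above the 2D keep threshold (the `d`/`m` miss
#' processes subsume sub-threshold scores). Each augmented scan additionally
#' receives `Poisson(fp_rate)` false-positive boxes of random type and
#' position with untruncated Beta scores, so low-scoring false positives
#' are filtered exactly as a real detector's would be.
#'
#' @param d per-type per-scan detection probability: single value or named
#'   vector over [fracture_types()].
#' @param m per-slice 2D miss probability.
#' @param fp_rate expected false-positive boxes per augmented scan.
#' @param beta_tp,beta_fp `c(shape1, shape2)` of the score distributions.
#' @param extent volume extent `c(nx, ny, nz)` in voxels/slices.
#' @param K number of augmented scans.
#' @param keep_2d truncation point of the true-positive score distribution;
#'   keep equal to the fusion keep threshold.
#' @param jitter_px maximum absolute in-plane box jitter.
#' @param seed integer RNG seed.
#' @export
detector_params <- function(d = 0.7, m = 0.2, fp_rate = 0.2,
                            beta_tp = c(8, 2), beta_fp = c(2, 5),
                            extent = c(160L, 160L, 40L), K = 25L,
                            keep_2d = 0.5, jitter_px = 2L, seed = 1L) {
  if (length(d) == 1L) d <- setNames(rep(d, 7), fracture_types())
  if (!all(fracture_types() %in% names(d)))
    stop("`d` must cover every fracture type")
  if (any(d < 0 | d > 1) || m < 0 || m > 1) stop("probabilities outside [0, 1]")
  if (fp_rate < 0) stop("`fp_rate` must be >= 0")
  if (K < 1) stop("`K` must be >= 1")
  structure(list(d = d[fracture_types()], m = m, fp_rate = fp_rate,
                 beta_tp = beta_tp, beta_fp = beta_fp,
                 extent = as.integer(extent), K = as.integer(K),
                 keep_2d = keep_2d, jitter_px = as.integer(jitter_px),
                 seed = as.integer(seed)),
            class = "detector_params")
}

r_truncated_beta <- function(n, shape, lower) {
  qbeta(runif(n, pbeta(lower, shape[1], shape[2]), 1), shape[1], shape[2])
}

random_cuboid <- function(extent, size_xy = c(10L, 30L), size_z = c(2L, 5L)) {
  dx <- sample(size_xy[1]:size_xy[2], 1L)
  dy <- sample(size_xy[1]:size_xy[2], 1L)
  dz <- sample(size_z[1]:size_z[2], 1L)
  if (dx > extent[1] || dy > extent[2] || dz > extent[3])
    stop("fracture cuboid cannot fit in the volume extent")
  x0 <- sample(0:(extent[1] - dx), 1L)
  y0 <- sample(0:(extent[2] - dy), 1L)
  z0 <- sample(0:(extent[3] - dz), 1L)
  c(x_min = x0, y_min = y0, z_min = z0,
    x_max = x0 + dx, y_max = y0 + dy, z_max = z0 + dz)
}

#' Simulate noisy per-augmentation 2D detections for one patient
#'
#' Places one random cuboid per true fracture type, then emits jittered
#' per-slice boxes for every augmented scan according to the detector's
#' miss model, plus Poisson false positives.
#'
#' @param patient one patient row with `truth_<type>` columns.
#' @param det a [detector_params()] object.
#' @param seed RNG seed for this patient; defaults to the detector seed.
#' @return A detections data.frame (possibly empty).
#' @export
simulate_detections <- function(patient, det, seed = det$seed) {
  stopifnot(inherits(det, "detector_params"))
  truth_cols <- paste0("truth_", fracture_types())
  if (!all(truth_cols %in% names(patient)))
    stop("patient lacks ground-truth fracture columns")
  set.seed(seed)
  ext <- det$extent
  rows <- list()
  true_types <- fracture_types()[unlist(patient[truth_cols]) == 1L]
  for (type in true_types) {
    cub <- random_cuboid(ext)
    slices <- cub["z_min"]:(cub["z_max"] - 1L)
    ns <- length(slices)
    for (k in seq_len(det$K) - 1L) {
      if (runif(1) >= det$d[[type]]) next
      keep <- runif(ns) >= det$m
      if (!any(keep)) keep[sample.int(ns, 1L)] <- TRUE  # never drop all
      nk <- sum(keep)
      jx <- sample(seq(-det$jitter_px, det$jitter_px), 2L * nk, replace = TRUE)
      jy <- sample(seq(-det$jitter_px, det$jitter_px), 2L * nk, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patient$patient_id,
        augmentation_id = k,
        slice_index = as.integer(slices[keep]),
        x_min = pmax(0, cub["x_min"] + jx[seq_len(nk)]),
        y_min = pmax(0, cub["y_min"] + jy[seq_len(nk)]),
        x_max = pmin(ext[1], cub["x_max"] + jx[nk + seq_len(nk)]),
        y_max = pmin(ext[2], cub["y_max"] + jy[nk + seq_len(nk)]),
        fracture_type = type,
        network_score = r_truncated_beta(nk, det$beta_tp, det$keep_2d),
        stringsAsFactors = FALSE)
    }
  }
  if (det$fp_rate > 0) {
    n_fp_per_scan <- rpois(det$K, det$fp_rate)
    for (k in which(n_fp_per_scan > 0) - 1L) {
      for (i in seq_len(n_fp_per_scan[k + 1L])) {
        cub <- random_cuboid(ext, size_xy = c(8L, 20L), size_z = c(1L, 2L))
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = patient$patient_id,
          augmentation_id = as.integer(k),
          slice_index = as.integer(cub["z_min"]),
          x_min = cub["x_min"], y_min = cub["y_min"],
          x_max = cub["x_max"], y_max = cub["y_max"],
          fracture_type = sample(fracture_types(), 1L),
          network_score = rbeta(1, det$beta_fp[1], det$beta_fp[2]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty_detections())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # fix up any jitter-degenerate boxes before validation
  out$x_max <- pmax(out$x_max, out$x_min + 1)
  out$y_max <- pmax(out$y_max, out$y_min + 1)
  as_detections(out)
}

#' Simulate detections for a whole cohort
#'
#' Derives one sub-seed per patient from the detector seed so any single
#' patient's detections are reproducible in isolation.
#'
#' @param patients cohort data.frame from [generate_cohort()].
#' @param det a [detector_params()] object.
#' @return One detections data.frame covering the cohort.
#' @export
simulate_cohort_detections <- function(patients, det) {
  dfs <- lapply(seq_len(nrow(patients)), function(i)
    simulate_detections(patients[i, , drop = FALSE], det,
                        seed = (det$seed + 7919L * i) %% .Machine$integer.max))
  out <- do.call(rbind, dfs)
  if (is.null(out)) return(empty_detections())
  rownames(out) <- NULL
  out
}
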