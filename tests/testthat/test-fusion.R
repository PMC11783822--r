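box2d <- function(slice, x0 = 0, y0 = 0, x1 = 10, y1 = 10, type = "psd",
                  score = 0.9, aug = 0L, pid = "p1") {
  data.frame(patient_id = pid, augmentation_id = aug, slice_index = slice,
             x_min = x0, y_min = y0, x_max = x1, y_max = y1,
             fracture_type = type, network_score = score,
             stringsAsFactors = FALSE)
}

test_that("2D boxes on adjacent slices with overlap fuse into one 3D fracture", {
  d <- rbind(box2d(3), box2d(4))
  f <- fuse_2d_to_3d(d)
  expect_equal(nrow(f), 1L)
  expect_equal(f$z_min, 3)
  expect_equal(f$z_max, 5)  # half-open: slices 3 and 4 span [3, 5)
  expect_equal(f$score, 0.9)
  expect_equal(f$n_constituents, 2L)
})

test_that("identical boxes of different types stay separate", {
  d <- rbind(box2d(3, type = "psd"), box2d(3, type = "ring_fx"))
  f <- fuse_2d_to_3d(d)
  expect_equal(nrow(f), 2L)
  expect_setequal(f$fracture_type, c("psd", "ring_fx"))
})

test_that("fusion closes transitively along chains", {
  # a-b overlap and b-c overlap but a and c do not touch
  d <- rbind(box2d(0, x0 = 0, x1 = 10),
             box2d(1, x0 = 8, x1 = 20),
             box2d(2, x0 = 18, x1 = 30))
  f <- fuse_2d_to_3d(d)
  expect_equal(nrow(f), 1L)
  expect_equal(f$x_min, 0); expect_equal(f$x_max, 30)
})

test_that("the keep threshold is strict and mixed scans are rejected", {
  d <- rbind(box2d(1, score = 0.5), box2d(2, score = 0.51))
  f <- fuse_2d_to_3d(d, keep_2d = 0.5)
  expect_equal(nrow(f), 1L)           # score == 0.5 discarded
  expect_equal(f$n_constituents, 1L)
  expect_error(fuse_2d_to_3d(rbind(box2d(1, aug = 0L), box2d(1, aug = 1L))),
               "augmentation_id")
  expect_equal(nrow(fuse_2d_to_3d(box2d(1, score = 0.2))), 0L)
})

test_that("2D fusion matches the transitive-closure oracle on random instances", {
  set.seed(101)
  for (rep in 1:40) {
    d <- as_detections(random_detections(sample(2:50, 1)))
    f <- fuse_2d_to_3d(d, keep_2d = 0)
    memb <- oracle_components(oracle_adjacency_2d(d))
    expect_equal(nrow(f), length(unique(memb)))
    # each oracle component's minimal cuboid appears among the fused ones
    for (cid in unique(memb)) {
      ii <- which(memb == cid)
      hit <- f$fracture_type == d$fracture_type[ii[1]] &
        f$x_min == min(d$x_min[ii]) & f$x_max == max(d$x_max[ii]) &
        f$y_min == min(d$y_min[ii]) & f$y_max == max(d$y_max[ii]) &
        f$z_min == min(d$slice_index[ii]) &
        f$z_max == max(d$slice_index[ii]) + 1 &
        f$n_constituents == length(ii)
      expect_equal(sum(hit), 1L)
    }
  }
})

test_that("fusion output is invariant to input permutation", {
  set.seed(202)
  d <- as_detections(random_detections(30))
  f1 <- fuse_2d_to_3d(d)
  f2 <- fuse_2d_to_3d(d[sample(nrow(d)), ])
  expect_identical(f1[names(f1) != "constituents"],
                   f2[names(f2) != "constituents"])
})

test_that("cross-scan fusion reproduces the split/bridge worked example", {
  # scan 0: two same-type boxes with a one-slice gap; scan 1: one bridging
  # box intersecting both; scan 2: nothing. K = 3 -> frequency 2/3.
  f3d <- rbind(
    fuse_2d_to_3d(rbind(box2d(2, aug = 0L), box2d(5, aug = 0L)) |> as_detections()),
    fuse_2d_to_3d(as_detections(do.call(rbind, lapply(2:6, box2d, aug = 1L)))))
  expect_equal(nrow(f3d), 3L)  # two split + one bridging
  fused <- fuse_across_scans(f3d, K = 3L)
  expect_equal(nrow(fused), 1L)
  expect_equal(fused$frequency, 2 / 3)
  expect_equal(fused$n_augmentations, 2L)
  # component cuboid is the elementwise min/max of the members
  expect_equal(fused$z_min, min(f3d$z_min))
  expect_equal(fused$z_max, max(f3d$z_max))
})

test_that("disjoint same-type findings in one scan get frequency 1/K each", {
  f3d <- rbind(fuse_2d_to_3d(box2d(1, x0 = 0, x1 = 10)),
               fuse_2d_to_3d(box2d(1, x0 = 50, x1 = 60)))
  fused <- fuse_across_scans(f3d, K = 25L)
  expect_equal(nrow(fused), 2L)
  expect_equal(fused$frequency, c(1 / 25, 1 / 25))
  expect_error(fuse_across_scans(f3d, K = 0L), "positive")
  expect_error(fuse_across_scans(f3d, K = -2L), "positive")
})

test_that("frequency counts each augmented scan once", {
  expect_equal(frequency_score(c(0L, 0L, 1L), 3L), 2 / 3)
  expect_equal(frequency_score(0:24, 25L), 1)
  # duplicates in an already-counted scan never change the score
  expect_equal(frequency_score(c(2L, 2L, 2L), 25L),
               frequency_score(2L, 25L))
})

test_that("frequencies live on the K-grid", {
  set.seed(33)
  for (rep in 1:20) {
    K <- sample(2:25, 1)
    augs <- sample(0:(K - 1), sample(K, 1), replace = TRUE)
    expect_true(any(abs(frequency_score(augs, K) - (0:K) / K) < 1e-12))
  }
})

test_that("type confidence is the per-type max frequency with 0 defaults", {
  f3d <- rbind(fuse_2d_to_3d(box2d(1, type = "psd", aug = 0L)),
               fuse_2d_to_3d(as_detections(
                 box2d(1, x0 = 40, x1 = 50, type = "psd", aug = 1L))),
               fuse_2d_to_3d(as_detections(box2d(8, type = "ring_fx", aug = 0L))))
  fused <- fuse_across_scans(f3d, K = 5L)
  conf <- type_confidence(fused)
  expect_named(conf, fracture_types())
  expect_equal(unname(conf["psd"]), 1 / 5)       # two findings, both 1/5
  expect_equal(unname(conf["ring_fx"]), 1 / 5)
  expect_equal(unname(conf["si_parallel"]), 0)
  # no findings at all -> all zeros
  empty_conf <- type_confidence(fuse_across_scans(fuse_2d_to_3d(box2d(1, score = 0.1)), 5L))
  expect_true(all(empty_conf == 0))
})

test_that("detection sets are nested threshold sets", {
  conf <- c(psd = 1.0, ring_fx = 0.6)
  s <- detect_sets(conf, thresholds(z_high = 0.8, z_low = 0.5))
  expect_equal(s$high, "psd")
  expect_setequal(s$low, c("psd", "ring_fx"))
  expect_true(all(s$high %in% s$low))
  s0 <- detect_sets(setNames(numeric(7), fracture_types()), thresholds())
  expect_length(s0$high, 0); expect_length(s0$low, 0)
  s_eq <- detect_sets(conf, thresholds(z_high = 0.6, z_low = 0.6))
  expect_identical(s_eq$high, s_eq$low)
  # >= comparison: a frequency exactly at the threshold is kept
  expect_equal(detect_sets(c(psd = 1.0), thresholds(z_high = 1.0))$high, "psd")
})

test_that("grouped per-patient fusion equals the per-scan loop", {
  set.seed(55)
  for (rep in 1:10) {
    d <- random_detections(40, n_types = 4L)
    d$augmentation_id <- sample(0:4, 40, replace = TRUE)
    d <- as_detections(d)
    K <- 5L
    loop <- do.call(rbind, lapply(split(d, d$augmentation_id),
                                  fuse_2d_to_3d, keep_2d = 0.5))
    expected <- fuse_across_scans(loop, K)
    got <- fuse_patient(d, K)
    cols <- c("fracture_type", "x_min", "y_min", "z_min",
              "x_max", "y_max", "z_max", "frequency", "n_augmentations")
    expect_equal(got[cols], expected[cols], ignore_attr = TRUE)
  }
})

test_that("fused findings export to JSON-lines with constituent counts", {
  f3d <- rbind(fuse_2d_to_3d(box2d(1)), fuse_2d_to_3d(box2d(1, aug = 1L)))
  fused <- fuse_across_scans(f3d, K = 3L)
  tf <- tempfile(fileext = ".jsonl")
  write_fused(fused, tf, provenance = list(seed = 1))
  lines <- readLines(tf)
  expect_length(lines, 2L)  # provenance + one finding
  rec <- jsonlite::fromJSON(lines[2])
  expect_equal(rec$frequency, 2 / 3)
  expect_equal(rec$augmentations, c(0L, 1L))
  expect_equal(rec$constituents_per_augmentation, c(1L, 1L))
})
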