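# Independent oracles and random-instance generators used across the suite.
# These deliberately use different algorithms from the package code paths.

# --- full-joint enumeration oracle for boolean-network marginals ---------
# enumerates all 2^n assignments of the WHOLE network, multiplies CPD
# entries row by row, filters on the evidence, and normalizes
oracle_marginal <- function(spec, cpds, evidence, query) {
  nodes <- spec$nodes
  n <- length(nodes)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(grid) <- nodes
  probs <- apply(grid, 1L, function(assign) {
    p <- 1
    for (nd in nodes) {
      cpd <- cpds[[nd]]
      bits <- assign[cpd$parents]
      idx <- if (length(bits)) 1L + sum(bits * 2^(seq_along(bits) - 1L)) else 1L
      p1 <- cpd$p1[idx]
      p <- p * if (assign[[nd]] == 1L) p1 else 1 - p1
    }
    p
  })
  ev <- unlist(evidence)
  ok <- rep(TRUE, nrow(grid))
  for (nd in names(ev)) ok <- ok & grid[, nd] == as.integer(ev[[nd]] != 0)
  denom <- sum(probs[ok])
  if (denom <= 0) stop("zero-probability evidence")
  sum(probs[ok & grid[, query] == 1L]) / denom
}

# random DAG over n boolean nodes: edges only from earlier to later in a
# random node order, kept with probability p_edge
random_dag <- function(n, p_edge = 0.4) {
  nodes <- paste0("n", sample(n))
  from <- character(); to <- character()
  for (j in seq_len(n)) for (i in seq_len(j - 1L)) {
    if (runif(1) < p_edge) {
      from <- c(from, nodes[i]); to <- c(to, nodes[j])
    }
  }
  network_spec(nodes, data.frame(from = from, to = to))
}

random_cpds <- function(spec) {
  lapply(setNames(spec$nodes, spec$nodes), function(nd) {
    pa <- spec$parents[[nd]]
    cpd_table(nd, pa, runif(2^length(pa)))
  })
}

# --- transitive-closure oracle for connected-component fusion ------------
# boolean adjacency matrix closed under repeated squaring; component ids
# are the row patterns of the closure
oracle_components <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(integer())
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  match(apply(reach, 1L, paste, collapse = ""),
        unique(apply(reach, 1L, paste, collapse = "")))
}

# pairwise 2D fusion adjacency, written independently of the package rule
oracle_adjacency_2d <- function(d) {
  n <- nrow(d)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    adj[i, j] <- d$fracture_type[i] == d$fracture_type[j] &&
      abs(d$slice_index[i] - d$slice_index[j]) <= 1L &&
      d$x_min[i] < d$x_max[j] && d$x_min[j] < d$x_max[i] &&
      d$y_min[i] < d$y_max[j] && d$y_min[j] < d$y_max[i]
  }
  adj
}

# random detection tables for fusion property tests (single scan)
random_detections <- function(n, n_types = 3L, extent = 60L, max_slice = 10L) {
  types <- sample(fracture_types()[seq_len(n_types)], n, replace = TRUE)
  x0 <- runif(n, 0, extent - 10); y0 <- runif(n, 0, extent - 10)
  data.frame(patient_id = "rp", augmentation_id = 0L,
             slice_index = sample(0:max_slice, n, replace = TRUE),
             x_min = x0, y_min = y0,
             x_max = x0 + runif(n, 2, 15), y_max = y0 + runif(n, 2, 15),
             fracture_type = types,
             network_score = runif(n, 0.51, 1),
             stringsAsFactors = FALSE)
}

# ground-truth boolean table in the layout fit_cpds() expects
load_truth_table_for_tests <- function(patients, spec) {
  tab <- data.frame(R = patients$truth_R, T = patients$truth_T)
  for (t in fracture_types()) tab[[t]] <- patients[[paste0("truth_", t)]]
  if ("age60" %in% spec$nodes) tab$age60 <- age_flag(patients$age_years)
  tab
}

# small hand-checkable grading model used in refinement tests
tiny_grading_model <- function() {
  spec <- network_spec(
    c("R", "T", "psd", "si_anterior_divergent", "sacral_diastatic"),
    data.frame(from = c("R", "T", "R", "T", "T"),
               to = c("psd", "psd", "si_anterior_divergent",
                      "si_anterior_divergent", "sacral_diastatic")))
  cpds <- list(
    R = cpd_table("R", character(), 0.4),
    T = cpd_table("T", character(), 0.3),
    psd = cpd_table("psd", c("R", "T"), c(0.05, 0.4, 0.6, 0.9)),
    si_anterior_divergent = cpd_table("si_anterior_divergent", c("R", "T"),
                                      c(0.02, 0.7, 0.2, 0.6)),
    sacral_diastatic = cpd_table("sacral_diastatic", "T", c(0.05, 0.8)))
  list(spec = spec, cpds = cpds)
}
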