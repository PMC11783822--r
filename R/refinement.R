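fracture_evidence <- function(spec, positives, age60 = NULL) {
  fx <- intersect(fracture_types(), spec$nodes)
  ev <- setNames(as.integer(fx %in% positives), fx)
  if ("age60" %in% spec$nodes) {
    if (is.null(age60)) stop("model includes `age60`; supply the age flag")
    ev <- c(ev, age60 = as.integer(age60))
  }
  ev
}

#' Initial Tile grade from the high-confidence findings
#'
#' Sets every fracture node as evidence (1 when in `fx_high`, 0 otherwise)
#' together with the age flag, queries the posterior probabilities of
#' rotational and translational instability, and maps their 0.5-thresholded
#' values to a Tile grade.
#'
#' @param spec,cpds the network and its fitted CPDs.
#' @param fx_high character vector of high-confidence fracture types.
#' @param age60 0/1 age flag (see [age_flag()]); ignored by age-free models.
#' @return List with `p_R`, `p_T`, `tile`, and the evidence used.
#' @export
initial_grade <- function(spec, cpds, fx_high, age60 = NULL) {
  if (!all(fx_high %in% fracture_types()))
    stop("unknown fracture type in `fx_high`")
  ev <- fracture_evidence(spec, fx_high, age60)
  p_R <- marginal(spec, cpds, ev, "R")
  p_T <- marginal(spec, cpds, ev, "T")
  list(p_R = p_R, p_T = p_T,
       tile = tile_from_instability(p_R >= 0.5, p_T >= 0.5),
       evidence = ev)
}

#' Leave-one-out retrieval probabilities for candidate fractures
#'
#' For each candidate type `t`, the posterior probability that `t` is
#' present given everything else: the candidate's own state is removed from
#' the evidence while all other fracture states and the age flag stay fixed.
#'
#' @param spec,cpds the network and CPDs.
#' @param evidence named 0/1 evidence over the fracture nodes (and `age60`).
#' @param candidates fracture types to score; must not be positive in the
#'   evidence.
#' @return Named numeric vector of retrieval probabilities.
#' @export
candidate_probabilities <- function(spec, cpds, evidence, candidates) {
  if (!length(candidates)) return(setNames(numeric(0), character(0)))
  pos <- names(evidence)[unlist(evidence) == 1L]
  if (any(candidates %in% pos))
    stop("candidates must be disjoint from positive evidence")
  vapply(setNames(candidates, candidates), function(t)
    marginal(spec, cpds, evidence[setdiff(names(evidence), t)], t),
    numeric(1))
}

# P(fx = 1 | R, T) for each of the four instability states, straight from
# the candidate's CPD rows -- exposed for audit alongside the marginalized q
per_state_conditionals <- function(spec, cpds, type) {
  cpd <- cpds[[type]]
  states <- expand.grid(R = 0:1, T = 0:1)
  p <- vapply(seq_len(nrow(states)), function(i) {
    bits <- matrix(0L, 1L, length(cpd$parents),
                   dimnames = list(NULL, cpd$parents))
    for (pa in intersect(c("R", "T"), cpd$parents))
      bits[, pa] <- states[[pa]][i]
    cpd$p1[cpd_row_index(bits)]
  }, numeric(1))
  setNames(p, paste0("R", states$R, "T", states$T))
}

#' Refine the Tile grade by retrieving likely-missed fractures
#'
#' Starts from the high-confidence findings and repeatedly asks the
#' Bayesian model which candidate from the low-confidence set is most
#' likely present given everything currently believed. While the best
#' candidate's leave-one-out conditional reaches `z_star` it is promoted to
#' a positive finding (ties broken by the canonical fracture-type order),
#' the evidence is updated, and the search repeats. High-confidence
#' findings are never removed. The final grade is recomputed on the updated
#' evidence.
#'
#' @param spec,cpds the network and fitted CPDs.
#' @param fx_high high-confidence fracture types (initial positives).
#' @param fx_low low-confidence fracture types; must contain `fx_high`.
#' @param age60 0/1 age flag.
#' @param th a [thresholds()] object; only `z_star` is used here.
#' @return A `refinement_result`: initial and final evidence, instability
#'   posteriors and Tile grades, and one row per promoted fracture in
#'   `added` (type, retrieval probability at addition time, step, and the
#'   per-instability-state conditionals for audit).
#' @export
refine <- function(spec, cpds, fx_high, fx_low, age60 = NULL, th = thresholds()) {
  stopifnot(inherits(th, "thresholds"))
  if (!all(fx_high %in% fx_low))
    stop("`fx_high` must be a subset of `fx_low`")
  if (!all(fx_low %in% fracture_types()))
    stop("unknown fracture type in `fx_low`")
  init <- initial_grade(spec, cpds, fx_high, age60)
  positives <- intersect(fracture_types(), fx_high)
  added <- data.frame(fracture_type = character(), q = numeric(),
                      step = integer(), stringsAsFactors = FALSE)
  audit <- list()
  step <- 0L
  repeat {
    candidates <- intersect(fracture_types(), setdiff(fx_low, positives))
    if (!length(candidates)) break
    ev <- fracture_evidence(spec, positives, age60)
    q <- candidate_probabilities(spec, cpds, ev, candidates)
    best <- which.max(q)  # first max in canonical order breaks ties
    if (q[best] < th$z_star) break
    step <- step + 1L
    promoted <- candidates[best]
    positives <- intersect(fracture_types(), c(positives, promoted))
    added <- rbind(added, data.frame(fracture_type = promoted,
                                     q = unname(q[best]), step = step))
    audit[[promoted]] <- list(q_all = q,
                              per_state = per_state_conditionals(spec, cpds, promoted))
  }
  final <- initial_grade(spec, cpds, positives, age60)
  structure(list(
    fx_high = intersect(fracture_types(), fx_high),
    fx_low = intersect(fracture_types(), fx_low),
    initial_evidence = init$evidence,
    final_evidence = final$evidence,
    added = added,
    audit = audit,
    p_R_initial = init$p_R, p_T_initial = init$p_T,
    p_R_final = final$p_R, p_T_final = final$p_T,
    tile_initial = init$tile, tile_final = final$tile),
    class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("<refinement_result> initial %s (p_R=%.3f, p_T=%.3f) -> final %s (p_R=%.3f, p_T=%.3f)\n",
              x$tile_initial, x$p_R_initial, x$p_T_initial,
              x$tile_final, x$p_R_final, x$p_T_final))
  if (nrow(x$added)) {
    cat("  retrieved:\n")
    for (i in seq_len(nrow(x$added)))
      cat(sprintf("    step %d: %s (q = %.3f)\n", x$added$step[i],
                  x$added$fracture_type[i], x$added$q[i]))
  } else cat("  retrieved: none\n")
  invisible(x)
}

#' Serialize a refinement result to JSON
#'
#' Includes the per-step retrieval probabilities and per-instability-state
#' conditionals -- the explanation surface for reviewing why each fracture
#' was promoted.
#'
#' @param result a `refinement_result`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @param provenance optional named list embedded in the record.
#' @export
refinement_to_json <- function(result, path = NULL, provenance = NULL) {
  obj <- list(schema_version = SCHEMA_VERSION,
              provenance = provenance,
              fx_high = result$fx_high, fx_low = result$fx_low,
              initial = list(p_R = result$p_R_initial, p_T = result$p_T_initial,
                             tile = result$tile_initial,
                             evidence = as.list(result$initial_evidence)),
              final = list(p_R = result$p_R_final, p_T = result$p_T_final,
                           tile = result$tile_final,
                           evidence = as.list(result$final_evidence)),
              added = result$added,
              audit = result$audit)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
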