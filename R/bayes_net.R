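#' Boolean Bayesian network structure
#'
#' A directed acyclic graph over boolean nodes. For the default grading
#' model the nodes are the 7 fracture types plus `age60` (patient aged 60
#' or over), `R` (rotational instability), and `T` (translational
#' instability); the Tile grade is a deterministic label of (R, T), not a
#' node.
#'
#' @param nodes character vector of node names.
#' @param edges data.frame with character columns `from`, `to`.
#' @return A `bn_spec` with nodes in topological order and a precomputed
#'   parent list.
#' @export
network_spec <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      stringsAsFactors = FALSE)
  if (!all(c(edges$from, edges$to) %in% nodes))
    stop("edge endpoint not among nodes")
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g)) stop("network contains a directed cycle")
  topo <- igraph::topo_sort(g, mode = "out")$name
  parents <- lapply(setNames(topo, topo), function(nd)
    sort(edges$from[edges$to == nd]))
  structure(list(nodes = topo, edges = edges, parents = parents),
            class = "bn_spec")
}

#' @export
print.bn_spec <- function(x, ...) {
  cat(sprintf("<bn_spec> %d boolean nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  for (nd in x$nodes) {
    pa <- x$parents[[nd]]
    cat(sprintf("  %s%s\n", nd,
                if (length(pa)) paste0(" <- {", paste(pa, collapse = ", "), "}") else ""))
  }
  invisible(x)
}

#' Default causal structure for Tile grading
#'
#' Age influences both instabilities (`age60 -> R`, `age60 -> T`), and each
#' instability influences every fracture type (`R -> fx`, `T -> fx`): the
#' generative "instability explains findings" orientation. Under this
#' orientation observing one fracture changes the conditional probability of
#' the others through R and T, which is what makes finding retrieval
#' non-vacuous, and every CPD has at most 4 rows so it is fittable from
#' hundreds of patients.
#'
#' @param include_age include the `age60` node and its edges (set `FALSE`
#'   for the age-free model variant).
#' @return A `bn_spec` over 10 (or 9) nodes.
#' @export
default_structure <- function(include_age = TRUE) {
  fx <- fracture_types()
  nodes <- c(if (include_age) "age60", "R", "T", fx)
  edges <- rbind(
    if (include_age) data.frame(from = "age60", to = c("R", "T")),
    data.frame(from = rep(c("R", "T"), each = length(fx)), to = rep(fx, 2)))
  network_spec(nodes, edges)
}

# row index into a CPD probability vector: first parent is the least
# significant bit; bits is a matrix with one column per parent
cpd_row_index <- function(bits) {
  if (ncol(bits) == 0L) return(rep(1L, nrow(bits)))
  1L + as.integer(bits %*% 2^(seq_len(ncol(bits)) - 1L))
}

#' Conditional probability table of one node
#'
#' @param node node name.
#' @param parents ordered character vector of parent names.
#' @param p1 numeric vector of length `2^length(parents)`: probability the
#'   node is 1 for each parent configuration, rows ordered with the first
#'   parent as the least significant bit.
#' @return A `cpd_table`.
#' @export
cpd_table <- function(node, parents, p1) {
  parents <- as.character(parents)
  if (length(p1) != 2^length(parents))
    stop("`p1` must have length 2^|parents| (node ", node, ")")
  if (any(p1 < 0 | p1 > 1)) stop("probabilities outside [0, 1] (node ", node, ")")
  structure(list(node = node, parents = parents, p1 = as.numeric(p1)),
            class = "cpd_table")
}

#' Fit all CPDs by Bayesian (Laplace-smoothed) estimation
#'
#' For each node and parent configuration,
#' `P(node = 1 | config) = (n1 + a) / (n1 + n0 + 2a)` with pseudocount `a`;
#' configurations never observed get 0.5 (and with `a = 0` the
#' maximum-likelihood ratio, 0.5 when unobserved).
#'
#' @param spec a `bn_spec`.
#' @param data data.frame of 0/1 (or logical) columns covering every node.
#' @param pseudocount nonnegative smoothing pseudocount `a` (default 1).
#' @return Named list of [cpd_table()]s, one per node.
#' @export
fit_cpds <- function(spec, data, pseudocount = 1) {
  stopifnot(inherits(spec, "bn_spec"), pseudocount >= 0)
  miss <- setdiff(spec$nodes, names(data))
  if (length(miss)) stop("data missing node column(s): ", paste(miss, collapse = ", "))
  lapply(setNames(spec$nodes, spec$nodes), function(nd) {
    pa <- spec$parents[[nd]]
    x <- as.integer(data[[nd]] != 0)
    nrows <- 2^length(pa)
    if (length(x)) {
      bits <- as.matrix(as.data.frame(lapply(data[pa], function(v) as.integer(v != 0))))
      if (!length(pa)) bits <- matrix(integer(), nrow = length(x), ncol = 0)
      idx <- cpd_row_index(bits)
      n1 <- tabulate(idx[x == 1L], nbins = nrows)
      n0 <- tabulate(idx[x == 0L], nbins = nrows)
    } else {
      n1 <- n0 <- rep(0L, nrows)
    }
    denom <- n1 + n0 + 2 * pseudocount
    p1 <- ifelse(denom > 0, (n1 + pseudocount) / denom, 0.5)
    p1[n1 + n0 == 0 & pseudocount == 0] <- 0.5
    cpd_table(nd, pa, p1)
  })
}

# assignment matrix (configs x nodes, 0/1) -> joint probability vector
joint_over_assignments <- function(spec, cpds, assign) {
  joint <- rep(1, nrow(assign))
  for (nd in spec$nodes) {
    cpd <- cpds[[nd]]
    idx <- cpd_row_index(assign[, cpd$parents, drop = FALSE])
    p <- cpd$p1[idx]
    joint <- joint * ifelse(assign[, nd] == 1L, p, 1 - p)
  }
  joint
}

#' Exact posterior marginal of one boolean node
#'
#' Computes `P(query = 1 | evidence)` exactly: every CPD factor is reduced
#' by the evidence and the joint is summed over the remaining unobserved
#' variables only. Equivalent to variable elimination for these small
#' boolean networks, and checked against full-joint enumeration in the test
#' suite.
#'
#' @param spec a `bn_spec`.
#' @param cpds named list of [cpd_table()]s covering every node.
#' @param evidence named vector/list of 0/1 (or logical) observed nodes; may
#'   be empty.
#' @param query node to query; must not be in the evidence.
#' @return `P(query = 1 | evidence)` in `[0, 1]`.
#' @export
marginal <- function(spec, cpds, evidence = NULL, query) {
  stopifnot(inherits(spec, "bn_spec"))
  ev <- unlist(evidence)
  ev_nodes <- names(ev)
  if (!all(ev_nodes %in% spec$nodes))
    stop("evidence on unknown node(s): ",
         paste(setdiff(ev_nodes, spec$nodes), collapse = ", "))
  if (!query %in% spec$nodes) stop("unknown query node: ", query)
  if (query %in% ev_nodes) stop("query node is already observed")
  free <- setdiff(spec$nodes, ev_nodes)
  nf <- length(free)
  if (nf > 20L) stop("too many unobserved nodes for exact enumeration")
  m <- 2L^nf
  assign <- matrix(0L, nrow = m, ncol = length(spec$nodes),
                   dimnames = list(NULL, spec$nodes))
  for (j in seq_len(nf))
    assign[, free[j]] <- as.integer(bitwAnd(seq_len(m) - 1L, 2L^(j - 1L)) > 0L)
  if (length(ev_nodes))
    assign[, ev_nodes] <- matrix(rep(as.integer(ev != 0), each = m), nrow = m)
  joint <- joint_over_assignments(spec, cpds, assign)
  total <- sum(joint)
  if (total <= 0)
    stop("evidence has zero probability under the model")
  sum(joint[assign[, query] == 1L]) / total
}

#' Tile AO/OTA grade from the component instabilities
#'
#' Grade A: rotationally and translationally stable; grade B: rotationally
#' unstable, translationally stable; grade C: translationally unstable
#' (translational instability is the hallmark of global instability, so
#' `R = 0, T = 1` also maps to C).
#'
#' @param R,T logical (or 0/1) rotational / translational instability;
#'   vectorized.
#' @return Character vector of grades `"A"`, `"B"`, `"C"`.
#' @export
tile_from_instability <- function(R, T) {
  R <- as.logical(R); T <- as.logical(T)
  ifelse(T, "C", ifelse(R, "B", "A"))
}

#' Boolean age flag
#'
#' Ages below 60 map to 0, ages 60 and over to 1.
#'
#' @param age_years nonnegative integer age(s).
#' @return Integer 0/1 vector.
#' @export
age_flag <- function(age_years) {
  if (any(age_years < 0)) stop("negative age")
  as.integer(age_years >= 60)
}

#' Serialize / load a network and its CPDs
#'
#' Writes the structure and every conditional probability table to a
#' human-readable YAML file so the fitted model can be audited row by row.
#'
#' @param spec a `bn_spec`.
#' @param cpds named list of [cpd_table()]s.
#' @param path YAML file path.
#' @param provenance optional named list stored alongside the model.
#' @export
write_network <- function(spec, cpds, path, provenance = NULL) {
  rows <- function(cpd) {
    k <- length(cpd$parents)
    lapply(seq_len(2^k), function(i) {
      bits <- as.integer(bitwAnd(i - 1L, 2L^(seq_len(k) - 1L)) > 0L)
      list(config = if (k) paste(cpd$parents, bits, sep = "=", collapse = ",") else "",
           p1 = cpd$p1[i])
    })
  }
  obj <- list(schema_version = SCHEMA_VERSION,
              provenance = provenance,
              nodes = spec$nodes,
              edges = lapply(seq_len(nrow(spec$edges)), function(i)
                list(from = spec$edges$from[i], to = spec$edges$to[i])),
              cpds = lapply(unname(cpds), function(cpd)
                list(node = cpd$node, parents = as.list(cpd$parents),
                     rows = rows(cpd))))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_network
#' @return `read_network()` returns `list(spec, cpds)`.
#' @export
read_network <- function(path) {
  obj <- yaml::read_yaml(path)
  edges <- if (length(obj$edges)) {
    data.frame(from = vapply(obj$edges, `[[`, "", "from"),
               to = vapply(obj$edges, `[[`, "", "to"))
  } else data.frame(from = character(), to = character())
  spec <- network_spec(unlist(obj$nodes), edges)
  cpds <- lapply(obj$cpds, function(ct)
    cpd_table(ct$node, unlist(ct$parents) %||% character(),
              vapply(ct$rows, `[[`, numeric(1), "p1")))
  names(cpds) <- vapply(cpds, `[[`, "", "node")
  list(spec = spec, cpds = cpds[spec$nodes])
}
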