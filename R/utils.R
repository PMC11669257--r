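# Internal helpers shared across modules.

# Derive `n` reproducible child seeds from one master seed.  Every stage of
# the pipeline draws its own seed from this stream (stage order is fixed and
# documented in run_pipeline()), so stages can be re-run independently.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

abort_invalid <- function(msg) {
  rlang::abort(msg, class = "soilnet_invalid_argument")
}

abort_format <- function(msg) {
  rlang::abort(msg, class = "soilnet_format_error")
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_invalid(sprintf("`%s` must be a single finite number", name))
  }
}

# igraph helper: the same graph with edge weights stripped, for metrics that
# are defined on edge presence only (betweenness, efficiency, distances).
unweighted <- function(graph) {
  if ("weight" %in% igraph::edge_attr_names(graph)) {
    graph <- igraph::delete_edge_attr(graph, "weight")
  }
  graph
}
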