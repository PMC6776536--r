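`%||%` <- function(a, b) if (is.null(a)) b else a

# undirected edge data.frame (from, to, weight) from an igraph, weights
# taken as absolute values when asked
edge_table <- function(g, abs_weight = TRUE) {
  el <- igraph::as_data_frame(g, what = "edges")
  if (!"weight" %in% names(el)) el$weight <- 1
  if (abs_weight) el$weight <- abs(el$weight)
  el[, c("from", "to", "weight")]
}

# derive a stream of sub-seeds from one master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
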