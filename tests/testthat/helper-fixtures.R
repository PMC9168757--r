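# Shared fixtures. Simulated cohorts are memoized per (kind, seed) so tests
# that exercise different stages of the same planted cohort do not regenerate
# it.

.fixture_cache <- new.env(parent = emptyenv())

cached_bulk <- function(seed = 1L, ...) {
  key <- paste0("bulk_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_bulk_cohort(bulk_sim_config(seed = seed, ...))
  }
  .fixture_cache[[key]]
}

cached_sc <- function(seed = 1L, ...) {
  key <- paste0("sc_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_sc_cohort(sc_sim_config(seed = seed, ...))
  }
  .fixture_cache[[key]]
}

# Small labelled expression matrix.
toy_matrix <- function(values, genes = NULL, obs = NULL, ...) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(obs)) obs <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, obs)
  expr_matrix(values, ...)
}

# The reference-building steps shared by panel tests and acceptance runs:
# pseudo-bulk, three signature scores, quartile/zmax labels, signatures.
sc_reference <- function(sc) {
  pb <- pseudo_bulk(sc$expression, sc$cells)
  sets <- sc$truth$gene_sets
  scores <- dplyr::bind_rows(
    mean_signature_score(pb, sets$liver, "liver"),
    mean_signature_score(pb, sets$repressed, "immunosuppressed"),
    mean_signature_score(pb, sets$activatedT, "activatedT")
  )
  ref <- build_reference_labels(scores)
  list(pseudo_bulk = pb, scores = scores, labels = ref)
}

# Brute-force hypergeometric tail P(X >= x) by enumerating all C(N, n) draws.
hypergeom_bruteforce <- function(N, K, n, x) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # elements 1..K are the "successes"
  mean(hits >= x)
}
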