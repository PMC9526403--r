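# Shared fixtures, built once per test session.

.fixture_env <- new.env(parent = emptyenv())

## the anchored reference genome (deterministic layout + sequence)
fixture_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- make_genome(sim_config(profile = "pseudobassiana_like"))
  .fixture_env$sim
}

fixture_ann <- function() fixture_sim()$annotation

## one default random simulation with evidence, reused across tests
default_sim_evidence <- function() {
  if (is.null(.fixture_env$ev)) {
    sim <- make_genome(sim_config(seed = 7))
    mols <- simulate_processing(sim)
    .fixture_env$ev <- list(sim = sim, mols = mols,
                            ev = fragment_to_evidence(sim, mols))
  }
  .fixture_env$ev
}

## a small hand-built circular annotation for unit tests:
## geneA (PCG, with one intron), trnX, geneB (PCG), control; L = 2000
toy_annotation <- function() {
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE,
                      prob = c(.36, .14, .14, .36)), collapse = "")
  g <- circular_genome("toy", seq)
  feats <- data.frame(
    name = c("geneA", "trnX", "geneB", "control"),
    kind = c("PCG", "tRNA", "PCG", "control"),
    start = c(101L, 751L, 901L, 1501L),
    end = c(700L, 821L, 1400L, 1900L))
  introns <- data.frame(gene = "geneA", start = 301L, end = 500L)
  genome_annotation(g, feats, introns = introns)
}

## build a junction evidence table directly (for inference-only tests)
make_jev <- function(genes, statuses) {
  n <- length(genes)
  data.frame(upstream = genes,
             downstream = genes[c(2:n, 1L)],
             status = statuses)
}

circ_pos_test <- function(p, L) ((p - 1L) %% L) + 1L

## independent connected-components oracle over the circular junction list
oracle_unit_count <- function(statuses) {
  n <- length(statuses)
  edges <- which(statuses != "unsupported")
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) {
    from <- edges
    to <- ifelse(edges == n, 1L, edges + 1L)
    g <- igraph::add_edges(g, rbind(from, to))
  }
  igraph::components(g)$no
}
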