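# Shared fixtures, all generated in code.

# Hand-crafted linear chain graph with edge novel lengths 3, 4, 5 at
# k = 3 (vertex 2-mers chosen so no terminal collides with a reverse
# complement): distances from the chain start are 0, 3, 7, 12.
chain_graph <- function() {
  us <- c("AAGCC",        # AA -> CC, novel 3
          "CCTTAC",       # CC -> AC, novel 4
          "ACGGGCA")      # AC -> CA, novel 5
  readclouds:::new_assembly_graph(unique(c(us, revcomp(us))), 3)
}

vertex_id <- function(graph, kmer) {
  graph$vertices$vertex[match(kmer, graph$vertices$kmer)]
}

edge_id <- function(graph, sequence) {
  graph$edges$edge[match(sequence, graph$edges$sequence)]
}

# A kbp-scale chain for search-distance tests: four junction vertices
# in a row with novel lengths 4000, 7000, 4000 between them (k = 3).
kbp_chain_graph <- function() {
  span <- function(a, b, novel) {
    set.seed(novel) # filler content is irrelevant, only the length
    paste0(a, paste(sample(c("G", "T"), novel - 2, replace = TRUE),
                    collapse = ""), b)
  }
  # terminals: AA, CC, AC, CA (reverse complements TT, GG, GT, TG all
  # distinct from the forward set)
  us <- c(span("AA", "CC", 4000), span("CC", "AC", 7000),
          span("AC", "CA", 4000))
  readclouds:::new_assembly_graph(unique(c(us, revcomp(us))), 3)
}

# Minimal synthetic mapping-path rows for deconvolver unit tests.
path_row <- function(read_id, mate, vertices, t5, t3, umi, mapped = TRUE) {
  tibble::tibble(
    read_id = read_id, mate = mate, mapped = mapped, strand = "fwd",
    edges = list(integer(0)), vertices = list(as.integer(vertices)),
    terminal_5p = as.integer(t5), terminal_3p = as.integer(t3), umi = umi
  )
}

# The printed seven-read worked-example cloud: five reads agree down
# to family f_0, two sit higher (order o_0, kingdom k_0).
seven_read_cloud <- function() {
  as_classifications(tibble::tibble(
    read_id = paste0("read", 1:7),
    cloud_id = "cloud1",
    lineage = c(
      "k_0;p_0;c_0;o_0;f_0;g_0;s_0",
      "k_0;p_0;c_0;o_0;f_0;g_0;s_0",
      "k_0;p_0;c_0;o_0;f_0;g_0;s_1",
      "k_0;p_0;c_0;o_0;f_0;g_1",
      "k_0;p_0;c_0;o_0;f_0",
      "k_0;p_0;c_0;o_0",
      "k_0"
    )
  ))
}

# Small seeded end-to-end library shared by several test files
# (5 genomes x 60 kbp, 60 clouds of 2 fragments, error-free).
small_library <- function(seed = 11) {
  gen <- sim_genomes(5, 60000, seed = seed)
  cfg <- sim_config(n_umis = 60, fragments_per_umi = 2,
                    fragment_length = c(5000, 20000), error_rate = 0)
  list(genomes = gen, lib = sim_library(gen, cfg, seed = seed))
}

# Graph for the small library is built from the genomes themselves:
# error-free coverage of random sequence condenses back to one unitig
# per genome, which keeps unit tests fast and exact.
small_pipeline <- function(seed = 11, d = 5000) {
  sl <- small_library(seed)
  g <- build_graph(sl$genomes$sequence, k = 31)
  paths <- map_reads(g, sl$lib$reads)
  res <- deconvolve(g, paths = paths, config = deconv_config(d = d))
  c(sl, list(graph = g, paths = paths, result = res))
}
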