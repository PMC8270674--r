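# Shared fixtures, all built in code. Expensive objects (the default
# synthetic run and its network) are generated once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# tiny 3-domain table for I/O and filtering tests
tiny_table <- function() {
  counts <- matrix(
    c(10L, 5L, 0L, 2L,
      3L,  8L, 1L, 0L,
      0L,  0L, 4L, 6L,
      7L,  2L, 2L, 1L,
      1L,  1L, 9L, 3L,
      5L,  0L, 0L, 8L),
    nrow = 6, byrow = TRUE,
    dimnames = list(paste0("otu", 1:6), paste0("S", 1:4)))
  domain <- stats::setNames(
    c("bacteria", "bacteria", "bacteria", "archaea", "archaea", "eukaryota"),
    rownames(counts))
  lineage <- stats::setNames(
    paste(c("Bacteria", "Bacteria", "Bacteria", "Archaea", "Archaea",
            "Eukaryota"),
          c("Actinobacteria", "Proteobacteria", "Chloroflexi",
            "Thaumarchaeota", "Euryarchaeota", "Ascomycota"), sep = ";"),
    rownames(counts))
  otu_table(counts, domain, lineage)
}

# network with exactly the given edges (r defaults to 0.9, p to 0.001)
network_from_edges <- function(nodes, domains, edges, r = 0.9) {
  n <- length(nodes)
  rm_ <- diag(n)
  pm <- matrix(1, n, n)
  diag(pm) <- 0
  dimnames(rm_) <- dimnames(pm) <- list(nodes, nodes)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      rv <- if (ncol(edges) >= 3) as.numeric(edges[k, 3]) else r
      rm_[i, j] <- rm_[j, i] <- rv
      pm[i, j] <- pm[j, i] <- 0.001
    }
  }
  corr <- corr_matrix(rm_, pm, method = "spearman", n_samples = 14)
  build_network(corr, stats::setNames(domains, nodes))
}

complete_graph_network <- function(n, domain = "bacteria") {
  nodes <- sprintf("n%02d", seq_len(n))
  edges <- t(utils::combn(nodes, 2))
  network_from_edges(nodes, rep(domain, n), edges)
}

# closed-form natural connectivity of the complete graph K_n
nc_complete <- function(n) {
  if (n < 2) return(0)
  # ln((e^(n-1) + (n-1) e^-1) / n), factored to avoid overflow for large n
  (n - 1) + log1p((n - 1) * exp(-n)) - log(n)
}

default_metadata <- function() {
  cached("metadata", generate_metadata(gradient_config()))
}

default_sim <- function() {
  cached("sim", generate_otu_tables(default_metadata(),
                                    default_domain_configs(),
                                    default_planted_structure(),
                                    seed = 1L))
}

default_network <- function() {
  cached("network", {
    filt <- filter_rare_otus(default_sim()$table)
    build_network(spearman_matrix(filt), filt$domain,
                  pooled_rel_abundance(filt))
  })
}

# 50-OTU / 100-sample single-domain community with planted blocks, the
# parameter-recovery fixture for SparCC and network reconstruction
recovery_sim <- function() {
  cached("recovery", {
    md <- generate_metadata(gradient_config(n_sites = 100))
    cfg <- list(bacteria = domain_config("bacteria", pool_size = 50,
                                         richness_intercept = 50,
                                         richness_slope = 0, depth = 5000,
                                         lognormal_sigma = 1))
    st <- planted_structure(list(
      list(members = c("bac0001", "bac0002"), rho = 0.8),
      list(members = paste0("bac000", 3:5), rho = 0.8),
      list(members = c("bac0006", "bac0007", "bac0008"), rho = 0.8,
           signs = c(1, 1, -1)),
      list(members = c("bac0009", "bac0010"), rho = 0.8)))
    generate_otu_tables(md, cfg, st, seed = 11)
  })
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
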