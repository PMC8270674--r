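# Synthetic multi-domain OTU tables along an elevational gradient.
#
# The generator emulates, at the OTU-table level, a 14-site alpine-meadow
# survey spanning roughly 1,900-3,900 m: three domains (bacteria, archaea,
# eukaryota) with very different richness scales, bacterial and eukaryotic
# richness rising with elevation while archaeal richness stays flat, a
# narrow alkaline pH range, and a planted block-correlation structure
# dominated by positive associations. Ground truth (true richness and the
# planted edge list) is returned alongside the table so downstream
# estimators can be validated against known parameters.

#' Configure the elevational gradient and site covariates
#'
#' @param n_sites number of sampling sites (>= 3; regressions need 3 points).
#' @param elevation_min,elevation_max elevation range in metres.
#' @param mat_at_min mean annual temperature (deg C) at the lowest site.
#' @param mat_lapse temperature lapse rate in deg C per km of elevation
#'   (negative: cooler with height).
#' @param map_at_min mean annual precipitation (mm) at the lowest site.
#' @param map_slope precipitation gain in mm per km of elevation.
#' @param mat_noise_sd,map_noise_sd site-level micro-climate deviations
#'   (deg C, mm) around the lapse/slope lines; set to 0 for exactly linear
#'   climate columns.
#' @param ph_range two-element range soil pH is drawn from (alpine meadow
#'   soils here are narrowly alkaline).
#' @param ec_mean mean electrical conductivity (uS/cm), log-normal across sites.
#' @param tn_at_min total nitrogen (%) at the lowest site.
#' @param tn_slope total nitrogen gain in % per km of elevation.
#' @param tc_tn_mean mean soil TC/TN ratio.
#' @param seed integer seed controlling every random covariate.
#' @return an object of class `gradient_config`.
#' @export
gradient_config <- function(n_sites = 14,
                            elevation_min = 1936, elevation_max = 3896,
                            mat_at_min = 4.2, mat_lapse = -5.5,
                            map_at_min = 330, map_slope = 55,
                            mat_noise_sd = 0.3, map_noise_sd = 8,
                            ph_range = c(8.24, 8.95),
                            ec_mean = 150,
                            tn_at_min = 0.12, tn_slope = 0.08,
                            tc_tn_mean = 11,
                            seed = 1L) {
  if (n_sites < 3) {
    stop("configuration error: n_sites must be >= 3 (regressions are undefined below that)")
  }
  if (!(elevation_min < elevation_max)) {
    stop("configuration error: elevation_min must be < elevation_max")
  }
  if (length(ph_range) != 2 || any(ph_range < 0) || any(ph_range > 14) ||
      ph_range[1] > ph_range[2]) {
    stop("configuration error: ph_range must be an increasing pair within [0, 14]")
  }
  structure(list(
    n_sites = as.integer(n_sites),
    elevation_min = elevation_min, elevation_max = elevation_max,
    mat_at_min = mat_at_min, mat_lapse = mat_lapse,
    map_at_min = map_at_min, map_slope = map_slope,
    mat_noise_sd = mat_noise_sd, map_noise_sd = map_noise_sd,
    ph_range = ph_range, ec_mean = ec_mean,
    tn_at_min = tn_at_min, tn_slope = tn_slope,
    tc_tn_mean = tc_tn_mean,
    seed = as.integer(seed)
  ), class = "gradient_config")
}

#' Generate per-site sample metadata for a gradient configuration
#'
#' Elevations are evenly spaced across the configured range. MAT and MAP
#' follow the configured lapse/slope lines plus optional site-level noise;
#' pH is uniform within `ph_range`; EC is log-normal; TN rises with
#' elevation; TC is derived from TN and a site TC/TN ratio so that the
#' stored ratio is exact.
#'
#' @param config a [gradient_config()].
#' @return a `data.frame` of class `sample_metadata` with columns
#'   `sample_id`, `latitude`, `longitude`, `elevation`, `MAT`, `MAP`, `pH`,
#'   `EC`, `TC`, `TN`, `TC_TN`.
#' @export
generate_metadata <- function(config) {
  stopifnot(inherits(config, "gradient_config"))
  n <- config$n_sites
  elev <- seq(config$elevation_min, config$elevation_max, length.out = n)
  dkm <- (elev - config$elevation_min) / 1000
  with_seed(config$seed, {
    md <- data.frame(
      sample_id = sprintf("S%02d", seq_len(n)),
      latitude = round(38.2 + stats::runif(n, -0.5, 0.5), 4),
      longitude = round(99.5 + stats::runif(n, -1, 1), 4),
      elevation = elev,
      MAT = config$mat_at_min + config$mat_lapse * dkm +
        stats::rnorm(n, 0, config$mat_noise_sd),
      MAP = config$map_at_min + config$map_slope * dkm +
        stats::rnorm(n, 0, config$map_noise_sd),
      pH = stats::runif(n, config$ph_range[1], config$ph_range[2]),
      EC = stats::rlnorm(n, log(config$ec_mean), 0.25),
      TN = pmax(config$tn_at_min + config$tn_slope * dkm +
                  stats::rnorm(n, 0, 0.02), 0.02),
      stringsAsFactors = FALSE
    )
    ratio <- pmax(stats::rnorm(n, config$tc_tn_mean, 0.8), 5)
    md$TC <- md$TN * ratio
    md$TC_TN <- md$TC / md$TN
    md <- md[, c("sample_id", "latitude", "longitude", "elevation",
                 "MAT", "MAP", "pH", "EC", "TC", "TN", "TC_TN")]
    class(md) <- c("sample_metadata", "data.frame")
    md
  })
}

#' Configure one domain's regional OTU pool
#'
#' @param domain one of `"bacteria"`, `"archaea"`, `"eukaryota"`.
#' @param pool_size OTUs in the regional pool.
#' @param richness_intercept,richness_slope realized per-site richness model
#'   `intercept + slope * elevation_km + N(0, richness_sd)`; slope is OTUs
#'   per km so a flat domain simply uses slope 0.
#' @param richness_sd standard deviation of the site-to-site richness noise.
#' @param depth sequencing reads per sample for this domain (multinomial
#'   total; every sample's domain counts sum to exactly this).
#' @param lognormal_sigma dispersion of the log-normal species-abundance
#'   distribution on the latent log scale.
#' @param env_response_mean,env_response_sd per-OTU loadings on the shared
#'   standardized-elevation factor are drawn `N(mean, sd)`; a positive mean
#'   makes most taxa respond in the same direction along the gradient.
#'   Defaults 0 (no environmental turnover).
#' @param domain_factor_mean,domain_factor_sd per-OTU loadings on the
#'   domain-private latent factors (iid standard-normal scores per sample),
#'   modelling coherent within-domain co-variation that is not shared
#'   across domains. Defaults 0.
#' @param domain_factor_k number of independent domain-private factors
#'   (response guilds); each OTU loads on exactly one. More factors spread
#'   the same amount of within-domain co-variation over more, smaller
#'   coherent groups.
#' @return an object of class `domain_config`.
#' @export
domain_config <- function(domain, pool_size, richness_intercept,
                          richness_slope, depth, lognormal_sigma,
                          richness_sd = 0,
                          env_response_mean = 0, env_response_sd = 0,
                          domain_factor_mean = 0, domain_factor_sd = 0,
                          domain_factor_k = 1) {
  domain <- match.arg(domain, DOMAINS)
  if (depth <= 0) stop("depth must be > 0")
  if (lognormal_sigma <= 0) stop("lognormal_sigma must be > 0")
  if (pool_size < 2) stop("pool_size must be >= 2")
  structure(list(domain = domain, pool_size = as.integer(pool_size),
                 richness_intercept = richness_intercept,
                 richness_slope = richness_slope,
                 richness_sd = richness_sd,
                 depth = as.integer(depth),
                 lognormal_sigma = lognormal_sigma,
                 env_response_mean = env_response_mean,
                 env_response_sd = env_response_sd,
                 domain_factor_mean = domain_factor_mean,
                 domain_factor_sd = domain_factor_sd,
                 domain_factor_k = as.integer(domain_factor_k)),
            class = "domain_config")
}

#' Default domain configurations for the study conditions
#'
#' Encodes the community scales of the emulated survey: bacterial OTU
#' richness in the low thousands rising steeply with elevation, archaeal
#' richness in the hundreds with no elevational trend (but large
#' site-to-site scatter), and eukaryotic richness of one to a few hundred
#' rising moderately. Sequencing depths are the per-domain rarefaction
#' depths used throughout (30,671 / 17,561 / 42,299 reads).
#'
#' @return named list of [domain_config()] objects.
#' @export
default_domain_configs <- function() {
  list(
    bacteria = domain_config("bacteria", pool_size = 3600,
                             richness_intercept = 700, richness_slope = 560,
                             richness_sd = 120, depth = 30671,
                             lognormal_sigma = 1.6,
                             env_response_mean = 0.15, env_response_sd = 0.25,
                             domain_factor_mean = 0.55, domain_factor_sd = 0.45,
                             domain_factor_k = 10),
    archaea = domain_config("archaea", pool_size = 1500,
                            richness_intercept = 420, richness_slope = 0,
                            richness_sd = 130, depth = 17561,
                            lognormal_sigma = 1.8,
                            env_response_mean = 0.15, env_response_sd = 0.25,
                            domain_factor_mean = 0.6, domain_factor_sd = 0.45,
                            domain_factor_k = 1),
    eukaryota = domain_config("eukaryota", pool_size = 520,
                              richness_intercept = -20, richness_slope = 60,
                              richness_sd = 30, depth = 42299,
                              lognormal_sigma = 1.4,
                              env_response_mean = 0.15, env_response_sd = 0.25,
                              domain_factor_mean = 0.55, domain_factor_sd = 0.45,
                              domain_factor_k = 4)
  )
}

otu_id <- function(domain, i) {
  prefix <- c(bacteria = "bac", archaea = "arc", eukaryota = "euk")[domain]
  sprintf("%s%04d", prefix, i)
}

block_edges <- function(members, signs) {
  idx <- utils::combn(seq_along(members), 2)
  data.frame(otu_a = members[idx[1, ]], otu_b = members[idx[2, ]],
             sign = ifelse(signs[idx[1, ]] * signs[idx[2, ]] > 0,
                           "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Define the planted correlation structure
#'
#' Each block is a set of OTUs sharing one latent Gaussian factor; a member
#' with loading sign -1 is anti-correlated with the + members of its block.
#' The block's `rho` is the target *basis* correlation between any two
#' members on the latent log-abundance scale (loadings are
#' `sqrt(rho / (1 - rho))` against unit idiosyncratic noise). Every planted
#' within-block pair becomes a ground-truth edge whose sign is the product
#' of the member signs; `fraction_negative` is computed from that edge list,
#' so the positive-edge fraction of the ground truth equals its complement
#' exactly.
#'
#' @param blocks list of blocks, each a list with elements `members`
#'   (character OTU ids), `rho` (target basis correlation in (0, 1)), and
#'   optionally `signs` (+1/-1 per member, default all +1). Blocks whose
#'   members span two domains are the cross-domain blocks.
#' @param fraction_negative optional; if supplied it must equal the realized
#'   negative-edge fraction of the implied edge list exactly.
#' @return object of class `planted_structure` with the implied `edges`.
#' @export
planted_structure <- function(blocks, fraction_negative = NULL) {
  all_members <- unlist(lapply(blocks, `[[`, "members"))
  if (anyDuplicated(all_members)) {
    stop("every member OTU must belong to exactly one block; duplicated: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  }
  blocks <- lapply(blocks, function(b) {
    if (is.null(b$signs)) b$signs <- rep(1, length(b$members))
    stopifnot(length(b$signs) == length(b$members),
              all(b$signs %in% c(-1, 1)),
              b$rho > 0, b$rho < 1, length(b$members) >= 2)
    b
  })
  edges <- do.call(rbind, lapply(blocks, function(b) {
    e <- block_edges(b$members, b$signs)
    e$rho <- b$rho
    e
  }))
  rownames(edges) <- NULL
  realized <- mean(edges$sign == "negative")
  if (!is.null(fraction_negative) && fraction_negative != realized) {
    stop(sprintf(
      "fraction_negative %.6f does not match the edge list implied by the blocks (%.6f)",
      fraction_negative, realized))
  }
  structure(list(blocks = blocks, edges = edges,
                 fraction_negative = realized),
            class = "planted_structure")
}

#' Default planted structure: positive-dominated, archaea as hub domain
#'
#' The archaeal domain carries one large tight block (a clique of strongly
#' positively associated OTUs) plus cross-domain blocks linking it to
#' bacteria and to eukaryota, making archaea the structural hub of the
#' planted network. Bacterial blocks are more numerous but smaller, with a
#' minority of negatively loaded members, so positive planted edges
#' dominate and intradomain edges outnumber interdomain ones.
#'
#' @param rho target basis correlation for ordinary blocks.
#' @param hub_rho target basis correlation for the archaeal hub clique.
#' @return a [planted_structure()].
#' @export
default_planted_structure <- function(rho = 0.85, hub_rho = 0.9) {
  bac <- function(i) otu_id("bacteria", i)
  arc <- function(i) otu_id("archaea", i)
  euk <- function(i) otu_id("eukaryota", i)
  blocks <- list(
    # archaeal hub clique: large, abundant and tight, so any scenario that
    # retains archaea keeps a strongly connected spectral core
    list(members = arc(1:40), rho = hub_rho),
    # bacterial blocks, two all-positive and two with negative members
    list(members = bac(1:7), rho = rho),
    list(members = bac(8:14), rho = rho),
    list(members = bac(15:22), rho = rho,
         signs = c(1, 1, 1, 1, 1, -1, -1, -1)),
    list(members = bac(23:30), rho = rho,
         signs = c(1, 1, 1, 1, 1, -1, -1, -1)),
    # eukaryotic block
    list(members = euk(1:6), rho = rho),
    # cross-domain blocks: archaea bridge to both other domains
    list(members = c(arc(41:44), bac(31:34)), rho = rho),
    list(members = c(arc(45:47), euk(7:9)), rho = rho),
    list(members = c(bac(35:36), euk(10:11)), rho = rho,
         signs = c(1, 1, 1, -1))
  )
  planted_structure(blocks)
}

#' Generate multi-domain OTU count tables with known ground truth
#'
#' Per domain, each OTU gets a log-normal baseline abundance; planted block
#' members additionally load on shared latent Gaussian factors (loading
#' `sign * sqrt(rho/(1-rho))` against unit-variance idiosyncratic noise, so
#' the pairwise latent correlation is the block's `rho`). Per site, realized
#' richness follows the domain's elevational richness model; the realized
#' OTU set is the planted members plus the highest-latent-abundance
#' remaining OTUs, and counts are a single multinomial draw of the domain's
#' depth over that set (compositional closure: per-sample per-domain totals
#' equal the configured depth exactly).
#'
#' @param metadata a `sample_metadata` table from [generate_metadata()].
#' @param domain_configs named list of [domain_config()]s (one per domain).
#' @param structure a [planted_structure()]; members must reference ids
#'   within the configured pools (`bac0001`, `arc0001`, `euk0001`, ...).
#' @param seed integer seed.
#' @return list with elements `table` (an [otu_table()], all-zero OTUs
#'   dropped) and `truth` (class `ground_truth`: per-domain true richness
#'   per site, the planted edge list with signs, and the generative
#'   parameters echoed back).
#' @export
generate_otu_tables <- function(metadata, domain_configs, structure, seed = 1L) {
  stopifnot(inherits(metadata, "sample_metadata"),
            inherits(structure, "planted_structure"))
  n <- nrow(metadata)
  elev_km <- metadata$elevation / 1000

  pool_ids <- lapply(domain_configs, function(dc) otu_id(dc$domain, seq_len(dc$pool_size)))
  names(pool_ids) <- vapply(domain_configs, `[[`, "", "domain")
  known <- unlist(pool_ids, use.names = FALSE)
  bad <- setdiff(unlist(lapply(structure$blocks, `[[`, "members")), known)
  if (length(bad)) {
    stop("planted block members not in any configured pool: ",
         paste(bad, collapse = ", "))
  }

  # loading per planted member, indexed by OTU id
  loading <- numeric(0)
  block_of <- integer(0)
  for (b in seq_along(structure$blocks)) {
    blk <- structure$blocks[[b]]
    a <- sqrt(blk$rho / (1 - blk$rho))
    loading[blk$members] <- blk$signs * a
    block_of[blk$members] <- b
  }

  elev_std <- as.vector(scale(metadata$elevation))
  with_seed(seed, {
    z <- matrix(stats::rnorm(length(structure$blocks) * n), ncol = n) # factor x site
    counts_list <- list()
    truth_rich <- list()
    for (dc in domain_configs) {
      d <- dc$domain
      ids <- pool_ids[[d]]
      planted <- intersect(ids, names(loading))
      free <- setdiff(ids, planted)
      mu <- stats::rnorm(dc$pool_size, 0, dc$lognormal_sigma)
      names(mu) <- ids
      # planted members sit in the abundant tail of the domain's SAD
      # (around the 90th percentile) so their associations are observable
      mu[planted] <- mu[planted] / 4 + 1.3 * dc$lognormal_sigma
      lam <- matrix(mu, nrow = dc$pool_size, ncol = n) +
        matrix(stats::rnorm(dc$pool_size * n), dc$pool_size, n)
      rownames(lam) <- ids
      # background structure for non-planted OTUs: a shared response to the
      # elevational gradient plus a domain-private factor (coherent
      # within-domain co-variation not shared across domains)
      if (length(free)) {
        g <- stats::rnorm(length(free), dc$env_response_mean, dc$env_response_sd)
        h <- stats::rnorm(length(free), dc$domain_factor_mean, dc$domain_factor_sd)
        k <- max(dc$domain_factor_k, 1L)
        guild <- sample.int(k, length(free), replace = TRUE)
        u <- matrix(stats::rnorm(k * n), k, n)
        lam[free, ] <- lam[free, ] + outer(g, elev_std) + h * u[guild, , drop = FALSE]
      }
      if (length(planted)) {
        lam[planted, ] <- lam[planted, ] +
          loading[planted] * z[block_of[planted], , drop = FALSE]
      }
      S <- round(dc$richness_intercept + dc$richness_slope * elev_km +
                   stats::rnorm(n, 0, dc$richness_sd))
      S <- pmin(pmax(S, length(planted) + 2L), dc$pool_size)
      cnt <- matrix(0L, dc$pool_size, n, dimnames = list(ids, metadata$sample_id))
      for (s in seq_len(n)) {
        extra <- setdiff(ids, planted)
        keep <- c(planted,
                  extra[order(lam[extra, s], decreasing = TRUE)[seq_len(S[s] - length(planted))]])
        p <- exp(lam[keep, s])
        cnt[keep, s] <- as.integer(stats::rmultinom(1, dc$depth, p / sum(p)))
      }
      counts_list[[d]] <- cnt
      truth_rich[[d]] <- data.frame(sample_id = metadata$sample_id,
                                    domain = d, true_richness = as.integer(S),
                                    stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, counts_list)
    domain <- rep(names(counts_list), vapply(counts_list, nrow, 0L))
    names(domain) <- rownames(counts)
    lineage <- assign_lineages(rownames(counts), domain)
    nonzero <- rowSums(counts) > 0
    tab <- otu_table(counts[nonzero, , drop = FALSE],
                     domain[nonzero], lineage[nonzero])
    truth <- structure(list(
      richness = do.call(rbind, c(truth_rich, list(make.row.names = FALSE))),
      edges = structure$edges,
      fraction_negative = structure$fraction_negative,
      params = list(domain_configs = domain_configs, seed = seed)
    ), class = "ground_truth")
    list(table = tab, truth = truth)
  })
}

# Phylum-level lineages drawn from the handful of phyla that dominate
# alkaline alpine-meadow soils; only domain and phylum ranks are consumed
# downstream.
assign_lineages <- function(ids, domain) {
  phyla <- list(
    bacteria = c("Actinobacteria", "Proteobacteria", "Acidobacteria",
                 "Chloroflexi", "Gemmatimonadetes", "Bacteroidetes",
                 "Verrucomicrobia", "Patescibacteria"),
    archaea = c("Thaumarchaeota", "Euryarchaeota", "Archaea_unclassified"),
    eukaryota = c("Ascomycota", "Basidiomycota", "Mucoromycota",
                  "Ciliophora", "Fungi_unclassified")
  )
  root <- c(bacteria = "Bacteria", archaea = "Archaea", eukaryota = "Eukaryota")
  vapply(seq_along(ids), function(i) {
    d <- domain[i]
    ph <- phyla[[d]][(match(ids[i], ids) %% length(phyla[[d]])) + 1]
    paste(root[d], ph, sep = ";")
  }, "")
}

#' @export
print.planted_structure <- function(x, ...) {
  cat(sprintf("planted_structure: %d blocks, %d edges (%.1f%% negative)\n",
              length(x$blocks), nrow(x$edges), 100 * x$fraction_negative))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d planted edges, richness for %d site-domain pairs\n",
              nrow(x$edges), nrow(x$richness)))
  invisible(x)
}
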