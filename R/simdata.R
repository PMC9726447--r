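#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical shape of a joint-genotyped panel of
#' diverged source populations plus one hybrid query: several populations
#' with two strains each, sites placed by a Poisson process, a configurable
#' fraction of sites carrying an allele private to exactly one population
#' (the diagnostic signal), low within-strain heterozygosity, and optional
#' missingness and genotyping error. The hybrid's genome is a mosaic of
#' tracts copied from the source populations, recorded as ground truth.
#'
#' Defaults describe one 500-kb chromosome with one diagnostic-scale site
#' every 200 bp on average, 80% of sites private to a single population,
#' 1% within-strain heterozygosity and no missingness or genotyping error —
#' a clean baseline onto which noise is added explicitly.
#'
#' @param seed Integer seed; every draw in the generator is derived from it.
#' @param n_chromosomes,chrom_length Number and length (bp) of chromosomes.
#' @param n_populations,strains_per_population Panel shape (default 3 x 2).
#' @param site_density Expected sites per bp (default 1/200).
#' @param private_allele_fraction Fraction of sites whose ALT allele is
#'   carried by exactly one population (default 0.8); the remainder carry an
#'   ALT shared by two populations.
#' @param het_rate Per-strain, per-site probability of an extra heterozygous
#'   call (default 0.01).
#' @param missing_rate Per-genotype missingness probability applied to all
#'   samples, query included (default 0).
#' @param genotype_error_rate Per-genotype probability of replacing the call
#'   with a different genotype (default 0).
#' @param tract_spec `"random"` or an explicit data frame with columns
#'   `chrom`, `start`, `end` (0-based half-open), `label` tiling each
#'   chromosome.
#' @param n_tracts Number of hybrid tracts when `tract_spec = "random"`
#'   (default 10, split across chromosomes in proportion to length).
#' @param population_labels Labels; default Tibet / Ireland / NorthCarolina
#'   for three populations, else Pop1..PopK.
#' @param query_name Name of the hybrid sample (default "hybrid").
#' @param degrade Inject sub-threshold DP/GQ values into 5% of genotypes to
#'   exercise the quality filters (default FALSE; otherwise DP = 50, GQ = 99
#'   everywhere).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 1L, chrom_length = 500000L,
                       n_populations = 3L, strains_per_population = 2L,
                       site_density = 1 / 200, private_allele_fraction = 0.8,
                       het_rate = 0.01, missing_rate = 0,
                       genotype_error_rate = 0, tract_spec = "random",
                       n_tracts = 10L, population_labels = NULL,
                       query_name = "hybrid", degrade = FALSE) {
  rates <- c(private_allele_fraction, het_rate, missing_rate, genotype_error_rate)
  if (any(rates < 0 | rates > 1)) stop("rates/proportions must lie in [0, 1]", call. = FALSE)
  if (site_density <= 0) stop("site_density must be positive", call. = FALSE)
  if (n_populations < 2) stop("need at least two populations", call. = FALSE)
  if (is.null(population_labels)) {
    population_labels <- if (n_populations == 3) {
      c("Tibet", "Ireland", "NorthCarolina")
    } else {
      paste0("Pop", seq_len(n_populations))
    }
  }
  if (length(population_labels) != n_populations) {
    stop("population_labels length must equal n_populations", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.numeric(chrom_length),
                 n_populations = as.integer(n_populations),
                 strains_per_population = as.integer(strains_per_population),
                 site_density = site_density,
                 private_allele_fraction = private_allele_fraction,
                 het_rate = het_rate, missing_rate = missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 tract_spec = tract_spec, n_tracts = as.integer(n_tracts),
                 population_labels = population_labels,
                 query_name = as.character(query_name), degrade = isTRUE(degrade)),
            class = "sim_config")
}

sim_strain_names <- function(cfg) {
  unlist(lapply(cfg$population_labels, function(p) {
    paste0(p, "_s", seq_len(cfg$strains_per_population))
  }))
}

sim_index <- function(cfg) {
  genome_index(sprintf("chr%02d", seq_len(cfg$n_chromosomes)),
               rep(cfg$chrom_length, cfg$n_chromosomes))
}

#' Simulate the source-population panel
#'
#' Places SNP sites by a Poisson process along each chromosome and draws
#' genotypes for every source strain. With probability
#' `private_allele_fraction` a site's ALT allele is private to one population
#' (all its strains homozygous ALT, everyone else homozygous REF); otherwise
#' the ALT is shared by two populations. On top, each strain independently
#' becomes heterozygous at a site with probability `het_rate`. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List: `table` (a [variant_table()] of source strains only),
#'   `origin` (per-site character: the private population's label, or `NA`
#'   for shared sites).
#' @export
simulate_populations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  index <- sim_index(cfg)
  strains <- sim_strain_names(cfg)
  k <- cfg$n_populations
  pop_of_strain <- rep(cfg$population_labels, each = cfg$strains_per_population)

  chroms <- list()
  for (i in seq_len(nrow(index))) {
    n <- stats::rpois(1, index$length[i] * cfg$site_density)
    if (n == 0) {
      warning("chromosome ", index$name[i], " received 0 simulated sites")
      next
    }
    pos <- sort(sample.int(index$length[i], min(n, index$length[i])))
    chroms[[index$name[i]]] <- data.frame(chrom = index$name[i], pos = pos,
                                          stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, unname(chroms))
  n <- nrow(sites)
  bases <- c("A", "C", "G", "T")
  ref_i <- sample.int(4, n, replace = TRUE)
  alt_i <- ((ref_i - 1L + sample.int(3, n, replace = TRUE)) %% 4L) + 1L
  sites$ref <- bases[ref_i]
  sites$alt <- bases[alt_i]

  private <- stats::runif(n) < cfg$private_allele_fraction
  origin <- rep(NA_character_, n)
  origin[private] <- sample(cfg$population_labels, sum(private), replace = TRUE)
  # shared sites: ALT carried by two populations
  carrier <- matrix(FALSE, n, k, dimnames = list(NULL, cfg$population_labels))
  carrier[cbind(which(private), match(origin[private], cfg$population_labels))] <- TRUE
  for (j in which(!private)) {
    carrier[j, sample.int(k, 2)] <- TRUE
  }

  ns <- length(strains)
  a1 <- matrix(0L, n, ns); a2 <- matrix(0L, n, ns)
  for (s in seq_len(ns)) {
    alt_carrier <- carrier[, pop_of_strain[s]]
    a1[alt_carrier, s] <- 1L
    a2[alt_carrier, s] <- 1L
    het <- stats::runif(n) < cfg$het_rate
    a1[het, s] <- 0L
    a2[het, s] <- 1L
  }
  dp <- matrix(50L, n, ns); gq <- matrix(99L, n, ns)
  if (cfg$degrade) {
    low <- matrix(stats::runif(n * ns) < 0.05, n, ns)
    dp[low] <- sample(0:14, sum(low), replace = TRUE)
    low2 <- matrix(stats::runif(n * ns) < 0.05, n, ns)
    gq[low2] <- sample(0:39, sum(low2), replace = TRUE)
  }
  vt <- variant_table(strains, index, sites, a1, a2, dp = dp, gq = gq)
  list(table = vt, origin = origin)
}

#' Random truth tracts tiling the genome
#'
#' Splits the genome into `n_tracts` tracts at uniform random breakpoints
#' (allocated to chromosomes in proportion to length) and labels them so
#' that adjacent tracts come from different populations. Uses the current
#' RNG state.
#'
#' @param index A [genome_index()].
#' @param n_tracts Total number of tracts (>= number of chromosomes).
#' @param labels Population labels to draw from.
#' @return Data frame `chrom`, `start`, `end` (0-based half-open), `label`.
#' @export
random_tracts <- function(index, n_tracts, labels) {
  if (n_tracts < nrow(index)) stop("need at least one tract per chromosome", call. = FALSE)
  alloc <- pmax(1L, round(n_tracts * index$length / sum(index$length)))
  while (sum(alloc) > n_tracts) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_tracts) alloc[which.min(alloc)] <- alloc[which.min(alloc)] + 1L
  out <- list()
  for (i in seq_len(nrow(index))) {
    m <- alloc[i]; len <- index$length[i]
    cuts <- if (m > 1) sort(sample.int(len - 1, m - 1)) else numeric(0)
    start <- c(0, cuts); end <- c(cuts, len)
    lab <- character(m)
    lab[1] <- sample(labels, 1)
    for (j in seq_len(m)[-1]) lab[j] <- sample(setdiff(labels, lab[j - 1]), 1)
    out[[i]] <- data.frame(chrom = index$name[i], start = start, end = end,
                           label = lab, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

validate_tracts <- function(tracts, index, labels) {
  req <- c("chrom", "start", "end", "label")
  if (!all(req %in% names(tracts))) stop("tract spec needs chrom, start, end, label", call. = FALSE)
  bad <- setdiff(unique(tracts$label), labels)
  if (length(bad)) stop("tract references unknown population: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(index))) {
    t <- tracts[tracts$chrom == index$name[i], , drop = FALSE]
    t <- t[order(t$start), , drop = FALSE]
    ok <- nrow(t) > 0 && t$start[1] == 0 && t$end[nrow(t)] == index$length[i] &&
      (nrow(t) == 1 || all(t$start[-1] == t$end[-nrow(t)]))
    if (!ok) stop("tract spec does not tile chromosome ", index$name[i], call. = FALSE)
  }
  invisible(tracts)
}

#' Add the mosaic hybrid query to a simulated panel
#'
#' Within each truth tract the query's genotypes copy one randomly chosen
#' strain of the tract's source population. Afterwards `missing_rate` masks
#' genotypes and `genotype_error_rate` replaces calls with a different
#' genotype, independently over all samples (query included). Uses the
#' current RNG state; [simulate_dataset()] wires up full seeding.
#'
#' @param pop_out Output of [simulate_populations()].
#' @param tracts Truth-tract data frame tiling each chromosome (0-based
#'   half-open, labels drawn from the population labels).
#' @param cfg The [sim_config()].
#' @return List: `table` (full [variant_table()] including the query) and
#'   `truth` (the tract data frame).
#' @export
simulate_hybrid <- function(pop_out, tracts, cfg) {
  vt <- pop_out$table
  validate_tracts(tracts, vt$index, cfg$population_labels)
  strains <- vt$roster
  pop_of_strain <- rep(cfg$population_labels, each = cfg$strains_per_population)
  n <- n_sites(vt)
  qa1 <- integer(n); qa2 <- integer(n)
  for (i in seq_len(nrow(tracts))) {
    donor_pool <- which(pop_of_strain == tracts$label[i])
    donor <- donor_pool[sample.int(length(donor_pool), 1)]
    in_tract <- vt$sites$chrom == tracts$chrom[i] &
      vt$sites$pos > tracts$start[i] & vt$sites$pos <= tracts$end[i]
    qa1[in_tract] <- vt$a1[in_tract, donor]
    qa2[in_tract] <- vt$a2[in_tract, donor]
  }
  full <- variant_table(c(strains, cfg$query_name), vt$index, vt$sites,
                        cbind(vt$a1, qa1), cbind(vt$a2, qa2),
                        dp = cbind(vt$dp, rep(50L, n)),
                        gq = cbind(vt$gq, rep(99L, n)))
  ns <- n_samples(full)
  if (cfg$genotype_error_rate > 0) {
    err <- matrix(stats::runif(n * ns) < cfg$genotype_error_rate, n, ns) & !is.na(full$a1)
    if (any(err)) {
      cur <- full$a1[err] + full$a2[err]              # genotype coded 0, 1, 2
      shift <- sample.int(2, sum(err), replace = TRUE) # move to one of the other two
      new <- (cur + shift) %% 3L
      full$a1[err] <- as.integer(new >= 1L)
      full$a2[err] <- as.integer(new == 2L)
    }
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(n * ns) < cfg$missing_rate, n, ns)
    full$a1[miss] <- NA_integer_
    full$a2[miss] <- NA_integer_
  }
  list(table = full, truth = tracts)
}

#' Simulate a complete study-shaped dataset
#'
#' Convenience wrapper: [simulate_populations()], truth tracts (random or
#' explicit), [simulate_hybrid()], and the matching [population_scheme()]
#' (assignment rep = first strain of each population, exclusion reps = all
#' its strains). Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List: `table`, `truth`, `scheme`, `index`, `origin`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  pops <- simulate_populations(cfg)
  tracts <- if (is.data.frame(cfg$tract_spec)) {
    cfg$tract_spec
  } else {
    random_tracts(pops$table$index, cfg$n_tracts, cfg$population_labels)
  }
  hyb <- simulate_hybrid(pops, tracts, cfg)
  strains <- sim_strain_names(cfg)
  pop_of_strain <- rep(cfg$population_labels, each = cfg$strains_per_population)
  populations <- lapply(cfg$population_labels, function(p) {
    list(assign = strains[pop_of_strain == p][1], exclude = strains[pop_of_strain == p])
  })
  names(populations) <- cfg$population_labels
  scheme <- population_scheme(cfg$query_name, populations)
  list(table = hyb$table, truth = hyb$truth, scheme = scheme,
       index = hyb$table$index, origin = pops$origin)
}

#' Per-population truth proportions
#'
#' @param truth Truth-tract data frame.
#' @param labels Population label order.
#' @param index Optional [genome_index()]; denominator defaults to total
#'   tract length.
#' @return Named numeric vector of percentages summing to 100.
#' @export
truth_percent <- function(truth, labels, index = NULL) {
  len <- truth$end - truth$start
  total <- if (is.null(index)) sum(len) else genome_bp(index)
  bp <- tapply(len, factor(truth$label, levels = labels), sum)
  bp[is.na(bp)] <- 0
  stats::setNames(100 * as.numeric(bp) / total, labels)
}

#' Write a simulated dataset to disk
#'
#' Emits `sim.vcf`, `sim.fai`, `truth.bed` and `scheme.yaml` into `dir`.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "sim.vcf"), fai = file.path(dir, "sim.fai"),
             truth = file.path(dir, "truth.bed"), scheme = file.path(dir, "scheme.yaml"))
  write_vcf(sim$table, paths["vcf"])
  write_genome_index(sim$index, paths["fai"])
  write_bed(sim$truth, paths["truth"], index = sim$index)
  write_scheme(sim$scheme, paths["scheme"])
  invisible(paths)
}

#' Read/write a population scheme as YAML
#'
#' @param scheme A [population_scheme()].
#' @param path File path.
#' @return `read_scheme()` returns a `population_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "population_scheme"))
  yaml::write_yaml(list(query = scheme$query, populations = scheme$populations), path)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  population_scheme(y$query, y$populations)
}
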