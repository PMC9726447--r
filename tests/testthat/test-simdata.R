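test_that("the generator is deterministic and has the configured panel shape", {
  cfg <- sim_config(seed = 13, chrom_length = 30000)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_equal(s1$table$sites, s2$table$sites)
  expect_equal(s1$table$a1, s2$table$a1)
  expect_equal(s1$truth, s2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  expect_equal(unname(tools::md5sum(file.path(d1, "sim.vcf"))),
               unname(tools::md5sum(file.path(d2, "sim.vcf"))))

  expect_equal(n_samples(s1$table), 3 * 2 + 1)
  expect_equal(s1$table$roster[7], "hybrid")
  expect_equal(names(s1$scheme$populations), c("Tibet", "Ireland", "NorthCarolina"))
  # scheme round-trips through YAML
  p <- file.path(d1, "scheme.yaml")
  expect_equal(read_scheme(p)$populations, s1$scheme$populations)
})

test_that("private sites are diagnostic for exactly one population", {
  cfg <- sim_config(seed = 17, chrom_length = 20000,
                    private_allele_fraction = 1, het_rate = 0)
  pops <- simulate_populations(cfg)
  expect_true(all(!is.na(pops$origin)))
  vt <- pops$table
  pop_of_strain <- rep(cfg$population_labels, each = 2)
  carries_alt <- (vt$a1 == 1L) | (vt$a2 == 1L)
  for (p in cfg$population_labels) {
    own <- pop_of_strain == p
    sel <- pops$origin == p
    expect_true(all(carries_alt[sel, own]))
    expect_false(any(carries_alt[sel, !own]))
  }
})

test_that("truth tracts tile the genome and bad specs are rejected", {
  sim <- simulate_dataset(sim_config(seed = 19, n_chromosomes = 2,
                                     chrom_length = 25000, n_tracts = 6))
  for (ch in sim$index$name) {
    t <- sim$truth[sim$truth$chrom == ch, ]
    t <- t[order(t$start), ]
    expect_equal(t$start[1], 0)
    expect_equal(t$end[nrow(t)], 25000)
    expect_true(all(t$start[-1] == t$end[-nrow(t)]))
  }
  expect_equal(nrow(sim$truth), 6)

  cfg <- sim_config(seed = 19, chrom_length = 25000)
  pops <- simulate_populations(cfg)
  overlap <- data.frame(chrom = "chr01", start = c(0, 10000), end = c(15000, 25000),
                        label = c("Tibet", "Ireland"))
  expect_error(simulate_hybrid(pops, overlap, cfg), "tile")
  unknown <- data.frame(chrom = "chr01", start = 0, end = 25000, label = "Mars")
  expect_error(simulate_hybrid(pops, unknown, cfg), "unknown population")
})

test_that("a fully-missing query paints as 100% unassigned", {
  cfg <- sim_config(seed = 23, chrom_length = 30000)
  sim <- simulate_dataset(cfg)
  vt <- sim$table
  qi <- match("hybrid", vt$roster)
  vt$a1[, qi] <- NA_integer_; vt$a2[, qi] <- NA_integer_
  p <- paint_ancestry(vt, sim$scheme)
  expect_equal(attr(p$summary, "assigned_bp"), 0)
  expect_equal(attr(p$summary, "unassigned_bp"), 30000)
})

test_that("noise-free diagnostic sites inside a tract are all assigned to its source", {
  cfg <- sim_config(seed = 29, chrom_length = 20000,
                    private_allele_fraction = 1, het_rate = 0,
                    tract_spec = data.frame(chrom = "chr01", start = 0,
                                            end = 20000, label = "Ireland"))
  sim <- simulate_dataset(cfg)
  a <- classify_sites(sim$table, sim$scheme)
  expect_true(all(a$label[sim$origin == "Ireland"] == "Ireland"))
  # sites diagnostic for another population are unassigned, never misassigned
  expect_true(all(a$label %in% c("Ireland", "UNASSIGNED")))
})

test_that("site-level accuracy is 1 on noise-free mosaics with fully private alleles", {
  cfg <- sim_config(seed = 37, chrom_length = 100000,
                    private_allele_fraction = 1, het_rate = 0, n_tracts = 5)
  sim <- simulate_dataset(cfg)
  a <- classify_sites(sim$table, sim$scheme)
  truth_at <- character(nrow(a))
  for (i in seq_len(nrow(sim$truth))) {
    sel <- a$chrom == sim$truth$chrom[i] & a$pos > sim$truth$start[i] &
      a$pos <= sim$truth$end[i]
    truth_at[sel] <- sim$truth$label[i]
  }
  diag_of_truth <- sim$origin == truth_at & !is.na(sim$origin)
  expect_true(all(a$label[diag_of_truth] == truth_at[diag_of_truth]))
})

test_that("increasing genotype error raises unassigned + misassigned bp in trend", {
  err_levels <- c(0, 0.05, 0.25)
  bad_bp <- vapply(err_levels, function(e) {
    total <- 0
    for (seed in 1:3) {
      cfg <- sim_config(seed = 300 + seed, chrom_length = 50000,
                        genotype_error_rate = e, n_tracts = 4)
      sim <- simulate_dataset(cfg)
      p <- paint_ancestry(filter_variants(sim$table)$table, sim$scheme)
      blocks <- p$blocks
      for (i in seq_len(nrow(blocks))) {
        tr <- sim$truth[sim$truth$chrom == blocks$chrom[i], ]
        ov <- pmin(blocks$end[i], tr$end) - pmax(blocks$start[i], tr$start)
        ov[ov < 0] <- 0
        total <- total + sum(ov[tr$label != blocks$label[i]])
      }
    }
    total
  }, numeric(1))
  expect_true(all(diff(bad_bp) > 0))
})

test_that("degraded DP/GQ values exercise the quality filters", {
  cfg <- sim_config(seed = 41, chrom_length = 30000, degrade = TRUE)
  sim <- simulate_dataset(cfg)
  masked <- mask_low_quality_genotypes(sim$table)
  expect_gt(attr(masked, "masked_dp"), 0)
  expect_gt(attr(masked, "masked_gq"), 0)
})
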