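test_that("site classification follows the uniquely-shared-allele rule", {
  scheme <- tiny_scheme()
  mk <- function(q, t, i, n) {
    gt <- cbind(q = q, t = t, i = i, n = n)
    toy_table("chrI", 100, "A", "G", gt)
  }
  # query and Tibet rep share ALT; other populations homozygous REF
  a <- classify_sites(mk("1/1", "0/1", "0/0", "0/0"), scheme)
  expect_equal(a$label, "Tibet")
  # ALT also in the Irish rep: not uniquely shared with anyone
  a <- classify_sites(mk("1/1", "1/1", "0/1", "0/0"), scheme)
  expect_equal(a$label, "UNASSIGNED")
  expect_equal(a$reason, "shared_by_none")
  # heterozygous query sharing REF with one population and ALT with another
  two_pop <- population_scheme("q", list(
    Tibet = list(assign = "t", exclude = "t"),
    Ireland = list(assign = "i", exclude = "i")))
  gt <- cbind(q = "0/1", t = "1/1", i = "0/0", n = "0/0")
  a <- classify_sites(toy_table("chrI", 100, "A", "G", gt), two_pop)
  expect_equal(a$reason, "shared_by_multiple")
  # REF allele uniquely shared with Ireland (allele-symmetric rule)
  a <- classify_sites(mk("0/0", "1/1", "0/0", "1/1"), scheme)
  expect_equal(a$label, "Ireland")
  # query missing
  a <- classify_sites(mk(NA, "1/1", "0/0", "0/0"), scheme)
  expect_equal(a$reason, "query_missing")
  # all reps of one population missing
  a <- classify_sites(mk("1/1", NA, "0/0", "0/0"), scheme)
  expect_equal(a$reason, "reps_missing")
  # allele found nowhere
  a <- classify_sites(mk("1/1", "0/0", "0/0", "0/0"), scheme)
  expect_equal(a$reason, "shared_by_none")
  # alt-presence-only mode refuses the REF-shared assignment
  a <- classify_sites(mk("0/0", "1/1", "0/0", "1/1"), scheme,
                      alt_presence_only = TRUE)
  expect_equal(a$reason, "shared_by_none")
  # scheme/roster mismatch
  bad <- population_scheme("q", list(A = list(assign = "zz", exclude = "zz"),
                                     B = list(assign = "t", exclude = "t")))
  expect_error(classify_sites(mk("0/0", "0/0", "0/0", "0/0"), bad), "zz")
})

test_that("classification agrees with a set-wise oracle over all genotype configurations", {
  scheme <- tiny_scheme()
  gts <- c("0/0", "0/1", "1/1", NA)
  grid <- expand.grid(q = gts, t = gts, i = gts, n = gts,
                      stringsAsFactors = FALSE)
  gt <- as.matrix(grid)
  vt <- toy_table("chrI", seq_len(nrow(grid)) * 10, rep("A", nrow(grid)),
                  rep("G", nrow(grid)), gt)
  got <- classify_sites(vt, scheme)
  for (r in seq_len(nrow(grid))) {
    want <- classify_oracle(as.list(grid[r, ]), "q", scheme$populations)
    expect_equal(got$label[r], want$label,
                 info = paste(unlist(grid[r, ]), collapse = " "))
    expect_equal(got$reason[r], want$reason,
                 info = paste(unlist(grid[r, ]), collapse = " "))
  }
})

test_that("classification is invariant to population order", {
  set.seed(5)
  gts <- c("0/0", "0/1", "1/1", NA)
  gt <- cbind(q = sample(gts, 200, TRUE), t = sample(gts, 200, TRUE),
              i = sample(gts, 200, TRUE), n = sample(gts, 200, TRUE))
  vt <- toy_table("chrI", seq_len(200) * 4, rep("A", 200), rep("G", 200), gt)
  fwd <- classify_sites(vt, tiny_scheme())
  rev_scheme <- population_scheme("q", rev(tiny_scheme()$populations))
  bwd <- classify_sites(vt, rev_scheme)
  expect_equal(fwd$label, bwd$label)
  expect_equal(fwd$reason, bwd$reason)
})

assignments_df <- function(pos, label, reason = NA_character_, chrom = "chrI") {
  chrom <- rep_len(chrom, length(pos))
  reason <- rep_len(reason, length(pos))
  structure(data.frame(chrom = chrom, pos = pos, label = label,
                       reason = reason, stringsAsFactors = FALSE),
            class = c("site_assignments", "data.frame"))
}

test_that("block calling respects the two-or-more rule and run breaking", {
  a <- assignments_df(c(100, 200, 500, 600), c("A", "A", "B", "B"))
  raw <- call_blocks(a)
  expect_equal(raw$first, c(100, 500))
  expect_equal(raw$last, c(200, 600))
  expect_equal(raw$label, c("A", "B"))
  expect_equal(raw$support, c(2L, 2L))

  # singleton forms no block
  raw <- call_blocks(assignments_df(c(100, 300, 400), c("A", "B", "B")))
  expect_equal(raw$label, "B")
  expect_equal(raw$first, 300)

  expect_equal(nrow(call_blocks(assignments_df(integer(0), character(0)))), 0)

  # a singleton of a different population breaks the surrounding run
  a <- assignments_df(c(1, 2, 3, 4, 5) * 100, c("A", "A", "B", "A", "A"))
  raw <- call_blocks(a)
  expect_equal(raw$label, c("A", "A"))
  expect_equal(raw$first, c(100, 400))

  # UNASSIGNED sites are transparent by default but break with the flag
  a <- assignments_df(c(1, 2, 3, 4) * 100, c("A", "UNASSIGNED", "A", "A"),
                      c(NA, "shared_by_none", NA, NA))
  expect_equal(nrow(call_blocks(a)), 1)
  expect_equal(call_blocks(a)$support, 3L)
  raw <- call_blocks(a, unassigned_breaks_runs = TRUE)
  expect_equal(raw$first, 300)       # only the trailing pair survives

  expect_error(call_blocks(assignments_df(c(200, 100), c("A", "A"))), "sorted")
})

test_that("long query_missing runs become UNASSIGNED desert blocks that split runs", {
  pos <- seq(100, by = 50, length.out = 24)
  label <- c(rep("A", 6), rep("UNASSIGNED", 12), rep("A", 6))
  reason <- c(rep(NA, 6), rep("query_missing", 12), rep(NA, 6))
  a <- assignments_df(pos, label, reason)
  raw <- call_blocks(a, desert_min_run = 10)
  expect_equal(raw$label, c("A", "UNASSIGNED", "A"))
  expect_equal(raw$first[2], pos[7])
  expect_equal(raw$last[2], pos[18])
  # below the desert threshold the run stays intact
  raw2 <- call_blocks(a, desert_min_run = 13)
  expect_equal(raw2$label, "A")
  expect_equal(raw2$support, 12L)
})

test_that("midpoint expansion matches the worked example and tiles the chromosome", {
  raw <- data.frame(chrom = "chrI", first = c(100, 500), last = c(200, 600),
                    label = c("A", "B"), support = c(2L, 2L))
  exp <- expand_blocks(raw, 1000)
  expect_equal(exp$start, c(0, 350))
  expect_equal(exp$end, c(350, 1000))
  expect_equal(exp$end - exp$start, c(350, 650))

  single <- expand_blocks(raw[1, ], 1000)
  expect_equal(c(single$start, single$end), c(0, 1000))

  none <- expand_blocks(raw[0, ], 1000, chrom = "chrI")
  expect_equal(none$label, "UNASSIGNED")
  expect_equal(none$end, 1000)

  expect_error(expand_blocks(data.frame(chrom = "chrI", first = 1, last = 2000,
                                        label = "A", support = 2L), 1000),
               "outside")
})

test_that("expansion equals the per-base nearest-site brute force on random instances", {
  set.seed(202)
  for (rep in 1:60) {
    len <- sample(200:2000, 1)
    k <- sample(0:8, 1)
    raw <- NULL
    if (k > 0) {
      pts <- sort(sample.int(len, 2 * k))
      raw <- data.frame(chrom = "c", first = pts[seq(1, 2 * k, 2)],
                        last = pts[seq(2, 2 * k, 2)],
                        label = sample(LETTERS[1:3], k, TRUE),
                        support = 2L, stringsAsFactors = FALSE)
    } else {
      raw <- data.frame(chrom = character(), first = integer(), last = integer(),
                        label = character(), support = integer())
    }
    got <- expand_blocks(raw, len, chrom = "c")
    want <- expand_oracle(raw, len, "c")
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$label, want$label)
    # conservation: blocks tile [0, len) exactly
    expect_equal(sum(got$end - got$start), len)
    expect_true(all(got$start[-1] == got$end[-nrow(got)]))
  }
})

test_that("summaries use assigned bp as denominator and enforce tiling", {
  s <- ancestry_summary(c(A = 350, B = 650))
  expect_equal(s$percent_of_assigned, c(35, 65))

  blocks <- data.frame(chrom = c("chrI", "chrI", "chrII"),
                       start = c(0, 400, 0), end = c(400, 1000, 2000),
                       label = c("A", "UNASSIGNED", "B"))
  sm <- summarize_blocks(blocks, toy_index())
  expect_equal(sm$assigned_bp[sm$population == "A"], 400)
  expect_equal(attr(sm, "unassigned_bp"), 600)
  expect_equal(attr(sm, "genome_bp"), 3000)
  expect_equal(sum(sm$percent_of_assigned), 100)

  gap <- blocks[-2, ]
  expect_error(summarize_blocks(gap, toy_index()), "tile")
  expect_error(ancestry_summary(c(A = 10), unassigned_bp = 5, genome_bp = 100),
               "must equal")
})

test_that("strain-percentage averaging matches hand arithmetic", {
  s1 <- ancestry_summary(c(Ireland = 40, Tibet = 50, NC = 10))
  s2 <- ancestry_summary(c(Ireland = 20, Tibet = 70, NC = 10))
  avg <- summarize_across_strains(list(s1, s2))
  expect_equal(avg$mean_percent, c(30, 60, 10))
  expect_equal(summarize_across_strains(list(s1))$mean_percent, s1$percent_of_assigned)
  s3 <- ancestry_summary(c(X = 100, Y = 0))
  expect_error(summarize_across_strains(list(s1, s3)), "labels differ")
})

test_that("raising min_support never increases population-assigned bp", {
  sim <- simulate_dataset(sim_config(seed = 31, chrom_length = 100000,
                                     het_rate = 0.05, genotype_error_rate = 0.02,
                                     missing_rate = 0.05))
  vt <- filter_variants(sim$table)$table
  assigned_bp <- vapply(c(2L, 3L, 5L, 8L), function(ms) {
    p <- paint_ancestry(vt, sim$scheme, min_support = ms)
    attr(p$summary, "assigned_bp")
  }, numeric(1))
  expect_true(all(diff(assigned_bp) <= 0))
})
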