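# Shared fixtures and independent brute-force oracles.

toy_index <- function(lengths = c(chrI = 1000L, chrII = 2000L)) {
  genome_index(names(lengths), lengths)
}

# Build a small variant table directly; gt is a character matrix of
# "a/b" strings ("." for missing), sites x samples.
toy_table <- function(chrom, pos, ref, alt, gt, roster = colnames(gt),
                      index = toy_index(), dp = NULL, gq = NULL) {
  gt <- as.matrix(gt)
  split2 <- function(part) {
    f <- vapply(strsplit(as.vector(gt), "/", fixed = TRUE), `[`, character(1), part)
    suppressWarnings(matrix(as.integer(f), nrow(gt), ncol(gt)))
  }
  variant_table(roster, index,
                data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt),
                split2(1L), split2(2L), dp = dp, gq = gq)
}

write_toy_vcf <- function(path, records, samples = c("s1", "s2", "s3"),
                          contigs = c(chrI = 1000L, chrII = 2000L),
                          format = "GT:DP:GQ") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    vapply(records, function(r) paste(c(r[1:8], format, r[-(1:8)]), collapse = "\t"),
           character(1))
  ), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, ...) {
  c(chrom, pos, ".", ref, alt, "50", "PASS", ".", ...)
}

# Oracle for the SNP-cluster rule: slide a window of `window` bp over every
# start coordinate and mark all SNPs inside any window holding >= size SNPs.
cluster_oracle <- function(pos, size, window) {
  marked <- logical(length(pos))
  if (length(pos) == 0) return(marked)
  for (s in seq(min(pos), max(pos))) {
    inside <- which(pos >= s & pos <= s + window - 1)
    if (length(inside) >= size) marked[inside] <- TRUE
  }
  marked
}

# Per-base oracle for midpoint expansion: each 1-based base goes to the raw
# block whose nearest outermost supporting site is closest; ties go to the
# left (earlier) block. Returns an expanded tiling data frame.
expand_oracle <- function(raw, chrom_length, chrom) {
  if (nrow(raw) == 0) {
    return(data.frame(chrom = chrom, start = 0, end = chrom_length,
                      label = "UNASSIGNED", stringsAsFactors = FALSE))
  }
  lab_per_base <- character(chrom_length)
  for (p in seq_len(chrom_length)) {
    d <- pmin(abs(p - raw$first), abs(p - raw$last))
    d[p >= raw$first & p <= raw$last] <- 0
    lab_per_base[p] <- raw$label[which.min(d)]  # which.min takes the leftmost tie
  }
  r <- rle(lab_per_base)
  end <- cumsum(r$lengths)
  data.frame(chrom = chrom, start = c(0, end[-length(end)]), end = end,
             label = r$values, stringsAsFactors = FALSE)
}

# Literal re-statement of the uniquely-shared-allele rule on one site,
# written set-wise over allele strings rather than matrix-wise.
classify_oracle <- function(genos, query, scheme_pops) {
  alleles_of <- function(g) if (is.na(g)) character(0) else unlist(strsplit(g, "/"))
  q <- alleles_of(genos[[query]])
  if (length(q) == 0) return(list(label = "UNASSIGNED", reason = "query_missing"))
  for (p in names(scheme_pops)) {
    reps <- unique(unlist(scheme_pops[[p]]))
    if (all(vapply(genos[reps], is.na, logical(1)))) {
      return(list(label = "UNASSIGNED", reason = "reps_missing"))
    }
  }
  qualifying <- character(0)
  for (p in names(scheme_pops)) {
    others <- setdiff(names(scheme_pops), p)
    excl <- unique(unlist(lapply(others, function(o) {
      unlist(lapply(scheme_pops[[o]]$exclude, function(s) alleles_of(genos[[s]])))
    })))
    assign_alleles <- unique(unlist(lapply(scheme_pops[[p]]$assign,
                                           function(s) alleles_of(genos[[s]]))))
    if (any(q %in% assign_alleles & !(q %in% excl))) qualifying <- c(qualifying, p)
  }
  if (length(qualifying) == 1) return(list(label = qualifying, reason = NA_character_))
  if (length(qualifying) == 0) return(list(label = "UNASSIGNED", reason = "shared_by_none"))
  list(label = "UNASSIGNED", reason = "shared_by_multiple")
}

# Three-population scheme over single-strain reps q, t, i, n.
tiny_scheme <- function() {
  population_scheme("q", list(
    Tibet   = list(assign = "t", exclude = "t"),
    Ireland = list(assign = "i", exclude = "i"),
    NC      = list(assign = "n", exclude = "n")))
}
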