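#' Configuration for Random Repeated Haplotype Sampling
#'
#' RRHS builds pseudo-haplotype SNP alignments by randomly resolving each
#' heterozygous genotype to one of its two alleles, independently per sample
#' and per site, repeated over many iterations. The alignments feed external
#' phylogenetic tree search; tree inference itself is out of scope here.
#'
#' @param iterations Number of alignments to generate (default 1000).
#' @param seed Base seed; iteration `i` uses the derived stream `seed + i`,
#'   so individual iterations can be regenerated independently.
#' @param missing_char Character emitted for missing genotypes (default "N").
#' @param format Alignment format, `"phylip"` (default) or `"fasta"`.
#' @return An `rrhs_config` list.
#' @export
rrhs_config <- function(iterations = 1000L, seed = 1L, missing_char = "N",
                        format = c("phylip", "fasta")) {
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  structure(list(iterations = iterations, seed = seed,
                 missing_char = as.character(missing_char),
                 format = match.arg(format)),
            class = "rrhs_config")
}

#' Resolve heterozygous genotypes once into pseudo-haplotype rows
#'
#' Homozygous calls emit their allele's base; heterozygous calls emit either
#' allele with probability 1/2, independently per sample and per site (no
#' within-chromosome phasing); missing calls emit `missing_char`. Uses the
#' current RNG state — seed control lives in [generate_alignments()].
#'
#' @param vt A [variant_table()] containing only biallelic SNPs.
#' @param missing_char Character for missing genotypes.
#' @return Named character vector: one sequence per sample in roster order.
#' @export
resolve_haplotypes <- function(vt, missing_char = "N") {
  stopifnot(inherits(vt, "variant_table"))
  if (n_sites(vt) == 0) stop("cannot resolve an empty variant table", call. = FALSE)
  if (!all(is_snp(vt) & is_biallelic(vt))) {
    stop("RRHS requires a table of biallelic SNPs only (run the filter cascade first)",
         call. = FALSE)
  }
  n <- n_sites(vt); s <- n_samples(vt)
  base <- cbind(vt$sites$ref, vt$sites$alt)          # allele index 0 / 1 -> base
  pick_first <- matrix(stats::runif(n * s) < 0.5, n, s)
  allele <- ifelse(pick_first, vt$a1, vt$a2)
  chars <- matrix(missing_char, n, s)
  called <- !is.na(allele)
  chars[called] <- base[cbind(row(allele)[called], allele[called] + 1L)]
  rows <- apply(chars, 2, paste, collapse = "")
  names(rows) <- vt$roster
  rows
}

rrhs_iteration_seed <- function(seed, i) {
  s <- (as.double(seed) + as.double(i)) %% 2147483647
  as.integer(s)
}

#' Generate RRHS alignment files
#'
#' Writes `cfg$iterations` alignment files named `rrhs_NNNN.phy` (or `.fasta`)
#' into `outdir`. Iteration `i` seeds its own RNG substream from
#' `(seed, i)`, so the run is byte-reproducible and any single iteration can
#' be regenerated in isolation via `subset`.
#'
#' @param vt A filtered [variant_table()] of biallelic SNPs (non-empty).
#' @param cfg An [rrhs_config()].
#' @param outdir Output directory (created if needed).
#' @param subset Optional integer vector of iteration indices to (re)generate;
#'   default all of `1:cfg$iterations`.
#' @return Invisibly, the paths of the files written.
#' @export
generate_alignments <- function(vt, cfg = rrhs_config(), outdir, subset = NULL) {
  stopifnot(inherits(vt, "variant_table"), inherits(cfg, "rrhs_config"))
  if (n_sites(vt) == 0) stop("cannot generate alignments from a table of 0 sites", call. = FALSE)
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  if (file.access(outdir, mode = 2) != 0) {
    stop("output directory is not writable: ", outdir, call. = FALSE)
  }
  if (is.null(subset)) subset <- seq_len(cfg$iterations)
  if (any(subset < 1 | subset > cfg$iterations)) {
    stop("subset indices must lie in 1..iterations", call. = FALSE)
  }
  ext <- if (cfg$format == "phylip") "phy" else "fasta"
  width <- max(4L, nchar(as.character(cfg$iterations)))
  paths <- character(length(subset))
  for (j in seq_along(subset)) {
    i <- subset[j]
    set.seed(rrhs_iteration_seed(cfg$seed, i))
    rows <- resolve_haplotypes(vt, cfg$missing_char)
    paths[j] <- file.path(outdir, sprintf("rrhs_%0*d.%s", width, i, ext))
    write_alignment(rows, paths[j], format = cfg$format)
  }
  invisible(paths)
}

#' Pairwise SNP distances between alignment rows
#'
#' Entry (i, j) counts sites where both sequences are non-missing and carry
#' different bases; sites with `N` in either sequence are excluded.
#'
#' @param rows Named character vector of equal-length sequences.
#' @param missing_char Character treated as missing (default "N").
#' @return Symmetric integer matrix with zero diagonal, dimnames from `rows`.
#' @export
pairwise_snp_distance <- function(rows, missing_char = "N") {
  if (length(unique(nchar(rows))) != 1) {
    stop("ragged alignment: rows differ in length", call. = FALSE)
  }
  s <- length(rows)
  m <- do.call(rbind, strsplit(rows, ""))
  d <- matrix(0L, s, s, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(s)) {
    for (j in seq_len(s)[-seq_len(i)]) {
      ok <- m[i, ] != missing_char & m[j, ] != missing_char
      d[i, j] <- d[j, i] <- sum(ok & m[i, ] != m[j, ])
    }
  }
  d
}
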