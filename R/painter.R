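#' Population scheme: the classification contract
#'
#' Names the hybrid query sample and, for each candidate source population,
#' the assignment representative(s) whose alleles can vouch for that
#' population and the exclusion strain(s) in which a diagnostic allele must
#' be absent. Assignment reps may be a subset of the exclusion set; both must
#' be non-empty.
#'
#' @param query Sample name of the hybrid query.
#' @param populations Named list: one entry per population label, each a list
#'   with character vectors `assign` and `exclude`.
#' @return A `population_scheme` object.
#' @examples
#' population_scheme("lager", list(
#'   Tibet   = list(assign = "tibet1",  exclude = c("tibet1", "tibet2")),
#'   Ireland = list(assign = "irish1",  exclude = c("irish1", "irish2"))))
#' @export
population_scheme <- function(query, populations) {
  query <- as.character(query)
  if (length(query) != 1 || !nzchar(query)) stop("exactly one query sample required", call. = FALSE)
  labels <- names(populations)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels)) {
    stop("populations must be a named list with unique labels", call. = FALSE)
  }
  if (length(populations) < 2) stop("at least two candidate populations required", call. = FALSE)
  populations <- lapply(populations, function(p) {
    a <- as.character(p$assign); e <- as.character(p$exclude)
    if (length(a) == 0 || length(e) == 0) {
      stop("each population needs non-empty assign and exclude sets", call. = FALSE)
    }
    list(assign = a, exclude = e)
  })
  all_reps <- unlist(lapply(populations, function(p) c(p$assign, p$exclude)))
  if (query %in% all_reps) stop("query sample may not appear in any representative set", call. = FALSE)
  if ("UNASSIGNED" %in% labels) stop("'UNASSIGNED' is a reserved label", call. = FALSE)
  structure(list(query = query, populations = populations),
            class = "population_scheme")
}

scheme_labels <- function(scheme) names(scheme$populations)

validate_scheme <- function(scheme, roster) {
  stopifnot(inherits(scheme, "population_scheme"))
  need <- unique(c(scheme$query,
                   unlist(lapply(scheme$populations, function(p) c(p$assign, p$exclude)))))
  absent <- setdiff(need, roster)
  if (length(absent)) {
    stop("scheme sample(s) absent from VCF roster: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  invisible(scheme)
}

#' Classify each SNP site by uniquely shared ancestry
#'
#' For each site, let Q be the set of alleles carried by the query. The site
#' is assigned to population P if and only if some allele in Q is carried by
#' at least one of P's assignment representatives and by none of the
#' exclusion representatives of any other population. Exactly one qualifying
#' population gives that label; two or more give `UNASSIGNED`
#' (`shared_by_multiple`); none gives `UNASSIGNED` (`shared_by_none`). A
#' missing query genotype gives `query_missing`; a population whose
#' representatives are all missing at the site gives `reps_missing`. The
#' rule is symmetric in REF and ALT: a uniquely shared REF allele assigns
#' just as an ALT does. `alt_presence_only = TRUE` switches to the literal
#' ALT-presence reading (only ALT alleles can vouch for a population).
#'
#' @param vt A filtered [variant_table()] of biallelic SNPs.
#' @param scheme A [population_scheme()].
#' @param alt_presence_only Restrict sharing evidence to ALT alleles.
#' @return A `site_assignments` data frame: `chrom`, `pos`, `label`
#'   (population label or "UNASSIGNED"), `reason` (`NA` when assigned, else
#'   one of query_missing, reps_missing, shared_by_multiple, shared_by_none).
#' @export
classify_sites <- function(vt, scheme, alt_presence_only = FALSE) {
  stopifnot(inherits(vt, "variant_table"))
  validate_scheme(scheme, vt$roster)
  if (!all(is_snp(vt) & is_biallelic(vt))) {
    stop("classification requires biallelic SNP sites only", call. = FALSE)
  }
  n <- n_sites(vt)
  labels <- scheme_labels(scheme)
  qi <- match(scheme$query, vt$roster)

  carries <- function(samples, allele) {
    ix <- match(samples, vt$roster)
    if (n == 0) return(logical(0))
    a1 <- vt$a1[, ix, drop = FALSE]; a2 <- vt$a2[, ix, drop = FALSE]
    hit <- (a1 == allele) | (a2 == allele)
    hit[is.na(hit)] <- FALSE
    rowSums(hit) > 0
  }
  all_missing <- function(samples) {
    ix <- match(samples, vt$roster)
    rowSums(!is.na(vt$a1[, ix, drop = FALSE])) == 0
  }

  q_ref <- carries(scheme$query, 0L)
  q_alt <- carries(scheme$query, 1L)
  q_missing <- is.na(vt$a1[, qi])

  k <- length(labels)
  assign_ref <- assign_alt <- excl_ref <- excl_alt <- reps_na <-
    matrix(FALSE, n, k, dimnames = list(NULL, labels))
  for (p in labels) {
    pop <- scheme$populations[[p]]
    assign_ref[, p] <- carries(pop$assign, 0L)
    assign_alt[, p] <- carries(pop$assign, 1L)
    excl_ref[, p] <- carries(pop$exclude, 0L)
    excl_alt[, p] <- carries(pop$exclude, 1L)
    reps_na[, p] <- all_missing(unique(c(pop$assign, pop$exclude)))
  }

  qualifies <- matrix(FALSE, n, k, dimnames = list(NULL, labels))
  for (p in labels) {
    others <- setdiff(labels, p)
    other_ref <- rowSums(excl_ref[, others, drop = FALSE]) > 0
    other_alt <- rowSums(excl_alt[, others, drop = FALSE]) > 0
    via_alt <- q_alt & assign_alt[, p] & !other_alt
    via_ref <- if (alt_presence_only) FALSE else q_ref & assign_ref[, p] & !other_ref
    qualifies[, p] <- via_alt | via_ref
  }

  n_qual <- rowSums(qualifies)
  label <- rep("UNASSIGNED", n)
  reason <- rep(NA_character_, n)
  one <- n_qual == 1
  if (any(one)) label[one] <- labels[max.col(qualifies[one, , drop = FALSE], "first")]
  reason[n_qual == 0] <- "shared_by_none"
  reason[n_qual >= 2] <- "shared_by_multiple"
  any_reps_na <- rowSums(reps_na) > 0
  label[any_reps_na] <- "UNASSIGNED"; reason[any_reps_na] <- "reps_missing"
  label[q_missing] <- "UNASSIGNED"; reason[q_missing] <- "query_missing"

  structure(data.frame(chrom = vt$sites$chrom, pos = vt$sites$pos,
                       label = label, reason = reason, stringsAsFactors = FALSE),
            class = c("site_assignments", "data.frame"))
}

#' Call raw ancestry blocks from runs of concordant sites
#'
#' Within each chromosome, maximal runs of consecutive same-label
#' population-assigned sites with at least `min_support` sites become raw
#' blocks spanning first to last supporting site. By default `UNASSIGNED`
#' sites are transparent — they do not break a run — while a site assigned to
#' a *different* population always breaks the run, even a singleton
#' (`unassigned_breaks_runs = TRUE` makes any unassigned site break runs
#' too). A run of at least `desert_min_run` consecutive `query_missing` sites
#' is emitted as an `UNASSIGNED` raw block (a no-call desert): it breaks
#' population runs it interrupts and later caps block expansion at its
#' midpoints.
#'
#' @param assignments A `site_assignments` data frame from [classify_sites()],
#'   sorted by position within each chromosome.
#' @param min_support Minimum run length for a population block (default 2).
#' @param unassigned_breaks_runs Make unassigned sites break runs (default FALSE).
#' @param desert_min_run Minimum consecutive `query_missing` sites that form
#'   an `UNASSIGNED` desert block; `Inf` disables deserts (default 10).
#' @return A `raw_blocks` data frame: `chrom`, `first`, `last` (1-based
#'   outermost supporting sites), `label`, `support`.
#' @export
call_blocks <- function(assignments, min_support = 2L,
                        unassigned_breaks_runs = FALSE, desert_min_run = 10L) {
  stopifnot(is.data.frame(assignments),
            all(c("chrom", "pos", "label") %in% names(assignments)))
  if (min_support < 1) stop("min_support must be >= 1", call. = FALSE)
  out <- list()
  for (ch in unique(assignments$chrom)) {
    a <- assignments[assignments$chrom == ch, , drop = FALSE]
    if (is.unsorted(a$pos, strictly = TRUE)) {
      stop("assignments not sorted by position on ", ch, call. = FALSE)
    }
    out[[ch]] <- call_blocks_chrom(a, ch, min_support, unassigned_breaks_runs,
                                   desert_min_run)
  }
  res <- do.call(rbind, unname(out))
  if (is.null(res)) {
    res <- data.frame(chrom = character(), first = integer(), last = integer(),
                      label = character(), support = integer(),
                      stringsAsFactors = FALSE)
  }
  structure(res, class = c("raw_blocks", "data.frame"))
}

call_blocks_chrom <- function(a, ch, min_support, unassigned_breaks_runs,
                              desert_min_run) {
  n <- nrow(a)
  reason <- if ("reason" %in% names(a)) a$reason else rep(NA_character_, n)

  # no-call deserts: runs of consecutive query_missing sites
  desert_id <- integer(n)  # 0 = not in a desert
  if (is.finite(desert_min_run) && n > 0) {
    qm <- !is.na(reason) & reason == "query_missing"
    r <- rle(qm)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    did <- 0L
    for (j in seq_along(r$lengths)) {
      if (r$values[j] && r$lengths[j] >= desert_min_run) {
        did <- did + 1L
        desert_id[starts[j]:ends[j]] <- did
      }
    }
  }

  assigned <- a$label != "UNASSIGNED"
  blocks <- list()
  # population runs over assigned sites; a desert or (optionally) any
  # unassigned site between consecutive assigned sites breaks the run
  idx <- which(assigned)
  if (length(idx)) {
    breaks_before <- logical(length(idx))  # break between idx[i-1] and idx[i]
    if (length(idx) > 1) {
      for (i in 2:length(idx)) {
        between <- seq(idx[i - 1] + 1L, length.out = idx[i] - idx[i - 1] - 1L)
        brk <- a$label[idx[i]] != a$label[idx[i - 1]]
        if (!brk && length(between)) {
          if (any(desert_id[between] > 0)) brk <- TRUE
          if (unassigned_breaks_runs) brk <- TRUE
        }
        breaks_before[i] <- brk
      }
    }
    run_id <- cumsum(c(1L, as.integer(breaks_before[-1])))
    for (rid in unique(run_id)) {
      members <- idx[run_id == rid]
      if (length(members) >= min_support) {
        blocks[[length(blocks) + 1L]] <- data.frame(
          chrom = ch, first = a$pos[members[1]], last = a$pos[members[length(members)]],
          label = a$label[members[1]], support = length(members),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (any(desert_id > 0)) {
    for (did in setdiff(unique(desert_id), 0L)) {
      members <- which(desert_id == did)
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom = ch, first = a$pos[members[1]], last = a$pos[members[length(members)]],
        label = "UNASSIGNED", support = length(members), stringsAsFactors = FALSE)
    }
  }
  if (!length(blocks)) return(NULL)
  res <- do.call(rbind, blocks)
  res[order(res$first), , drop = FALSE]
}

#' Expand raw blocks to a full chromosome tiling
#'
#' Borders between adjacent raw blocks are drawn at the midpoint between
#' their facing outermost supporting sites: in 1-based coordinates the
#' boundary position is `floor((left_last + right_first) / 2)` and that base
#' goes to the left block. The first block extends to the chromosome start
#' and the last to its end; adjacent expanded blocks with identical labels
#' are merged. A chromosome with no raw blocks becomes one `UNASSIGNED`
#' block. Output coordinates are 0-based half-open and tile
#' `[0, chrom_length)` exactly.
#'
#' @param raw A `raw_blocks` data frame for one chromosome (sorted,
#'   non-overlapping).
#' @param chrom_length Chromosome length in bp.
#' @param chrom Chromosome name (required when `raw` has no rows).
#' @return An `ancestry_blocks` data frame: `chrom`, `start`, `end`, `label`,
#'   `support`.
#' @export
expand_blocks <- function(raw, chrom_length, chrom = NULL) {
  chrom_length <- as.numeric(chrom_length)
  if (nrow(raw) == 0) {
    if (is.null(chrom)) stop("chromosome name required when no raw blocks exist", call. = FALSE)
    return(structure(data.frame(chrom = chrom, start = 0, end = chrom_length,
                                label = "UNASSIGNED", support = 0L,
                                stringsAsFactors = FALSE),
                     class = c("ancestry_blocks", "data.frame")))
  }
  if (length(unique(raw$chrom)) != 1) stop("expand_blocks works on one chromosome", call. = FALSE)
  if (is.unsorted(raw$first, strictly = TRUE)) stop("raw blocks must be sorted", call. = FALSE)
  if (any(raw$last < raw$first)) stop("raw block with last < first", call. = FALSE)
  if (nrow(raw) > 1 && any(raw$first[-1] <= raw$last[-nrow(raw)])) {
    stop("raw blocks overlap", call. = FALSE)
  }
  if (any(raw$first < 1) || any(raw$last > chrom_length)) {
    stop("raw block outside [1, chrom_length]", call. = FALSE)
  }
  k <- nrow(raw)
  # 1-based boundary base belongs to the left block => half-open end = boundary
  bounds <- if (k > 1) floor((raw$last[-k] + raw$first[-1]) / 2) else numeric(0)
  start <- c(0, bounds)
  end <- c(bounds, chrom_length)
  res <- data.frame(chrom = raw$chrom, start = start, end = end,
                    label = raw$label, support = raw$support,
                    stringsAsFactors = FALSE)
  # merge adjacent blocks with identical labels
  grp <- cumsum(c(1L, as.integer(res$label[-1] != res$label[-k])))
  res <- do.call(rbind, lapply(split(res, factor(grp, levels = unique(grp))), function(g) {
    data.frame(chrom = g$chrom[1], start = g$start[1], end = g$end[nrow(g)],
               label = g$label[1], support = sum(g$support), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  structure(res, class = c("ancestry_blocks", "data.frame"))
}

#' Paint a hybrid subgenome end to end
#'
#' Runs [classify_sites()], [call_blocks()] and [expand_blocks()] over every
#' chromosome of the genome index and summarizes the tiling.
#'
#' @param vt A filtered [variant_table()] of biallelic SNPs.
#' @param scheme A [population_scheme()].
#' @param min_support Minimum supporting sites per block (default 2).
#' @param ... Passed on to [classify_sites()] and [call_blocks()]
#'   (`alt_presence_only`, `unassigned_breaks_runs`, `desert_min_run`).
#' @return An `ancestry_painting` list: `sites` (per-site assignments),
#'   `blocks` (expanded tiling for all chromosomes), `summary`
#'   (an `ancestry_summary`).
#' @export
paint_ancestry <- function(vt, scheme, min_support = 2L, ...) {
  dots <- list(...)
  cls_args <- dots[names(dots) %in% "alt_presence_only"]
  blk_args <- dots[names(dots) %in% c("unassigned_breaks_runs", "desert_min_run")]
  sites <- do.call(classify_sites, c(list(vt, scheme), cls_args))
  raw <- do.call(call_blocks, c(list(sites, min_support = min_support), blk_args))
  blocks <- do.call(rbind, lapply(seq_len(nrow(vt$index)), function(i) {
    ch <- vt$index$name[i]
    expand_blocks(raw[raw$chrom == ch, , drop = FALSE], vt$index$length[i], chrom = ch)
  }))
  class(blocks) <- c("ancestry_blocks", "data.frame")
  structure(list(sites = sites, blocks = blocks,
                 summary = summarize_blocks(blocks, vt$index, labels = scheme_labels(scheme))),
            class = "ancestry_painting")
}

#' @export
print.ancestry_painting <- function(x, ...) {
  cat(sprintf("ancestry painting: %d sites, %d blocks\n", nrow(x$sites), nrow(x$blocks)))
  print(x$summary)
  invisible(x)
}

#' Summarize per-population assigned lengths
#'
#' Verifies that the expanded blocks tile every chromosome of the index
#' exactly (no gap, no overlap), then totals block lengths per population.
#' Percentages are of *assigned* bp: `100 * bp / sum(population bp)`,
#' excluding `UNASSIGNED`.
#'
#' @param blocks `ancestry_blocks` for all chromosomes.
#' @param index The [genome_index()].
#' @param labels Optional population label order for the output.
#' @return An `ancestry_summary` data frame (`population`, `assigned_bp`,
#'   `percent_of_assigned`) with attributes `assigned_bp`, `unassigned_bp`
#'   and `genome_bp`.
#' @export
summarize_blocks <- function(blocks, index, labels = NULL) {
  for (i in seq_len(nrow(index))) {
    ch <- index$name[i]
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) == 0 || b$start[1] != 0 || b$end[nrow(b)] != index$length[i] ||
        (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)]))) {
      stop("blocks do not tile chromosome ", ch, call. = FALSE)
    }
  }
  len <- blocks$end - blocks$start
  pop <- blocks$label[blocks$label != "UNASSIGNED"]
  bp <- tapply(len[blocks$label != "UNASSIGNED"], pop, sum)
  if (is.null(labels)) labels <- sort(names(bp))
  bp_vec <- stats::setNames(as.numeric(bp[labels]), labels)
  bp_vec[is.na(bp_vec)] <- 0
  ancestry_summary(bp_vec,
                   unassigned_bp = sum(len[blocks$label == "UNASSIGNED"]),
                   genome_bp = genome_bp(index))
}

#' Build an ancestry summary from per-population bp totals
#'
#' The percentage denominator is the total *assigned* bp (the sum of the
#' per-population totals), not the genome length, so unassignable regions do
#' not dilute the population shares.
#'
#' @param bp Named numeric vector of assigned bp per population.
#' @param unassigned_bp Total unassigned bp (default 0).
#' @param genome_bp Total genome length; defaults to assigned + unassigned.
#' @return An `ancestry_summary` data frame.
#' @export
ancestry_summary <- function(bp, unassigned_bp = 0,
                             genome_bp = sum(bp) + unassigned_bp) {
  if (is.null(names(bp)) || any(!nzchar(names(bp)))) {
    stop("bp totals must be named by population", call. = FALSE)
  }
  if (any(bp < 0) || unassigned_bp < 0) stop("bp totals must be >= 0", call. = FALSE)
  if (abs(sum(bp) + unassigned_bp - genome_bp) > 1e-6) {
    stop("assigned + unassigned bp must equal genome bp", call. = FALSE)
  }
  assigned <- sum(bp)
  pct <- if (assigned > 0) 100 * bp / assigned else rep(NA_real_, length(bp))
  structure(data.frame(population = names(bp), assigned_bp = as.numeric(bp),
                       percent_of_assigned = as.numeric(pct),
                       stringsAsFactors = FALSE, row.names = NULL),
            assigned_bp = assigned, unassigned_bp = unassigned_bp,
            genome_bp = genome_bp,
            class = c("ancestry_summary", "data.frame"))
}

#' @export
print.ancestry_summary <- function(x, ...) {
  cat("ancestry summary\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-16s %12.0f bp  %6.2f%%\n", x$population[i], x$assigned_bp[i],
                x$percent_of_assigned[i]))
  }
  cat(sprintf("  %-16s %12.0f bp\n", "unassigned", attr(x, "unassigned_bp")))
  cat(sprintf("  %-16s %12.0f bp\n", "genome", attr(x, "genome_bp")))
  invisible(x)
}

#' Write an ancestry summary as TSV
#' @param summary An `ancestry_summary`.
#' @param path Output path.
#' @export
write_summary <- function(summary, path) {
  utils::write.table(as.data.frame(summary), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Average percentages across strains
#'
#' Unweighted mean of per-strain population percentages, e.g. to state the
#' genome-wide contribution of each source population across several hybrid
#' strains.
#'
#' @param summaries List of `ancestry_summary` objects with identical
#'   population labels.
#' @return Data frame: `population`, `mean_percent` (2 decimals),
#'   `mean_percent_rounded` (nearest integer).
#' @export
summarize_across_strains <- function(summaries) {
  if (length(summaries) < 1) stop("at least one summary required", call. = FALSE)
  labs <- summaries[[1]]$population
  for (s in summaries) {
    if (!identical(s$population, labs)) {
      stop("population labels differ across summaries", call. = FALSE)
    }
  }
  pct <- rowMeans(vapply(summaries, function(s) s$percent_of_assigned,
                         numeric(length(labs))))
  data.frame(population = labs,
             mean_percent = round(pct, 2),
             mean_percent_rounded = round(pct),
             stringsAsFactors = FALSE)
}
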