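#' Gene-component priority classes
#'
#' The nine ranked region classes plus the unranked remainder. When
#' annotations overlap, a base takes the minimum-rank class: CDS beats 5'UTR
#' beats 3'UTR beats noncoding exon beats intron beats the 1 kb flanks beats
#' the 5 kb flanks; anything untouched is REMAINDER.
#'
#' @return Character vector of class labels in priority order.
#' @export
region_classes <- function() {
  c("CDS", "UTR5", "UTR3", "NONCODING", "INTRON",
    "UP1000", "DOWN1000", "UP5000", "DOWN5000", "REMAINDER")
}

ranked_classes <- function() region_classes()[1:9]

iranges_of <- function(tbl) {
  IRanges::IRanges(start = tbl$start + 1L, end = tbl$end)  # to 1-based closed
}

tibble_of_iranges <- function(ir, chrom) {
  tibble(chrom = chrom, start = BiocGenerics::start(ir) - 1L,
         end = BiocGenerics::end(ir))
}

#' Partition chromosomes into priority region classes
#'
#' Gene bodies contribute their component intervals (CDS, UTR5, UTR3,
#' NONCODING exons, INTRON); each gene additionally contributes four
#' strand-agnostic flanks on genomic coordinates: `[start-1000, start)`,
#' `[end, end+1000)`, `[start-5000, start)` and `[end, end+5000)`, truncated
#' at chromosome edges. Overlaps are resolved per base by priority rank;
#' whatever no annotation reaches is REMAINDER. The result is an exhaustive,
#' exclusive partition: per-class coverages sum to the genome length.
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open gene span), `coding` (logical).
#' @param components Tibble with columns `gene_id`, `chrom`, `class` (one of
#'   CDS/UTR5/UTR3/NONCODING/INTRON), `start`, `end` (0-based half-open).
#'   Overlapping intervals within one class are unioned, never an error.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @return Tibble of disjoint intervals: `chrom`, `start`, `end`, `class`.
#' @export
partition_genome <- function(genes, components, chrom_lengths) {
  flanks <- bind_rows(
    tibble(chrom = genes$chrom, class = "UP1000",
           start = genes$start - 1000, end = genes$start),
    tibble(chrom = genes$chrom, class = "DOWN1000",
           start = genes$end, end = genes$end + 1000),
    tibble(chrom = genes$chrom, class = "UP5000",
           start = genes$start - 5000, end = genes$start),
    tibble(chrom = genes$chrom, class = "DOWN5000",
           start = genes$end, end = genes$end + 5000)
  )
  ann <- bind_rows(
    dplyr::select(components, "chrom", "class", "start", "end"),
    flanks
  )
  out <- lapply(names(chrom_lengths), function(chrom) {
    L <- chrom_lengths[[chrom]]
    ca <- dplyr::filter(ann, .data$chrom == !!chrom,
                        .data$end > 0, .data$start < L)
    ca$start <- pmax(ca$start, 0)
    ca$end <- pmin(ca$end, L)
    taken <- IRanges::IRanges()  # bases already claimed by a higher priority
    pieces <- list()
    for (cls in ranked_classes()) {
      rows <- ca[ca$class == cls & ca$end > ca$start, , drop = FALSE]
      if (nrow(rows) == 0) next
      ir <- IRanges::reduce(iranges_of(rows))
      free <- IRanges::setdiff(ir, taken)
      if (length(free) > 0) {
        pieces[[cls]] <- dplyr::mutate(tibble_of_iranges(free, chrom),
                                       class = cls)
      }
      taken <- IRanges::reduce(IRanges::union(taken, ir))
    }
    rest <- IRanges::setdiff(IRanges::IRanges(1L, as.integer(L)), taken)
    if (length(rest) > 0) {
      pieces[["REMAINDER"]] <- dplyr::mutate(tibble_of_iranges(rest, chrom),
                                             class = "REMAINDER")
    }
    bind_rows(pieces)
  })
  arrange(bind_rows(out), .data$chrom, .data$start)
}

#' Per-class coverage of a partition
#'
#' @param partition Tibble from [partition_genome()].
#' @return Tibble `class`, `coverage` (bp), in priority order, including
#'   zero rows for absent classes.
#' @export
partition_coverage <- function(partition) {
  cov <- partition %>%
    group_by(.data$class) %>%
    summarise(coverage = sum(.data$end - .data$start), .groups = "drop")
  tibble(class = region_classes()) %>%
    left_join(cov, by = "class") %>%
    mutate(coverage = ifelse(is.na(.data$coverage), 0, .data$coverage))
}

#' Classify intervals by repeat overlap
#'
#' An interval is REPEAT iff it overlaps at least one repeat interval by at
#' least one base; half-open coordinates, so a repeat starting exactly at the
#' interval end does not count.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param repeats Tibble of repeat intervals in the same convention (e.g. from
#'   [read_bed()]); may be empty.
#' @return `intervals` with an added `repeat_status` column
#'   (`"REPEAT"`/`"NONREPEAT"`).
#' @export
classify_repeat <- function(intervals, repeats) {
  status <- rep("NONREPEAT", nrow(intervals))
  if (nrow(repeats) > 0) {
    for (chrom in unique(intervals$chrom)) {
      qi <- which(intervals$chrom == chrom)
      rr <- repeats[repeats$chrom == chrom, , drop = FALSE]
      if (nrow(rr) == 0) next
      hits <- IRanges::overlapsAny(iranges_of(intervals[qi, , drop = FALSE]),
                                   iranges_of(rr))
      status[qi[hits]] <- "REPEAT"
    }
  }
  mutate(intervals, repeat_status = status)
}

#' Read a BED file of intervals
#'
#' @param path BED path (first three columns chrom, start, end; 0-based
#'   half-open, as BED is).
#' @return Tibble `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  tibble(chrom = bed[[1]], start = as.numeric(bed[[2]]),
         end = as.numeric(bed[[3]]))
}

#' Read gene models from interval TSVs
#'
#' Two plain TSVs stand in for a GFF3/GTF export: a gene table and a
#' component table (see [partition_genome()] for the required columns).
#'
#' @param genes_path,components_path TSV paths with headers.
#' @return List with tibbles `genes` and `components`.
#' @export
read_gene_models <- function(genes_path, components_path) {
  genes <- readr::read_tsv(genes_path, col_types = readr::cols(
    gene_id = "c", chrom = "c", start = "d", end = "d",
    strand = "c", coding = "l"
  ), progress = FALSE)
  components <- readr::read_tsv(components_path, col_types = readr::cols(
    gene_id = "c", chrom = "c", class = "c", start = "d", end = "d"
  ), progress = FALSE)
  list(genes = as_tibble(genes), components = as_tibble(components))
}

#' Per-gene ratio-of-averages F_ST with extended regions
#'
#' For each gene, aggregates Hudson components over variants inside the gene
#' body `[start, end)` and over the extended region `[start-5000, end+5000)`.
#' Genes without usable variants are reported with `defined = FALSE`.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `coding`).
#' @param x A [genotype_matrix()].
#' @param panel Panel tibble.
#' @param popA,popB Population labels.
#' @param extend Extension in bp on each side for the extended estimate
#'   (default 5000).
#' @param corrected Bias-correct the components (default `TRUE`).
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`, `coding`,
#'   `n_variants`, `fst`, `defined`, `n_variants_ext`, `fst_ext`,
#'   `defined_ext`.
#' @export
gene_fst_table <- function(genes, x, panel, popA, popB, extend = 5000,
                           corrected = TRUE) {
  fm <- allele_freq_matrix(x, panel)
  comp <- pair_components(fm, popA, popB, corrected)
  pos0 <- x$variants$pos - 1
  per_gene <- function(i, lo, hi) {
    sel <- x$variants$chrom == genes$chrom[i] & pos0 >= lo & pos0 < hi
    fst_region(comp[sel, , drop = FALSE])
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    body <- per_gene(i, genes$start[i], genes$end[i])
    ext <- per_gene(i, genes$start[i] - extend, genes$end[i] + extend)
    tibble(
      gene_id = genes$gene_id[i], chrom = genes$chrom[i],
      start = genes$start[i], end = genes$end[i],
      coding = genes$coding[i],
      n_variants = body$n_variants, fst = body$fst, defined = body$defined,
      n_variants_ext = ext$n_variants, fst_ext = ext$fst,
      defined_ext = ext$defined
    )
  })
  bind_rows(rows)
}

#' Select extreme-F_ST region sets
#'
#' Regions are sorted by estimate descending (ties broken by chromosome then
#' start, so all-equal inputs select deterministically); the top and bottom
#' sets are the highest/lowest 1% (`ceiling(k * n)` regions) in `fraction`
#' mode, or exactly `k` regions in `count` mode. Only defined estimates may
#' be supplied.
#'
#' @param estimates Tibble with columns `fst`, `chrom`, `start` (a
#'   [gene_fst_table()] or [windowed_fst()] output restricted to
#'   `defined` rows).
#' @param mode `"fraction"` (default) or `"count"`.
#' @param k Fraction (default 0.01) or count, per `mode`.
#' @return List of tibbles `top` and `bottom` (row order: descending /
#'   ascending estimate respectively).
#' @export
select_extremes <- function(estimates, mode = c("fraction", "count"),
                            k = 0.01) {
  mode <- match.arg(mode)
  if (any(is.na(estimates$fst))) abort("estimates must be defined (no NA fst)")
  n <- nrow(estimates)
  n_take <- if (mode == "fraction") ceiling(k * n) else as.integer(k)
  if (n_take > n) {
    warn(sprintf("requested %d regions from %d; taking all", n_take, n))
    n_take <- n
  }
  ord <- order(-estimates$fst, estimates$chrom, estimates$start)
  sorted <- estimates[ord, , drop = FALSE]
  top <- sorted[seq_len(n_take), , drop = FALSE]
  bottom <- sorted[seq(n, by = -1L, length.out = n_take), , drop = FALSE]
  n_overlap <- length(intersect(
    paste(top$chrom, top$start), paste(bottom$chrom, bottom$start)))
  if (n_overlap > 0) {
    warn(sprintf("top and bottom sets overlap in %d region(s)", n_overlap))
  }
  list(top = as_tibble(top), bottom = as_tibble(bottom))
}

#' Length-matched random control regions
#'
#' For each target region, places one region of identical length uniformly at
#' random on the same chromosome, rejecting placements that overlap any
#' exclusion interval (by default the targets themselves) and resampling up
#' to `max_tries` times. Reproducible given the seed.
#'
#' @param targets Tibble `chrom`, `start`, `end` (0-based half-open).
#' @param chrom_lengths Named numeric vector.
#' @param exclusions Tibble of intervals the matches must not overlap
#'   (default: `targets`).
#' @param seed Integer seed (mandatory).
#' @param max_tries Rejection-sampling cap per region (default 1000).
#' @return Tibble `chrom`, `start`, `end` with `end - start` exactly matching
#'   the targets, row for row.
#' @export
length_matched_sample <- function(targets, chrom_lengths, exclusions = targets,
                                  seed, max_tries = 1000) {
  if (missing(seed)) abort("seed is required")
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  place <- function() {
    rows <- lapply(seq_len(nrow(targets)), function(i) {
      chrom <- targets$chrom[i]
      len <- targets$end[i] - targets$start[i]
      L <- chrom_lengths[[chrom]]
      if (is.null(L) || len > L) {
        abort(sprintf("region %s:[%s,%s) cannot be placed on its chromosome",
                      chrom, targets$start[i], targets$end[i]))
      }
      excl <- exclusions[exclusions$chrom == chrom, , drop = FALSE]
      for (t in seq_len(max_tries)) {
        s <- floor(runif(1, 0, L - len + 1))
        hit <- nrow(excl) > 0 && any(s < excl$end & (s + len) > excl$start)
        if (!hit) return(tibble(chrom = chrom, start = s, end = s + len))
      }
      abort(sprintf("no non-overlapping placement found for %s:[%s,%s) after %d tries",
                    chrom, targets$start[i], targets$end[i], max_tries))
    })
    bind_rows(rows)
  }
  withr_seed(place())
}

#' eQTL enrichment of one region set against another
#'
#' Compares, per eQTL category, the proportion of regions containing at least
#' one significant eQTL (FDR < 0.05) between two region sets using a 2x2
#' chi-squared test with one degree of freedom and no continuity correction.
#' Degenerate margins (a category all-positive or all-negative across both
#' sets) yield `p = NA`, flagged, not an error.
#'
#' @param flagsA,flagsB Tibbles with a `category` column and a logical
#'   `has_eqtl` column, one row per region per category.
#' @return Tibble per category: `category`, `n_A`, `n_B`, `prop_A`, `prop_B`,
#'   `chisq`, `p`, `defined`.
#' @export
region_eqtl_enrichment <- function(flagsA, flagsB) {
  cats <- sort(unique(c(flagsA$category, flagsB$category)))
  rows <- lapply(cats, function(cat) {
    a <- flagsA$has_eqtl[flagsA$category == cat]
    b <- flagsB$has_eqtl[flagsB$category == cat]
    tab <- rbind(c(sum(a), sum(!a)), c(sum(b), sum(!b)))
    ok <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
    if (ok) {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      stat <- unname(ct$statistic); p <- ct$p.value
    } else {
      stat <- NA_real_; p <- NA_real_
    }
    tibble(category = cat, n_A = length(a), n_B = length(b),
           prop_A = mean(a), prop_B = mean(b),
           chisq = stat, p = p, defined = ok)
  })
  bind_rows(rows)
}
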