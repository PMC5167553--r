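#' Pipeline configuration
#'
#' Bundles the analysis settings with their study defaults: 1,000 and
#' 10,000 bp windows, top/bottom 1% (or top-100) extreme selection, cis
#' p < 0.05 / trans p < 0.01 / FDR < 0.05 / MAF > 0.05 / 1 Mb cis window,
#' and delta-DAF group sizes of 20,000 (coding) and 10,000 (noncoding)
#' variants.
#'
#' @param window_sizes Window sizes in bp.
#' @param extreme_mode `"fraction"` or `"count"`.
#' @param extreme_k Fraction or count for [select_extremes()].
#' @param cis_p,trans_p,fdr,maf,cis_distance eQTL thresholds.
#' @param group_size_coding,group_size_noncoding Delta-DAF group sizes.
#' @param seed Integer seed used by any randomised stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window_sizes = c(1000, 10000),
                            extreme_mode = "fraction", extreme_k = 0.01,
                            cis_p = 0.05, trans_p = 0.01, fdr = 0.05,
                            maf = 0.05, cis_distance = 1e6,
                            group_size_coding = 20000,
                            group_size_noncoding = 10000,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

load_dataset <- function(data_dir) {
  p <- function(f) file.path(data_dir, f)
  gm <- read_vcf(p("genotypes.vcf"))
  anc <- readr::read_tsv(p("ancestral.tsv"), col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", alt = "c", ancestral = "c"),
    progress = FALSE)
  gm <- set_ancestral(gm, tibble(
    key = paste(anc$chrom, anc$pos, anc$ref, anc$alt, sep = ":"),
    ancestral = anc$ancestral))
  models <- read_gene_models(p("genes.tsv"), p("components.tsv"))
  expr_tbl <- readr::read_tsv(p("expression.tsv"), progress = FALSE,
                              col_types = readr::cols(feature_id = "c",
                                                      .default = "d"))
  expr <- as.matrix(expr_tbl[, -1])
  rownames(expr) <- expr_tbl$feature_id
  list(
    genotypes = gm,
    panel = read_panel(p("panel.tsv")),
    genes = models$genes, components = models$components,
    repeats = read_bed(p("repeats.bed")),
    expression = expr,
    anchors = readr::read_tsv(p("anchors.tsv"), col_types = readr::cols(
      feature_id = "c", chrom = "c", pos = "d"), progress = FALSE)
  )
}

write_provenance <- function(out_dir, stage, config, extra = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    c(list(stage = stage, config = unclass(config),
           package_version = as.character(utils::packageVersion("popdiffr"))),
      extra),
    file.path(out_dir, paste0(stage, "_provenance.json")),
    auto_unbox = TRUE, digits = NA)
}

#' Windowed F_ST scan over all population pairs
#'
#' Runs [windowed_fst()] for every population pair and window size and
#' writes one TSV per pair and size, plus a JSON summary of the
#' distributions (defined/undefined counts, means).
#'
#' @param data_dir Dataset directory (layout of [write_dataset()]).
#' @param out_dir Output directory.
#' @param chrom_lengths Named chromosome lengths.
#' @param config A [pipeline_config()].
#' @param corrected Bias-correct (default `TRUE`, for sampled data).
#' @return Invisibly, a tibble of all windows with `pop_pair` and `window_size`
#'   columns.
#' @export
run_windowed_scan <- function(data_dir, out_dir, chrom_lengths,
                              config = pipeline_config(), corrected = TRUE) {
  write_provenance(out_dir, "windowed_scan", config)
  d <- load_dataset(data_dir)
  pops <- sort(unique(d$panel$population))
  pairs <- utils::combn(pops, 2, simplify = FALSE)
  out <- list()
  for (w in config$window_sizes) {
    for (pr in pairs) {
      wins <- windowed_fst(d$genotypes, d$panel, pr[1], pr[2], w,
                           chrom_lengths, corrected = corrected)
      tag <- sprintf("%s_vs_%s_w%d", pr[1], pr[2], as.integer(w))
      readr::write_tsv(wins, file.path(out_dir, paste0("windows_", tag, ".tsv")),
                       progress = FALSE)
      out[[tag]] <- mutate(wins, pop_pair = paste(pr, collapse = "_vs_"),
                           window_size = w)
    }
  }
  all_wins <- bind_rows(out)
  summary <- all_wins %>%
    group_by(.data$pop_pair, .data$window_size) %>%
    summarise(n_defined = sum(.data$defined),
              n_undefined = sum(!.data$defined),
              mean_fst = mean(.data$fst[.data$defined]), .groups = "drop")
  jsonlite::write_json(summary, file.path(out_dir, "windowed_summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(all_wins)
}

#' Region-class F_ST summary table
#'
#' Partitions the genome into the nine priority classes plus remainder,
#' assigns every variant to its class, and reports per class: coverage (bp),
#' variant count, and the ratio-of-averages F_ST per population pair — the
#' genome-wide summary-table analogue — together with pooled rows:
#' genome-wide, gene region (classes CDS..INTRON), non-genic region (flanks
#' + remainder), repeat and non-repeat.
#'
#' @inheritParams run_windowed_scan
#' @return Invisibly, the summary tibble (also written as TSV).
#' @export
run_region_summary <- function(data_dir, out_dir, chrom_lengths,
                               config = pipeline_config()) {
  write_provenance(out_dir, "region_summary", config)
  d <- load_dataset(data_dir)
  part <- partition_genome(d$genes, d$components, chrom_lengths)
  pops <- sort(unique(d$panel$population))
  pairs <- utils::combn(pops, 2, simplify = FALSE)
  fm <- allele_freq_matrix(d$genotypes, d$panel)

  # class of each variant (position is 1-based; partition is 0-based)
  vclass <- rep("REMAINDER", nrow(d$genotypes$haplotypes))
  pos0 <- d$genotypes$variants$pos - 1
  for (chrom in unique(part$chrom)) {
    pc <- part[part$chrom == chrom, , drop = FALSE]
    vi <- which(d$genotypes$variants$chrom == chrom)
    if (length(vi) == 0) next
    hit <- findInterval(pos0[vi], pc$start)
    ok <- hit >= 1 & pos0[vi] < pc$end[pmax(hit, 1)]
    vclass[vi[ok]] <- pc$class[hit[ok]]
  }
  rep_status <- classify_repeat(
    tibble(chrom = d$genotypes$variants$chrom, start = pos0, end = pos0 + 1),
    d$repeats)$repeat_status

  cov <- partition_coverage(part)
  sets <- c(
    list(`genome-wide` = rep(TRUE, length(vclass)),
         repeat_ = rep_status == "REPEAT",
         `non-repeat` = rep_status == "NONREPEAT"),
    setNames(lapply(region_classes(), function(cl) vclass == cl),
             region_classes()),
    list(`gene region` = vclass %in% region_classes()[1:5],
         `non-genic region` = !(vclass %in% region_classes()[1:5]))
  )
  names(sets)[names(sets) == "repeat_"] <- "repeat"
  coverage_of <- function(nm) {
    if (nm %in% region_classes()) cov$coverage[cov$class == nm]
    else if (nm == "gene region") sum(cov$coverage[cov$class %in% region_classes()[1:5]])
    else if (nm == "non-genic region") sum(cov$coverage[!cov$class %in% region_classes()[1:5]])
    else NA_real_
  }
  rows <- lapply(names(sets), function(nm) {
    sel <- sets[[nm]]
    row <- tibble(index = nm, coverage = coverage_of(nm),
                  n_variants = sum(sel))
    for (pr in pairs) {
      comp <- pair_components(fm, pr[1], pr[2], corrected = TRUE)
      est <- fst_region(comp[sel, , drop = FALSE])
      row[[paste0("fst_", pr[1], "_vs_", pr[2])]] <- est$fst
    }
    row
  })
  summary <- bind_rows(rows)
  readr::write_tsv(summary, file.path(out_dir, "region_summary.tsv"),
                   progress = FALSE)
  invisible(summary)
}

#' Extreme-F_ST eQTL enrichment analysis
#'
#' Per-gene F_ST table, extreme-set selection, combined-population eQTL scan,
#' then the proportion of regions holding at least one FDR < 0.05 eQTL:
#' top set versus bottom set and top set versus a length-matched random set,
#' with chi-squared tests per cis/trans category.
#'
#' @inheritParams run_windowed_scan
#' @return Invisibly, a list with `gene_fst`, `scan` (the `eqtl_scan`),
#'   `vs_bottom` and `vs_matched` enrichment tibbles.
#' @export
run_eqtl_enrichment <- function(data_dir, out_dir, chrom_lengths,
                                config = pipeline_config()) {
  write_provenance(out_dir, "eqtl_enrichment", config)
  d <- load_dataset(data_dir)
  gf <- gene_fst_table(d$genes, d$genotypes, d$panel,
                       sort(unique(d$panel$population))[1],
                       sort(unique(d$panel$population))[2])
  defined <- dplyr::filter(gf, .data$defined)
  if (nrow(defined) == 0) abort("no gene has a defined F_ST estimate")
  ext <- select_extremes(defined, mode = config$extreme_mode,
                         k = config$extreme_k)
  if (nrow(ext$top) == 0) abort("empty top set")

  filtered <- filter_maf(d$genotypes, threshold = config$maf,
                         samples = colnames(d$expression))
  scan <- eqtl_scan(filtered, d$expression, d$anchors, d$panel,
                    cis_p = config$cis_p, trans_p = config$trans_p,
                    fdr = config$fdr, cis_distance = config$cis_distance)
  sig <- dplyr::filter(scan$records, .data$significant)

  region_flags <- function(regions) {
    rows <- lapply(c("cis", "trans"), function(kind) {
      kk <- sig[sig$kind == kind, , drop = FALSE]
      has <- vapply(seq_len(nrow(regions)), function(i) {
        any(kk$chrom == regions$chrom[i] &
              kk$pos - 1 >= regions$start[i] & kk$pos - 1 < regions$end[i])
      }, logical(1))
      tibble(category = kind, has_eqtl = has)
    })
    bind_rows(rows)
  }
  matched <- length_matched_sample(ext$top, chrom_lengths,
                                   exclusions = ext$top, seed = config$seed)
  vs_bottom <- region_eqtl_enrichment(region_flags(ext$top),
                                      region_flags(ext$bottom))
  vs_matched <- region_eqtl_enrichment(region_flags(ext$top),
                                       region_flags(matched))
  jsonlite::write_json(
    list(vs_bottom = vs_bottom, vs_matched = vs_matched),
    file.path(out_dir, "enrichment.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(list(gene_fst = gf, scan = scan, vs_bottom = vs_bottom,
                 vs_matched = vs_matched))
}

#' Delta-DAF group analysis
#'
#' Polarises variants, applies the MAF filter, runs the combined-population
#' eQTL scan, groups analyzed variants by decreasing delta-DAF separately for
#' coding-gene and noncoding-gene membership, and writes per-group eQTL
#' proportions, mean DAFs and DAF histograms.
#'
#' @inheritParams run_windowed_scan
#' @param pop_pair Character vector of the two populations whose DAF
#'   difference ranks the variants (default: first two alphabetically).
#' @return Invisibly, a list with `grouped` and `summaries` tibbles per
#'   membership (`coding`, `noncoding`) and the `histograms`.
#' @export
run_ddaf_analysis <- function(data_dir, out_dir, chrom_lengths,
                              config = pipeline_config(), pop_pair = NULL) {
  write_provenance(out_dir, "ddaf_analysis", config)
  d <- load_dataset(data_dir)
  pops <- sort(unique(d$panel$population))
  if (is.null(pop_pair)) pop_pair <- pops[1:2]

  filtered <- filter_maf(d$genotypes, threshold = config$maf,
                         samples = colnames(d$expression))
  daf <- polarize(filtered, d$panel)
  daf <- dplyr::filter(daf, !.data$excluded)
  scan <- eqtl_scan(filtered, d$expression, d$anchors, d$panel,
                    cis_p = config$cis_p, trans_p = config$trans_p,
                    fdr = config$fdr, cis_distance = config$cis_distance)
  sig <- dplyr::filter(scan$records, .data$significant)
  daf$cis_eqtl <- daf$key %in% sig$variant[sig$kind == "cis"]
  daf$trans_eqtl <- daf$key %in% sig$variant[sig$kind == "trans"]
  daf$delta_daf <- delta_daf(daf[[paste0("daf_", pop_pair[1])]],
                             daf[[paste0("daf_", pop_pair[2])]])

  gene_member <- function(coding_flag) {
    g <- d$genes[d$genes$coding == coding_flag, , drop = FALSE]
    sel <- rep(FALSE, nrow(daf))
    for (i in seq_len(nrow(g))) {
      sel <- sel | (daf$chrom == g$chrom[i] & daf$pos - 1 >= g$start[i] &
                      daf$pos - 1 < g$end[i])
    }
    sel
  }
  out <- list()
  for (mem in c("coding", "noncoding")) {
    sel <- gene_member(mem == "coding")
    recs <- daf[sel, , drop = FALSE]
    gsize <- if (mem == "coding") config$group_size_coding else
      config$group_size_noncoding
    if (nrow(recs) == 0) next
    grouped <- group_by_delta_daf(recs, min(gsize, max(1, nrow(recs))))
    summaries <- group_summaries(grouped)
    readr::write_tsv(summaries,
                     file.path(out_dir, paste0("ddaf_groups_", mem, ".tsv")),
                     progress = FALSE)
    hist_tbl <- bind_rows(lapply(pops, function(p) {
      mutate(daf_histogram(recs[[paste0("daf_", p)]]), population = p)
    }))
    readr::write_tsv(hist_tbl,
                     file.path(out_dir, paste0("daf_hist_", mem, ".tsv")),
                     progress = FALSE)
    out[[mem]] <- list(grouped = grouped, summaries = summaries,
                       histograms = hist_tbl)
  }
  invisible(out)
}

#' Neutral-reference simulation study
#'
#' Runs the forward Wright-Fisher presets and summarises the windowed
#' uncorrected F_ST distributions for each window size (pooled means and
#' fixed-width histograms), written as JSON.
#'
#' @param out_dir Output directory.
#' @param N,L,replicates Simulation preset (defaults: the base preset of 200
#'   individuals on 2 Mb).
#' @param window_sizes Window sizes in bp.
#' @param seed Integer seed.
#' @return Invisibly, a list per window size with `mean_fst`, `n_defined`
#'   and `histogram`.
#' @export
run_simulation_study <- function(out_dir, N = 200, L = 2e6, replicates = 10,
                                 window_sizes = c(1000, 10000), seed = 1L) {
  cfg <- pipeline_config(window_sizes = window_sizes, seed = seed)
  write_provenance(out_dir, "simulation_study", cfg,
                   extra = list(N = N, L = L, replicates = replicates))
  sim <- wf_simulate(N = N, L = L, replicates = replicates, seed = seed)
  out <- lapply(window_sizes, function(w) {
    s <- summarize_windows(sim, w)
    list(window = w, mean_fst = s$mean_fst, n_defined = s$n_defined,
         n_undefined = s$n_undefined, histogram = s$histogram)
  })
  names(out) <- paste0("w", window_sizes)
  jsonlite::write_json(out, file.path(out_dir, "simulation_summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(out)
}
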