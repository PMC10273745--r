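# End-to-end pairwise analysis: harmonize -> exclude -> pool -> resolve ->
# threshold -> cross-test -> per-hit colocalization, plus report rendering.

#' Configuration for a pairwise analysis
#'
#' Validates paths and analysis parameters for [run_pair_analysis()].
#'
#' @param sumstats_a,sumstats_b Summary-statistics file paths.
#' @param leads_a,leads_b Lead-list file paths.
#' @param proxies Optional proxy-table path.
#' @param blocks LD-block BED path.
#' @param trait_a,trait_b Trait labels.
#' @param meta_a,meta_b Optional [study_meta()] objects (labels default from
#'   `trait_a`/`trait_b`).
#' @param sensitivity Optional path to a third trait's summary statistics,
#'   joined to the report at nominal significance (see [sensitivity_join()]).
#' @param alpha Family-wise error rate, default 0.05.
#' @param r2_min Strict r² threshold for proxy rescue, default 0.8.
#' @param exclude Exclusion region ([mhc_region()] by default; `NULL`
#'   disables).
#' @param priors [coloc_priors()] for colocalization.
#' @param prior_sd Length-2 effect-scale priors for the two traits.
#' @param column_map_a,column_map_b Optional column maps for the readers.
#' @param out_dir Optional directory; when given, the report and run log are
#'   written there.
#' @return A `pair_analysis_config` list.
#' @export
pair_analysis_config <- function(sumstats_a, sumstats_b, leads_a, leads_b,
                                 blocks, proxies = NULL,
                                 trait_a = "trait_a", trait_b = "trait_b",
                                 meta_a = NULL, meta_b = NULL,
                                 sensitivity = NULL, alpha = 0.05,
                                 r2_min = 0.8, exclude = mhc_region(),
                                 priors = coloc_priors(),
                                 prior_sd = c(0.2, 0.2),
                                 column_map_a = NULL, column_map_b = NULL,
                                 out_dir = NULL) {
  paths <- c(sumstats_a, sumstats_b, leads_a, leads_b, blocks, proxies,
             sensitivity)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("input file(s) not found: ", paste(missing, collapse = ", ")),
          class = "pleioscan_config_error")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)", class = "pleioscan_config_error")
  }
  structure(list(
    sumstats_a = sumstats_a, sumstats_b = sumstats_b,
    leads_a = leads_a, leads_b = leads_b, blocks = blocks, proxies = proxies,
    trait_a = trait_a, trait_b = trait_b,
    meta_a = if (is.null(meta_a)) study_meta(trait_a) else meta_a,
    meta_b = if (is.null(meta_b)) study_meta(trait_b) else meta_b,
    sensitivity = sensitivity, alpha = alpha, r2_min = r2_min,
    exclude = exclude, priors = priors, prior_sd = rep_len(prior_sd, 2),
    column_map_a = column_map_a, column_map_b = column_map_b,
    out_dir = out_dir), class = "pair_analysis_config")
}

#' Run the full pairwise cross-trait analysis
#'
#' Reads all inputs, harmonizes the pair, applies the exclusion region to both
#' lead sets, pools them, resolves testability (with LD proxy rescue against
#' the harmonized variant set), applies the Bonferroni threshold, cross-tests
#' every testable variant, and colocalizes each significant hit over its
#' approximately independent LD block. With `out_dir` set, writes
#' `report.tsv` and `run_log.tsv`.
#'
#' @param config A [pair_analysis_config()].
#' @return List with `report` (one row per significant cross-test, including
#'   `pp_shared`/`pp_distinct`), `tests` (all cross-tests), and `log`
#'   (`m`, `threshold`, lead censuses, drop/proxy tallies).
#' @export
run_pair_analysis <- function(config) {
  a <- read_sumstats(config$sumstats_a, config$column_map_a, config$meta_a)
  b <- read_sumstats(config$sumstats_b, config$column_map_b, config$meta_b)
  leads_a <- read_lead_variants(config$leads_a, config$trait_a)
  leads_b <- read_lead_variants(config$leads_b, config$trait_b)
  proxies <- if (!is.null(config$proxies)) read_proxy_table(config$proxies)
  blocks <- read_ld_blocks(config$blocks)
  sens <- if (!is.null(config$sensitivity)) {
    read_sumstats(config$sensitivity,
                  meta = study_meta("sensitivity"))
  }
  analyze_pair(a, b, leads_a, leads_b, blocks, proxies = proxies,
               sensitivity = sens, alpha = config$alpha,
               r2_min = config$r2_min, exclude = config$exclude,
               priors = config$priors, prior_sd = config$prior_sd,
               out_dir = config$out_dir)
}

#' Pairwise cross-trait analysis on in-memory tables
#'
#' The computational core of [run_pair_analysis()]; useful when the inputs
#' already live in memory (e.g. straight from [simulate_study()]).
#'
#' @param a,b Validated summary-statistics tibbles.
#' @param leads_a,leads_b `lead_set`s for the two traits.
#' @param blocks An `ld_blocks` set.
#' @param proxies Optional `ld_proxies` table.
#' @param sensitivity Optional third-trait summary-statistics tibble.
#' @inheritParams pair_analysis_config
#' @return As [run_pair_analysis()].
#' @export
analyze_pair <- function(a, b, leads_a, leads_b, blocks, proxies = NULL,
                         sensitivity = NULL, alpha = 0.05, r2_min = 0.8,
                         exclude = mhc_region(), priors = coloc_priors(),
                         prior_sd = c(0.2, 0.2), out_dir = NULL) {
  trait_a <- if (nrow(leads_a) > 0) leads_a$trait[1] else attr(leads_a, "trait")
  trait_b <- if (nrow(leads_b) > 0) leads_b$trait[1] else attr(leads_b, "trait")
  pair <- harmonize_pair(a, b)
  la <- exclude_region(leads_a, exclude)
  lb <- exclude_region(leads_b, exclude)
  pooled <- pool_leads(la, lb)
  testable <- resolve_testable(pooled, available = pair$id, proxies = proxies,
                               r2_min = r2_min)
  m <- attr(testable, "m")
  if (m == 0 && nrow(pooled) > 0) {
    abort("no pooled lead variant is testable in the other trait's data",
          class = "pleioscan_domain_error")
  }
  if (nrow(pooled) == 0) {
    # nothing genome-wide significant anywhere: an empty, successful run
    threshold <- NA_real_
    tests <- hits <- .empty_tests()
  } else {
    threshold <- bonferroni_threshold(m, alpha)
    tests <- cross_test(testable, pair, threshold)
    hits <- tests[tests$significant, , drop = FALSE]
  }

  report <- .colocalize_hits(hits, testable, pair, blocks, priors, prior_sd)
  if (!is.null(sensitivity)) {
    report <- sensitivity_join(report, sensitivity, pair)
  }
  log <- list(
    trait_a = trait_a, trait_b = trait_b,
    n_leads_a = nrow(leads_a), n_leads_b = nrow(leads_b),
    n_excluded_a = nrow(attr(la, "excluded")),
    n_excluded_b = nrow(attr(lb, "excluded")),
    n_pooled = nrow(pooled), m = m, threshold = threshold, alpha = alpha,
    r2_min = r2_min,
    n_proxy = sum(testable$status == "proxy"),
    n_dropped = sum(testable$status == "dropped"),
    n_harmonized = nrow(pair),
    n_harmonization_dropped = nrow(attr(pair, "dropped")),
    priors = unlist(unclass(priors)), prior_sd = prior_sd,
    n_significant = nrow(hits))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(report, file.path(out_dir, "report.tsv"),
                     progress = FALSE)
    log_df <- tibble::tibble(key = names(unlist(log)),
                             value = as.character(unlist(log)))
    readr::write_tsv(log_df, file.path(out_dir, "run_log.tsv"),
                     progress = FALSE)
  }
  list(report = report, tests = tests, log = log)
}

.empty_tests <- function() {
  tibble::tibble(
    variant = character(), tested_id = character(), lead_for = character(),
    source_trait = character(), target_trait = character(),
    beta_source = numeric(), or_source = numeric(), p_source = numeric(),
    beta_target = numeric(), or_target = numeric(), p_target = numeric(),
    threshold = numeric(), significant = logical(), direction = character())
}

# Colocalize each significant hit's LD block; hits in the same block share
# one posterior (leads sharing a block are annotated via the block id).
.colocalize_hits <- function(hits, testable, pair, blocks, priors, prior_sd) {
  if (nrow(hits) == 0) {
    out <- .empty_tests()
    out$block_id <- character()
    out$n_coloc <- integer()
    for (col in c("pp_h0", "pp_h1", "pp_h2", "pp_h3", "pp_h4",
                  "pp_shared", "pp_distinct")) out[[col]] <- numeric()
    return(out)
  }
  idx <- match(hits$tested_id, pair$id)
  hits$block_id <- assign_block(pair$chrom[idx], pair$pos[idx], blocks)
  pair_block <- assign_block(pair$chrom, pair$pos, blocks)
  coloc <- lapply(unique(hits$block_id[!is.na(hits$block_id)]), function(bid) {
    locus <- pair[!is.na(pair_block) & pair_block == bid, , drop = FALSE]
    out <- colocalize_locus(locus, priors = priors, prior_sd = prior_sd)
    out$block_id <- bid
    out
  })
  coloc <- dplyr::bind_rows(coloc)
  out <- dplyr::left_join(hits, coloc, by = "block_id")
  out <- dplyr::rename(out, n_coloc = "n")
  out
}

#' Join a sensitivity trait onto a shared-locus report
#'
#' Appends the sensitivity trait's odds ratio and p-value per report row plus
#' a nominal-significance flag (`p < 0.05`). The sensitivity effects are first
#' harmonized to the report's effect alleles via the same allele
#' reconciliation as [harmonize_pair()] (using `pair`, the harmonized pair the
#' report was built from, as the allele reference). Rows absent from the
#' sensitivity table get `NA` flags, not dropped.
#'
#' @param report Report tibble from [analyze_pair()].
#' @param sensitivity Validated summary-statistics tibble.
#' @param pair The `harmonized_pair` whose effect alleles the report uses.
#' @param nominal_alpha Flag threshold, default 0.05.
#' @return `report` with columns `or_sens`, `p_sens`, `sens_nominal`.
#' @export
sensitivity_join <- function(report, sensitivity, pair,
                             nominal_alpha = 0.05) {
  ref <- pair[, c("id", "chrom", "pos", "a1", "a2")]
  ref$beta <- 0; ref$se <- 1; ref$p <- 1
  ref$maf <- NA_real_; ref$info <- NA_real_; ref$n_eff <- NA_real_
  hp <- harmonize_pair(ref, sensitivity)
  idx <- match(report$tested_id, hp$id)
  report$or_sens <- exp(hp$beta_b[idx])
  report$p_sens <- hp$p_b[idx]
  report$sens_nominal <- ifelse(is.na(report$p_sens), NA,
                                report$p_sens < nominal_alpha)
  report
}

#' Nearest gene to a variant
#'
#' Interval-based lookup only: the gene whose interval is closest to the
#' position (distance 0 when overlapping). Equidistant ties are reported
#' joined by `/`.
#'
#' @param chrom,pos Variant coordinate (1-based).
#' @param genes Data frame with `chrom`, `start`, `end` (1-based, inclusive)
#'   and `gene`.
#' @return Gene label, `"g1/g2"` on ties, or `NA_character_` when the gene
#'   table is empty or the chromosome is absent.
#' @export
nearest_gene <- function(chrom, pos, genes) {
  if (is.null(genes) || nrow(genes) == 0) return(NA_character_)
  genes <- genes[.norm_chrom(genes$chrom) == .norm_chrom(chrom), , drop = FALSE]
  if (nrow(genes) == 0) return(NA_character_)
  gr <- GenomicRanges::GRanges(.norm_chrom(genes$chrom),
                               IRanges::IRanges(genes$start, genes$end))
  q <- GenomicRanges::GRanges(.norm_chrom(chrom), IRanges::IRanges(pos, pos))
  d <- GenomicRanges::distance(rep(q, nrow(genes)), gr)
  d[is.na(d)] <- Inf
  winners <- genes$gene[d == min(d)]
  paste(sort(unique(winners)), collapse = "/")
}
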