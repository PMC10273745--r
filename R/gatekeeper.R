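# Pooled lead-variant cross-trait testing at a 5% family-wise error rate.
#
# The discovery logic: pool the genome-wide significant lead variants of two
# traits, keep those testable in the other trait's statistics (directly or via
# an LD proxy), and look their p-values up in the other trait at a Bonferroni
# threshold of alpha divided by the number of testable variants. Restricting
# the second-stage lookup to first-stage hits (gatekeeper testing) keeps the
# family-wise error rate for joint association below alpha while correcting
# for ~10^2 tests instead of ~10^6.

#' Read a lead-variant list
#'
#' TSV with columns `id`, `chrom`, `pos` and optionally `a1`, `a2`.
#'
#' @param path TSV path.
#' @param trait Trait label attached to every row.
#' @return A `lead_set` tibble with columns `id`, `chrom`, `pos`, `a1`, `a2`,
#'   `trait`.
#' @export
read_lead_variants <- function(path, trait) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  lead_variant_set(df, trait)
}

#' Construct a lead-variant set
#'
#' @param df Data frame with `id`, `chrom`, `pos`, optional `a1`, `a2`.
#' @param trait Trait label.
#' @return A `lead_set` tibble; duplicate ids are an error.
#' @export
lead_variant_set <- function(df, trait) {
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(df))) {
    abort(paste0("lead list needs columns: ", paste(need, collapse = ", ")),
          class = "pleioscan_config_error")
  }
  df <- tibble::as_tibble(df)
  for (col in c("a1", "a2")) if (!col %in% names(df)) df[[col]] <- NA_character_
  df <- df[, c(need, "a1", "a2")]
  df$id <- as.character(df$id)
  df$a1 <- as.character(df$a1)
  df$a2 <- as.character(df$a2)
  df$pos <- as.numeric(df$pos)
  df$chrom <- .norm_chrom(df$chrom)
  if (anyDuplicated(df$id)) {
    abort("duplicate ids in lead-variant set", class = "pleioscan_config_error")
  }
  if (any(is.na(df$pos)) || any(is.na(df$id)) || any(df$id == "")) {
    abort("every lead variant needs an id and coordinates",
          class = "pleioscan_config_error")
  }
  df$trait <- trait
  attr(df, "trait") <- trait
  class(df) <- c("lead_set", class(df))
  df
}

#' Default MHC/HLA exclusion region
#'
#' The extended major histocompatibility complex on chromosome 6, excluded
#' from cross-trait lookups by convention because of its extreme long-range
#' LD. Default interval chr6:25,000,000-35,000,000 (hg38), configurable.
#'
#' @param chrom,start,end Region coordinates (1-based, inclusive).
#' @return A `genomic_region` list.
#' @export
mhc_region <- function(chrom = "chr6", start = 25e6, end = 35e6) {
  structure(list(chrom = .norm_chrom(chrom), start = start, end = end),
            class = "genomic_region")
}

#' Exclude lead variants in a genomic region
#'
#' @param leads A `lead_set`.
#' @param region A region from [mhc_region()], or `NULL` for no exclusion.
#' @return The filtered `lead_set`; removed rows are kept in the `"excluded"`
#'   attribute.
#' @examples
#' leads <- lead_variant_set(tibble::tibble(
#'   id = c("rs_in", "rs_out"), chrom = "chr6", pos = c(30e6, 40e6)), "PD")
#' nrow(exclude_region(leads, mhc_region()))  # 1
#' @export
exclude_region <- function(leads, region = mhc_region()) {
  if (is.null(region)) {
    attr(leads, "excluded") <- leads[0, ]
    return(leads)
  }
  inside <- leads$chrom == region$chrom &
    leads$pos >= region$start & leads$pos <= region$end
  out <- leads[!inside, , drop = FALSE]
  attr(out, "excluded") <- leads[inside, , drop = FALSE]
  attr(out, "trait") <- attr(leads, "trait")
  class(out) <- class(leads)
  out
}

#' Pool the lead variants of two traits
#'
#' Union of the two post-exclusion lead sets, preserving the source trait; a
#' variant that is a lead for both traits appears once with `lead_for =
#' "both"`.
#'
#' @param a,b `lead_set` tibbles.
#' @return A tibble with columns `id`, `chrom`, `pos`, `a1`, `a2`, `lead_for`
#'   (trait label of `a`, of `b`, or `"both"`).
#' @export
pool_leads <- function(a, b) {
  trait_a <- if (nrow(a) > 0) a$trait[1] else attr(a, "trait")
  trait_b <- if (nrow(b) > 0) b$trait[1] else attr(b, "trait")
  both <- intersect(a$id, b$id)
  out <- dplyr::bind_rows(tibble::as_tibble(a), tibble::as_tibble(b))
  out <- out[!duplicated(out$id), , drop = FALSE]
  out$lead_for <- out$trait
  out$lead_for[out$id %in% both] <- "both"
  out$trait <- NULL
  attr(out, "traits") <- c(trait_a, trait_b)
  out
}

#' Resolve which pooled lead variants are testable
#'
#' A pooled variant is testable when it is present in the other trait's data
#' (`available`) or, failing that, when [best_proxy()] finds a substitute with
#' r² above `r2_min`. The count of testable variants `m` (attribute `"m"`)
#' sets the Bonferroni denominator.
#'
#' @param pooled Output of [pool_leads()].
#' @param available Character vector of variant ids present in the other
#'   trait's (harmonized) statistics.
#' @param proxies Optional `ld_proxies` table for proxy rescue.
#' @param r2_min Strict r² threshold for proxies (default 0.8).
#' @return `pooled` plus columns `tested_id` (the id actually looked up, `NA`
#'   when dropped) and `status` (`"present"`, `"proxy"`, `"dropped"`);
#'   attribute `"m"` holds the testable count.
#' @export
resolve_testable <- function(pooled, available, proxies = NULL, r2_min = 0.8) {
  positions <- setNames(pooled$pos, pooled$id)
  status <- character(nrow(pooled))
  tested <- rep(NA_character_, nrow(pooled))
  for (i in seq_len(nrow(pooled))) {
    v <- pooled$id[i]
    if (v %in% available) {
      status[i] <- "present"; tested[i] <- v
    } else if (!is.null(proxies)) {
      pr <- best_proxy(v, proxies, available, r2_min = r2_min,
                       positions = positions)
      if (!is.na(pr)) { status[i] <- "proxy"; tested[i] <- pr }
      else status[i] <- "dropped"
    } else status[i] <- "dropped"
  }
  out <- pooled
  out$tested_id <- tested
  out$status <- status
  attr(out, "m") <- sum(status != "dropped")
  attr(out, "traits") <- attr(pooled, "traits")
  out
}

#' Bonferroni significance threshold
#'
#' `alpha / m` for `m` testable variants; controls the family-wise error rate
#' at `alpha` across the cross-trait lookups.
#'
#' @param m Number of testable variants (>= 1).
#' @param alpha Family-wise error rate, default 0.05.
#' @return The p-value threshold.
#' @examples
#' signif(bonferroni_threshold(162), 2)  # 3.1e-04
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (length(m) != 1 || is.na(m) || m < 1) {
    abort("m must be a single count >= 1", class = "pleioscan_domain_error")
  }
  alpha / m
}

#' Effect-direction concordance between two traits
#'
#' @param beta_a,beta_b Effects on the shared harmonized effect allele
#'   (vectorized).
#' @return Character vector: `"concordant"` when the signs agree and are
#'   nonzero, `"discordant"` for opposite nonzero signs, `"indeterminate"`
#'   when either effect is zero or missing.
#' @examples
#' direction_concordance(c(0.04, 0.05, 0), c(-0.02, 0.07, 0.1))
#' @export
direction_concordance <- function(beta_a, beta_b) {
  s <- sign(beta_a) * sign(beta_b)
  out <- ifelse(is.na(s) | s == 0, "indeterminate",
                ifelse(s > 0, "concordant", "discordant"))
  as.character(out)
}

#' Cross-trait lookup of testable lead variants
#'
#' For every testable variant, looks up the p-value of the variant (or its
#' proxy) in the other trait within the harmonized pair and declares
#' significance when that p-value is strictly below `threshold`. Variants that
#' are leads for both traits are tested in both directions (two rows) but were
#' counted once in `m`.
#'
#' @param testable Output of [resolve_testable()].
#' @param pair A `harmonized_pair` covering every `tested_id`.
#' @param threshold Bonferroni threshold from [bonferroni_threshold()] on the
#'   same `m`.
#' @return A tibble with one row per test: `variant`, `tested_id`, `lead_for`,
#'   `source_trait`, `target_trait`, `beta_source`, `or_source`, `p_source`,
#'   `beta_target`, `or_target`, `p_target`, `threshold`, `significant`,
#'   `direction`.
#' @export
cross_test <- function(testable, pair, threshold) {
  traits <- attr(testable, "traits")
  if (is.null(traits)) traits <- c(attr(pair, "trait_a"), attr(pair, "trait_b"))
  live <- testable[testable$status != "dropped", , drop = FALSE]
  if (nrow(live) == 0) {
    abort("no testable variants: refusing to run the cross-trait lookup",
          class = "pleioscan_domain_error")
  }
  miss <- setdiff(live$tested_id, pair$id)
  if (length(miss) > 0) {
    abort(paste0("tested variant(s) missing from the harmonized pair: ",
                 paste(head(miss, 5), collapse = ", ")),
          class = "pleioscan_internal_error")
  }
  idx <- match(live$tested_id, pair$id)
  rows <- list()
  for (k in seq_len(nrow(live))) {
    i <- idx[k]
    dirs <- switch(live$lead_for[k],
                   both = list(c(1, 2), c(2, 1)),
                   if (live$lead_for[k] == traits[1]) list(c(1, 2))
                   else list(c(2, 1)))
    for (d in dirs) {
      src <- d[1]; tgt <- d[2]
      bs <- if (src == 1) pair$beta_a[i] else pair$beta_b[i]
      bt <- if (tgt == 1) pair$beta_a[i] else pair$beta_b[i]
      ps <- if (src == 1) pair$p_a[i] else pair$p_b[i]
      pt <- if (tgt == 1) pair$p_a[i] else pair$p_b[i]
      rows[[length(rows) + 1]] <- tibble::tibble(
        variant = live$id[k], tested_id = live$tested_id[k],
        lead_for = live$lead_for[k],
        source_trait = traits[src], target_trait = traits[tgt],
        beta_source = bs, or_source = exp(bs), p_source = ps,
        beta_target = bt, or_target = exp(bt), p_target = pt,
        threshold = threshold, significant = pt < threshold,
        direction = direction_concordance(bs, bt))
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate the gatekeeper's family-wise error rate under the global null
#'
#' Draws `m` independent Uniform(0,1) other-trait p-values per replicate,
#' applies [bonferroni_threshold()] and records whether any variant is
#' declared significant. Under the global null the expected fraction is
#' `1 - (1 - alpha/m)^m < alpha`.
#'
#' @param m Number of testable variants per replicate.
#' @param n_reps Number of replicates.
#' @param alpha Family-wise error rate, default 0.05.
#' @return Fraction of replicates with at least one declaration.
#' @examples
#' set.seed(1)
#' simulate_null_fwer(172, n_reps = 200)
#' @export
simulate_null_fwer <- function(m, n_reps, alpha = 0.05) {
  thr <- bonferroni_threshold(m, alpha)
  hits <- vapply(seq_len(n_reps),
                 function(i) any(runif(m) < thr), logical(1))
  mean(hits)
}
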