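# Synthetic paired GWAS summary statistics with locus-level LD structure.
#
# Each locus is simulated directly at the summary-statistic level: given an
# AR(1) LD correlation matrix R and a causal configuration, each trait's
# z-scores are drawn from MVN(R %*% lambda, R), where lambda carries the
# standardized causal effect at the causal index. This reproduces the
# marginal sampling structure GWAS summary statistics are assumed to have
# (effect estimates with noise consistent with SE, LD-correlated z-scores)
# without simulating genotypes.

#' Specification of one simulated locus pair
#'
#' Defaults are the package's reference study conditions: case/control counts
#' 21,982/41,944 per trait (effective sample size ~57,693), causal effects of
#' 0.05 on the log-odds scale (odds ratio ~1.05, genome-wide significant at
#' these sample sizes), AR(1) LD with decay 0.9 between adjacent variants,
#' and minor allele frequencies uniform on [0.05, 0.5].
#'
#' @param n_variants Number of variants at the locus.
#' @param rho AR(1) LD decay parameter in [0, 1).
#' @param config Causal configuration: `"null"`, `"shared"` (same causal
#'   variant for both traits), `"distinct"` (two causal variants in weak LD),
#'   `"trait1_only"`, or `"trait2_only"`.
#' @param causal_beta Length-2 causal log-odds effects (trait 1, trait 2).
#' @param causal_z Optional target causal z-score; when given it overrides
#'   `causal_beta` by setting each trait's causal effect to
#'   `causal_z * se` at the causal variant.
#' @param causal_idx Optional length-2 causal variant indices (NA = no causal
#'   variant for that trait). Defaults: shared at `n/2`; distinct at `n/4`
#'   and `3n/4` (weak LD separation under the default decay).
#' @param maf_range Minor-allele-frequency bounds, drawn uniformly.
#' @param n_cases,n_controls Length-2 (or recycled) per-trait counts.
#' @param ambiguous_frac Fraction of variants given strand-ambiguous (A/T,
#'   C/G) allele codes; default 0.
#' @param seed Optional seed making [simulate_locus_pair()] self-contained.
#' @return A `locus_spec` list.
#' @export
locus_spec <- function(n_variants = 50, rho = 0.9,
                       config = c("null", "shared", "distinct",
                                  "trait1_only", "trait2_only"),
                       causal_beta = c(0.05, 0.05), causal_z = NULL,
                       causal_idx = NULL, maf_range = c(0.05, 0.5),
                       n_cases = c(21982, 21982),
                       n_controls = c(41944, 41944),
                       ambiguous_frac = 0, seed = NULL) {
  config <- match.arg(config)
  n <- as.integer(n_variants)
  if (n < 1) abort("n_variants must be >= 1", class = "pleioscan_domain_error")
  if (rho < 0 || rho >= 1) {
    abort("rho must lie in [0, 1)", class = "pleioscan_domain_error")
  }
  if (is.null(causal_idx)) {
    mid <- as.integer(ceiling(n / 2))
    causal_idx <- switch(config,
      null = c(NA_integer_, NA_integer_),
      shared = c(mid, mid),
      distinct = c(as.integer(ceiling(n / 4)),
                   as.integer(ceiling(3 * n / 4))),
      trait1_only = c(mid, NA_integer_),
      trait2_only = c(NA_integer_, mid))
  }
  causal_idx <- as.integer(rep_len(causal_idx, 2))
  if (config == "null" && !all(is.na(causal_idx))) {
    abort("null config admits no causal index", class = "pleioscan_domain_error")
  }
  if (config == "distinct" &&
      (anyNA(causal_idx) || causal_idx[1] == causal_idx[2])) {
    abort("distinct config needs two different causal indices",
          class = "pleioscan_domain_error")
  }
  if (any(!is.na(causal_idx) & (causal_idx < 1 | causal_idx > n))) {
    abort("causal_idx out of range", class = "pleioscan_domain_error")
  }
  structure(list(
    n_variants = n, rho = rho, config = config,
    causal_beta = rep_len(causal_beta, 2), causal_z = causal_z,
    causal_idx = causal_idx, maf_range = maf_range,
    n_cases = rep_len(n_cases, 2), n_controls = rep_len(n_controls, 2),
    ambiguous_frac = ambiguous_frac, seed = seed), class = "locus_spec")
}

#' AR(1) LD correlation matrix
#'
#' Entry (i, j) equals `rho^|i - j|`; symmetric and positive definite for
#' `rho` in [0, 1).
#'
#' @param n Number of variants.
#' @param rho Decay parameter in [0, 1).
#' @return An `n` x `n` correlation matrix.
#' @examples
#' simulate_ld_matrix(3, 0.5)
#' @export
simulate_ld_matrix <- function(n, rho) {
  if (rho < 0 || rho >= 1) {
    abort("rho must lie in [0, 1)", class = "pleioscan_domain_error")
  }
  idx <- seq_len(n)
  rho^abs(outer(idx, idx, "-"))
}

.nonambiguous_pairs <- rbind(
  c("A", "C"), c("C", "A"), c("A", "G"), c("G", "A"),
  c("C", "T"), c("T", "C"), c("G", "T"), c("T", "G"))
.ambiguous_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

.draw_alleles <- function(n, ambiguous_frac) {
  amb <- runif(n) < ambiguous_frac
  pick_ok <- sample.int(nrow(.nonambiguous_pairs), n, replace = TRUE)
  pick_amb <- sample.int(nrow(.ambiguous_pairs), n, replace = TRUE)
  a1 <- ifelse(amb, .ambiguous_pairs[pick_amb, 1], .nonambiguous_pairs[pick_ok, 1])
  a2 <- ifelse(amb, .ambiguous_pairs[pick_amb, 2], .nonambiguous_pairs[pick_ok, 2])
  tibble::tibble(a1 = a1, a2 = a2)
}

#' Simulate one locus pair
#'
#' Draws per-variant MAFs, sets each trait's per-variant standard errors to
#' `1 / sqrt(2 maf (1 - maf) n_eff)` with `n_eff` from [neff_from_counts()],
#' and draws z-scores from `MVN(R lambda, R)` where `lambda` is zero except
#' `beta_c / se_c` at the causal index. Effect estimates are `z * se` and
#' p-values two-sided normal tails (floored at [min_representable_p()]).
#'
#' @param spec A [locus_spec()].
#' @return List with `trait1`, `trait2` (tibbles: `idx`, `maf`, `a1`, `a2`,
#'   `z`, `beta`, `se`, `p`, `n_eff`), `truth` (config and causal indices)
#'   and `ld` (the correlation matrix).
#' @export
simulate_locus_pair <- function(spec) {
  run <- function() {
    n <- spec$n_variants
    R <- simulate_ld_matrix(n, spec$rho)
    maf <- runif(n, spec$maf_range[1], spec$maf_range[2])
    alleles <- .draw_alleles(n, spec$ambiguous_frac)
    traits <- vector("list", 2)
    for (t in 1:2) {
      neff <- neff_from_counts(spec$n_cases[t], spec$n_controls[t])
      se <- 1 / sqrt(2 * maf * (1 - maf) * neff)
      lambda <- numeric(n)
      ci <- spec$causal_idx[t]
      if (!is.na(ci)) {
        beta_c <- if (!is.null(spec$causal_z)) spec$causal_z * se[ci]
                  else spec$causal_beta[t]
        lambda[ci] <- beta_c / se[ci]
      }
      z <- as.numeric(MASS::mvrnorm(1, mu = as.numeric(R %*% lambda),
                                    Sigma = R))
      traits[[t]] <- tibble::tibble(
        idx = seq_len(n), maf = maf, a1 = alleles$a1, a2 = alleles$a2,
        z = z, beta = z * se, se = se,
        p = pmax(2 * pnorm(-abs(z)), min_representable_p()),
        n_eff = neff)
    }
    list(trait1 = traits[[1]], trait2 = traits[[2]],
         truth = list(config = spec$config, causal_idx = spec$causal_idx),
         ld = R)
  }
  if (!is.null(spec$seed)) withr::with_seed(spec$seed, run()) else run()
}

#' Simulate a paired study across loci
#'
#' Places each locus in its own 1-Mb approximately independent LD block on
#' chr1, assigns variant ids and positions, and assembles everything the
#' pipeline consumes: two canonical summary-statistics tables, per-trait lead
#' lists (each locus's minimum-p variant among those reaching `lead_p`), a
#' pairwise r² proxy table derived from the simulated LD (`r2 = rho^{2|i-j|}`,
#' pairs above `proxy_r2_floor`), the block set, and per-locus ground truth.
#'
#' A fraction `swap_frac` of trait 2's records are emitted with swapped
#' allele codes and negated beta, exercising harmonization; this is pure
#' re-encoding, not a change of effect.
#'
#' @param specs List of [locus_spec()] objects (or a single one).
#' @param trait_names Length-2 character vector of trait labels.
#' @param seed Optional seed; fixing it makes the whole bundle reproducible.
#' @param swap_frac Fraction of trait-2 rows re-encoded on the other allele.
#' @param proxy_r2_floor Smallest r² written to the proxy table.
#' @param lead_p Genome-wide significance threshold for synthetic lead
#'   calling; default 5e-8.
#' @return List: `sumstats` (list of two tibbles), `leads` (list of two
#'   `lead_set`s), `proxies`, `blocks`, `truth`, `trait_names`.
#' @export
simulate_study <- function(specs, trait_names = c("trait1", "trait2"),
                           seed = NULL, swap_frac = 0.3,
                           proxy_r2_floor = 0.5, lead_p = 5e-8) {
  if (inherits(specs, "locus_spec")) specs <- list(specs)
  if (length(specs) == 0) {
    abort("need at least one locus spec", class = "pleioscan_domain_error")
  }
  run <- function() {
    ss <- list(list(), list())
    proxies <- list()
    truth <- list()
    blocks <- tibble::tibble(chrom = "chr1",
                             start = (seq_along(specs) - 1) * 1e6,
                             end = seq_along(specs) * 1e6)
    for (k in seq_along(specs)) {
      spec <- specs[[k]]
      sim <- simulate_locus_pair(spec)
      n <- spec$n_variants
      ids <- sprintf("rs%d", k * 100000L + seq_len(n))
      pos <- (k - 1) * 1e6 + seq_len(n) * 1000
      swap <- runif(n) < swap_frac
      for (t in 1:2) {
        tr <- sim[[t]]
        tab <- tibble::tibble(
          id = ids, chrom = "chr1", pos = pos,
          a1 = tr$a1, a2 = tr$a2, beta = tr$beta, se = tr$se, p = tr$p,
          maf = tr$maf, info = 1, n_eff = tr$n_eff)
        if (t == 2) {
          tab$a1[swap] <- tr$a2[swap]
          tab$a2[swap] <- tr$a1[swap]
          tab$beta[swap] <- -tr$beta[swap]
        }
        ss[[t]][[k]] <- tab
      }
      # r^2 between simulated pairs follows from the AR(1) correlation
      pair_idx <- which(
        outer(seq_len(n), seq_len(n),
              function(i, j) j > i & spec$rho^(2 * abs(i - j)) > proxy_r2_floor),
        arr.ind = TRUE)
      if (nrow(pair_idx) > 0) {
        proxies[[k]] <- tibble::tibble(
          variant_a = ids[pair_idx[, 1]], variant_b = ids[pair_idx[, 2]],
          r2 = spec$rho^(2 * abs(pair_idx[, 1] - pair_idx[, 2])),
          population = "EUR")
      }
      ci <- sim$truth$causal_idx
      truth[[k]] <- tibble::tibble(
        locus = k, block_id = .block_id("chr1", (k - 1) * 1e6, k * 1e6),
        config = spec$config,
        causal_idx1 = ci[1], causal_idx2 = ci[2],
        causal_id1 = if (is.na(ci[1])) NA_character_ else ids[ci[1]],
        causal_id2 = if (is.na(ci[2])) NA_character_ else ids[ci[2]])
    }
    sumstats <- lapply(1:2, function(t) {
      tab <- validate_sumstats(dplyr::bind_rows(ss[[t]]))$table
      attr(tab, "meta") <- study_meta(
        trait_names[t],
        n_cases = specs[[1]]$n_cases[t],
        n_controls = specs[[1]]$n_controls[t])
      tab
    })
    leads <- lapply(1:2, function(t) {
      tab <- sumstats[[t]]
      tab$locus <- (tab$pos - 1) %/% 1e6 + 1
      hits <- tab[tab$p < lead_p, , drop = FALSE]
      top <- dplyr::slice_min(dplyr::group_by(hits, .data$locus), .data$p,
                              n = 1, with_ties = FALSE)
      lead_variant_set(dplyr::ungroup(top)[, c("id", "chrom", "pos", "a1", "a2")],
                       trait_names[t])
    })
    prox <- if (length(proxies) > 0) {
      ld_proxy_table(dplyr::bind_rows(proxies))
    } else {
      ld_proxy_table(tibble::tibble(variant_a = character(),
                                    variant_b = character(), r2 = numeric()))
    }
    list(sumstats = sumstats, leads = leads, proxies = prox,
         blocks = ld_block_set(blocks), truth = dplyr::bind_rows(truth),
         trait_names = trait_names)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Write a simulated study to disk as a pipeline-ready fixture bundle
#'
#' Emits exactly the dialects the readers consume: two summary-statistics
#' TSVs, two lead-list TSVs, a proxy TSV, a BED3 block file, and a
#' `truth.tsv` of per-locus ground truth.
#'
#' @param specs List of [locus_spec()]s, passed to [simulate_study()].
#' @param dir Output directory (created if needed).
#' @param ... Further arguments to [simulate_study()] (`seed`, `trait_names`,
#'   ...).
#' @return Invisibly, a list with the `bundle` (in-memory study) and `paths`
#'   of all written files.
#' @export
write_fixture_bundle <- function(specs, dir, ...) {
  bundle <- simulate_study(specs, ...)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tn <- bundle$trait_names
  paths <- list(
    sumstats = file.path(dir, paste0(tn, ".sumstats.tsv")),
    leads = file.path(dir, paste0(tn, ".leads.tsv")),
    proxies = file.path(dir, "proxies.tsv"),
    blocks = file.path(dir, "blocks.bed"),
    truth = file.path(dir, "truth.tsv"))
  for (t in 1:2) {
    write_sumstats(bundle$sumstats[[t]], paths$sumstats[t])
    readr::write_tsv(
      tibble::as_tibble(bundle$leads[[t]])[, c("id", "chrom", "pos", "a1", "a2")],
      paths$leads[t], progress = FALSE)
  }
  readr::write_tsv(tibble::as_tibble(bundle$proxies), paths$proxies,
                   progress = FALSE)
  write_ld_blocks(bundle$blocks, paths$blocks)
  readr::write_tsv(bundle$truth, paths$truth, progress = FALSE)
  invisible(list(bundle = bundle, paths = paths))
}
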