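# Reading, validating and pairwise-harmonizing GWAS summary statistics.

# Canonical column set for a summary-statistics table. `maf`, `info` and
# `n_eff` are optional on input and filled with NA when absent.
.ss_required <- c("id", "chrom", "pos", "a1", "a2", "beta", "se", "p")
.ss_optional <- c("maf", "info", "n_eff")

# Fixed contig vocabulary (hg38-style labels, "chr" prefix added on load).
.contigs <- c(paste0("chr", 1:22), "chrX", "chrY", "chrM")

#' Smallest p-value the package stores
#'
#' p-values are kept on the natural scale; anything smaller than the smallest
#' positive normalized double is clamped to it so that validated p-values stay
#' strictly positive. Threshold comparisons are always strict (`p < threshold`)
#' and performed at full double precision.
#'
#' @return A single positive double.
#' @export
min_representable_p <- function() .Machine$double.xmin

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file (tab- or whitespace-separated, transparently
#' gunzipped by extension) of per-variant association records, maps its columns
#' onto the canonical names, validates every row, and returns a tibble of the
#' surviving records. Rows violating the record invariants are dropped and
#' tallied in a load report (attribute `"load_report"`, a tibble of
#' reason/count pairs; also see [write_load_report()]).
#'
#' Canonical columns: `id`, `chrom`, `pos`, `a1` (effect allele), `a2` (other
#' allele), `beta` (log odds ratio), `se`, `p`, and optionally `maf`, `info`,
#' `n_eff`. Validation drops rows with nonpositive SE, p outside (0, 1]
#' (p below [min_representable_p()] is clamped, not dropped), identical or
#' empty alleles, MAF outside (0, 0.5], INFO outside (0, 1], positions < 1, or
#' contigs outside chr1-22/X/Y/M. Duplicate variant ids keep the record with
#' the smallest p.
#'
#' @param path Path to the file.
#' @param column_map Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(p = "P-value", id = "SNP")`. Canonical
#'   names not listed are looked up verbatim.
#' @param meta Optional study metadata from [study_meta()]; carried as the
#'   `"meta"` attribute. When it holds case/control counts and the table lacks
#'   `n_eff`, a study-wide [neff_from_counts()] value is filled in.
#' @return A tibble with the canonical columns, attributes `"load_report"` and
#'   `"meta"`.
#' @seealso [harmonize_pair()], [write_sumstats()]
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tchrom\tpos\ta1\ta2\tbeta\tse\tp",
#'              "rs1\t1\t1000\tA\tG\t0.05\t0.01\t1e-6"), f)
#' read_sumstats(f)
#' @export
read_sumstats <- function(path, column_map = NULL, meta = NULL) {
  if (!file.exists(path)) {
    abort(paste0("summary-statistics file not found: ", path),
          class = "pleioscan_input_error")
  }
  raw <- .read_delim_auto(path)
  if (nrow(raw) == 0) {
    abort(paste0("empty summary-statistics file: ", path),
          class = "pleioscan_input_error")
  }
  df <- .apply_column_map(raw, column_map, path)
  out <- validate_sumstats(df)
  tab <- out$table
  if (!is.null(meta)) {
    if (all(is.na(tab$n_eff)) && !is.null(meta$n_cases)) {
      tab$n_eff <- neff_from_counts(meta$n_cases, meta$n_controls)
    }
    attr(tab, "meta") <- meta
  }
  attr(tab, "load_report") <- out$report
  tab
}

# Sniff tab vs generic whitespace delimiting from the header line.
.read_delim_auto <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0) {
    abort(paste0("empty summary-statistics file: ", path),
          class = "pleioscan_input_error")
  }
  if (grepl("\t", first)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_table(path, show_col_types = FALSE, progress = FALSE)
  }
}

.apply_column_map <- function(df, column_map, path) {
  wanted <- c(.ss_required, .ss_optional)
  src <- setNames(wanted, wanted)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), wanted)
    if (length(bad) > 0) {
      abort(paste0("unknown canonical column(s) in column_map: ",
                   paste(bad, collapse = ", ")),
            class = "pleioscan_config_error")
    }
    src[names(column_map)] <- column_map
  }
  have <- vapply(.ss_required, function(k) src[[k]] %in% names(df), logical(1))
  if (any(!have)) {
    abort(paste0("missing mandatory column(s) in ", path, ": ",
                 paste(src[.ss_required[!have]], collapse = ", ")),
          class = "pleioscan_config_error")
  }
  out <- tibble::tibble(.rows = nrow(df))
  for (canon in wanted) {
    out[[canon]] <- if (src[[canon]] %in% names(df)) df[[src[[canon]]]] else NA
  }
  out
}

#' Validate summary-statistics records
#'
#' Enforces the per-record invariants (see [read_sumstats()]) on a data frame
#' already holding the canonical columns. Exposed mainly so in-memory tables
#' from the simulator can share the same validation path as files.
#'
#' @param df Data frame with canonical columns.
#' @return List with `table` (validated tibble) and `report` (tibble of
#'   `reason`/`n` drop counts, including a `"retained"` row).
#' @export
validate_sumstats <- function(df) {
  df <- tibble::as_tibble(df)
  for (col in .ss_optional) if (!col %in% names(df)) df[[col]] <- NA_real_
  df <- df[, c(.ss_required, .ss_optional)]
  df$id <- as.character(df$id)
  df$chrom <- .norm_chrom(df$chrom)
  df$a1 <- toupper(as.character(df$a1))
  df$a2 <- toupper(as.character(df$a2))
  for (col in c("pos", "beta", "se", "p", "maf", "info", "n_eff")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$p[!is.na(df$p) & df$p > 0 & df$p < min_representable_p()] <-
    min_representable_p()

  drops <- rep(NA_character_, nrow(df))
  flag <- function(cond, reason) {
    cond[is.na(cond)] <- FALSE
    drops[is.na(drops) & cond] <<- reason
  }
  flag(is.na(df$id) | df$id == "", "missing id")
  flag(is.na(df$chrom) | !(df$chrom %in% .contigs), "unknown contig")
  flag(is.na(df$pos) | df$pos < 1, "invalid position")
  flag(is.na(df$a1) | is.na(df$a2) | df$a1 == "" | df$a2 == "" |
         df$a1 == df$a2 | !grepl("^[ACGT]+$", df$a1) |
         !grepl("^[ACGT]+$", df$a2), "invalid alleles")
  flag(is.na(df$beta), "missing beta")
  flag(is.na(df$se) | df$se <= 0, "nonpositive SE")
  flag(is.na(df$p) | df$p <= 0 | df$p > 1, "p out of range")
  flag(!is.na(df$maf) & (df$maf <= 0 | df$maf > 0.5), "MAF out of range")
  flag(!is.na(df$info) & (df$info <= 0 | df$info > 1), "INFO out of range")

  kept <- df[is.na(drops), , drop = FALSE]
  # duplicate ids: keep the smallest p, log the rest
  dup_n <- 0L
  if (anyDuplicated(kept$id)) {
    ord <- order(kept$p)
    first <- !duplicated(kept$id[ord])
    dup_n <- sum(!first)
    kept <- kept[sort(ord[first]), , drop = FALSE]
  }
  report <- dplyr::count(
    tibble::tibble(reason = drops[!is.na(drops)]), .data$reason, name = "n")
  if (dup_n > 0) {
    report <- dplyr::bind_rows(
      report, tibble::tibble(reason = "duplicate id", n = dup_n))
  }
  report <- dplyr::bind_rows(
    report, tibble::tibble(reason = "retained", n = nrow(kept)))
  list(table = kept, report = report)
}

.norm_chrom <- function(x) {
  x <- as.character(x)
  x <- sub("^(?i)chr", "", x, perl = TRUE)
  x[x %in% c("23", "x")] <- "X"
  x[x %in% c("24", "y")] <- "Y"
  x[x %in% c("MT", "mt", "m")] <- "M"
  paste0("chr", x)
}

#' Study metadata
#'
#' @param trait_name Trait label used in reports.
#' @param n_cases,n_controls Positive case and control counts.
#' @param build Genome build label (default `"hg38"`).
#' @return A `study_meta` list.
#' @export
study_meta <- function(trait_name, n_cases = NULL, n_controls = NULL,
                       build = "hg38") {
  if (!is.null(n_cases) && (n_cases <= 0 || n_controls <= 0)) {
    abort("case and control counts must be positive",
          class = "pleioscan_config_error")
  }
  structure(list(trait_name = trait_name, n_cases = n_cases,
                 n_controls = n_controls, build = build),
            class = "study_meta")
}

#' Write a summary-statistics table in the canonical dialect
#'
#' Tab-separated with header, canonical column names and order.
#'
#' @param x Summary-statistics tibble.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  readr::write_tsv(x[, c(.ss_required, .ss_optional)], path, progress = FALSE)
  invisible(path)
}

#' Write a load report
#'
#' @param x A table returned by [read_sumstats()], or a report tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_load_report <- function(x, path) {
  rep <- if (is.data.frame(x) && all(c("reason", "n") %in% names(x))) x
         else attr(x, "load_report")
  if (is.null(rep)) abort("no load report attached to this object",
                          class = "pleioscan_input_error")
  readr::write_tsv(rep, path, progress = FALSE)
  invisible(path)
}

#' Is an allele pair strand-ambiguous?
#'
#' A biallelic SNV is strand-ambiguous when its two alleles are reverse
#' complements of each other ({A,T} or {C,G}), so the strand cannot be
#' resolved from the allele codes alone. Indels and multi-base alleles are
#' defined non-ambiguous.
#'
#' @param a1,a2 Character vectors of alleles (recycled).
#' @return Logical vector.
#' @examples
#' is_strand_ambiguous(c("A", "A", "CT"), c("T", "G", "C"))
#' @export
is_strand_ambiguous <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize a pair of summary-statistics tables
#'
#' Intersects two traits' tables on variant identity and expresses both
#' traits' effects on the first table's effect allele. Where the second
#' table's alleles are swapped relative to the first, its beta sign is flipped
#' (`flipped = TRUE`). Strand-ambiguous SNVs and variants whose allele sets do
#' not match even under swap are removed, with reasons recorded in the
#' `"dropped"` attribute.
#'
#' Variant identity is the shared `id` (rsID); variants matching by id are
#' checked for allele compatibility, and ids present in only one table are
#' additionally matched by `chrom:pos`. Multi-allelic sites are treated as
#' distinct records per allele pair.
#'
#' @param a,b Validated summary-statistics tibbles (see [read_sumstats()]).
#' @return A `harmonized_pair` tibble with columns `id`, `chrom`, `pos`, `a1`,
#'   `a2`, `beta_a`, `se_a`, `p_a`, `maf_a`, `beta_b`, `se_b`, `p_b`, `maf_b`,
#'   `flipped`; attributes `"dropped"` (tibble of id/reason), `"trait_a"`,
#'   `"trait_b"`.
#' @examples
#' a <- tibble::tibble(id = "rs1", chrom = "chr1", pos = 100, a1 = "A",
#'                     a2 = "G", beta = 0.1, se = 0.02, p = 1e-6,
#'                     maf = 0.3, info = NA, n_eff = NA)
#' b <- a; b$a1 <- "G"; b$a2 <- "A"; b$beta <- 0.2
#' harmonize_pair(a, b)  # b's beta becomes -0.2 on effect allele A
#' @export
harmonize_pair <- function(a, b) {
  meta_a <- attr(a, "meta"); meta_b <- attr(b, "meta")
  if (!is.null(meta_a) && !is.null(meta_b) &&
      !identical(meta_a$build, meta_b$build)) {
    abort(sprintf("genome builds differ: %s vs %s", meta_a$build,
                  meta_b$build), class = "pleioscan_config_error")
  }
  a <- tibble::as_tibble(a); b <- tibble::as_tibble(b)

  # primary key: shared rsID; fallback: chrom:pos for ids private to one table
  in_both <- intersect(a$id, b$id)
  ai <- a[a$id %in% in_both, ]
  bi <- b[match(ai$id, b$id), ]
  a_rest <- a[!a$id %in% in_both, ]
  b_rest <- b[!b$id %in% in_both, ]
  if (nrow(a_rest) > 0 && nrow(b_rest) > 0) {
    ka <- paste(a_rest$chrom, a_rest$pos, sep = ":")
    kb <- paste(b_rest$chrom, b_rest$pos, sep = ":")
    hit <- match(ka, kb)
    ok <- !is.na(hit)
    if (any(ok)) {
      ai <- dplyr::bind_rows(ai, a_rest[ok, ])
      bi <- dplyr::bind_rows(bi, b_rest[hit[ok], ])
    }
  }

  if (nrow(ai) == 0) {
    return(.new_harmonized(tibble::tibble(), tibble::tibble(id = character(),
                                                            reason = character()),
                           meta_a, meta_b))
  }

  same <- bi$a1 == ai$a1 & bi$a2 == ai$a2
  swapped <- bi$a1 == ai$a2 & bi$a2 == ai$a1
  ambiguous <- is_strand_ambiguous(ai$a1, ai$a2)

  reason <- rep(NA_character_, nrow(ai))
  reason[!same & !swapped] <- "allele mismatch"
  reason[is.na(reason) & ambiguous] <- "strand-ambiguous"
  keep <- is.na(reason)

  beta_b <- ifelse(swapped, -bi$beta, bi$beta)
  pair <- tibble::tibble(
    id = ai$id, chrom = ai$chrom, pos = ai$pos, a1 = ai$a1, a2 = ai$a2,
    beta_a = ai$beta, se_a = ai$se, p_a = ai$p, maf_a = ai$maf,
    beta_b = beta_b, se_b = bi$se, p_b = bi$p, maf_b = bi$maf,
    flipped = swapped)[keep, ]
  dropped <- tibble::tibble(id = ai$id[!keep], reason = reason[!keep])
  .new_harmonized(pair, dropped, meta_a, meta_b)
}

.new_harmonized <- function(pair, dropped, meta_a, meta_b) {
  attr(pair, "dropped") <- dropped
  attr(pair, "trait_a") <- if (!is.null(meta_a)) meta_a$trait_name else "trait_a"
  attr(pair, "trait_b") <- if (!is.null(meta_b)) meta_b$trait_name else "trait_b"
  class(pair) <- c("harmonized_pair", class(pair))
  pair
}

#' Per-variant effective sample size
#'
#' For case-control GWAS with imputed genotypes, the effective sample size of
#' a variant can be recovered from its summary statistics as
#' \deqn{N_{eff} = \frac{4/(2\,MAF(1-MAF)\,INFO) - \beta^2}{SE^2}.}
#' Missing INFO scores are treated as 1. A negative value (possible when
#' \eqn{\beta^2} is large) is returned as `NA` with a warning giving the count.
#'
#' @param maf Minor allele frequency in (0, 1) (vectorized).
#' @param beta,se Effect size and its standard error (`se > 0`).
#' @param info Imputation INFO score in (0, 1]; `NA` means 1.
#' @return Numeric vector of effective sample sizes (`NA` where negative).
#' @examples
#' neff_per_variant(0.5, beta = 0, se = 0.01)        # 80000
#' neff_per_variant(0.5, beta = 0.1, se = 0.01)      # 79900
#' @export
neff_per_variant <- function(maf, beta, se, info = 1) {
  if (any(!is.na(maf) & (maf <= 0 | maf >= 1))) {
    abort("maf must be strictly inside (0, 1)", class = "pleioscan_domain_error")
  }
  if (any(!is.na(se) & se <= 0)) {
    abort("se must be positive", class = "pleioscan_domain_error")
  }
  info <- ifelse(is.na(info), 1, info)
  n <- (4 / (2 * maf * (1 - maf) * info) - beta^2) / se^2
  neg <- !is.na(n) & n < 0
  if (any(neg)) {
    warn(sprintf("%d negative effective sample size(s) set to NA", sum(neg)))
    n[neg] <- NA_real_
  }
  n
}

#' Study-wide effective sample size from case/control counts
#'
#' \deqn{N_{eff} = 4/(1/N_{cas} + 1/N_{con}),} twice the harmonic mean of the
#' case and control counts; equals \eqn{N_{cas}+N_{con}} for a balanced design
#' and is smaller otherwise.
#'
#' @param n_cases,n_controls Positive counts (vectorized).
#' @return Numeric vector.
#' @examples
#' neff_from_counts(21982, 41944)  # ~57693
#' @export
neff_from_counts <- function(n_cases, n_controls) {
  if (any(n_cases <= 0) || any(n_controls <= 0)) {
    abort("case and control counts must be positive",
          class = "pleioscan_domain_error")
  }
  4 / (1 / n_cases + 1 / n_controls)
}
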