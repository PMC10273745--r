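# LD proxy lookup and approximately independent LD-block assignment.

#' Read a pairwise LD proxy table
#'
#' TSV with columns `variant_a`, `variant_b`, `r2` and optionally
#' `population`. The symmetric closure is applied on load, so a pair stored in
#' one orientation can be queried from either side.
#'
#' @param path TSV path.
#' @return An `ld_proxies` tibble.
#' @export
read_proxy_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ld_proxy_table(df)
}

#' Construct an LD proxy table from a data frame
#'
#' @param df Data frame with `variant_a`, `variant_b`, `r2`, optional
#'   `population`.
#' @return An `ld_proxies` tibble (symmetric closure applied, duplicates
#'   collapsed).
#' @export
ld_proxy_table <- function(df) {
  need <- c("variant_a", "variant_b", "r2")
  if (!all(need %in% names(df))) {
    abort(paste0("proxy table needs columns: ", paste(need, collapse = ", ")),
          class = "pleioscan_config_error")
  }
  df <- tibble::as_tibble(df)
  if (!"population" %in% names(df)) df$population <- NA_character_
  df <- df[, c(need, "population")]
  if (any(is.na(df$r2)) || any(df$r2 < 0 | df$r2 > 1)) {
    abort("r2 values must lie in [0, 1]", class = "pleioscan_config_error")
  }
  mirror <- df
  names(mirror)[1:2] <- c("variant_b", "variant_a")
  out <- dplyr::distinct(
    dplyr::bind_rows(df, mirror[, names(df)]),
    .data$variant_a, .data$variant_b, .keep_all = TRUE)
  class(out) <- c("ld_proxies", class(out))
  out
}

#' Best available LD proxy for a variant
#'
#' Among proxies of `variant` with `r2` strictly greater than `r2_min` whose
#' partner is in `available`, returns the partner with the highest r². Ties on
#' r² are broken by genomic distance to the query (when `positions` is given),
#' then by lexicographically smallest id, so the result does not depend on the
#' row order of the table.
#'
#' @param variant Query variant id.
#' @param proxies An `ld_proxies` table.
#' @param available Character vector of ids that count as usable proxies.
#' @param r2_min r² threshold; the comparison is strict (`r2 > r2_min`).
#'   Default 0.8.
#' @param positions Optional named numeric vector of base positions for the
#'   distance tie-break.
#' @return The chosen proxy id, or `NA_character_` when none qualifies.
#' @examples
#' tab <- ld_proxy_table(tibble::tibble(
#'   variant_a = c("rs1", "rs1"), variant_b = c("rs2", "rs3"),
#'   r2 = c(0.90, 0.85)))
#' best_proxy("rs1", tab, available = c("rs2", "rs3"))  # "rs2"
#' @export
best_proxy <- function(variant, proxies, available, r2_min = 0.8,
                       positions = NULL) {
  if (r2_min < 0 || r2_min > 1) {
    abort("r2_min must lie in [0, 1]", class = "pleioscan_domain_error")
  }
  cand <- proxies[proxies$variant_a == variant &
                    proxies$r2 > r2_min &
                    proxies$variant_b %in% available &
                    proxies$variant_b != variant, , drop = FALSE]
  if (nrow(cand) == 0) return(NA_character_)
  best <- cand[cand$r2 == max(cand$r2), , drop = FALSE]
  if (nrow(best) > 1 && !is.null(positions) && variant %in% names(positions)) {
    d <- abs(positions[best$variant_b] - positions[[variant]])
    d[is.na(d)] <- Inf
    best <- best[d == min(d), , drop = FALSE]
  }
  sort(best$variant_b)[1]
}

#' Read approximately independent LD blocks from BED
#'
#' BED3 input (0-based half-open intervals). Blocks must be non-overlapping
#' within each chromosome; overlap is a configuration error at load time.
#'
#' @param path BED file path.
#' @return An `ld_blocks` tibble with columns `chrom`, `start` (0-based),
#'   `end`, `block_id` (`chrom:start-end`), sorted by chromosome and start.
#' @export
read_ld_blocks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  ld_block_set(tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)))
}

#' Construct an LD block set
#'
#' @param df Data frame with `chrom`, `start` (0-based), `end` (half-open).
#' @return An `ld_blocks` tibble, validated and sorted.
#' @export
ld_block_set <- function(df) {
  df <- tibble::as_tibble(df[, c("chrom", "start", "end")])
  df$chrom <- .norm_chrom(df$chrom)
  if (any(df$start >= df$end)) {
    abort("LD blocks must satisfy start < end", class = "pleioscan_config_error")
  }
  df <- dplyr::arrange(df, .data$chrom, .data$start)
  by_chrom <- split(df, df$chrom)
  for (blk in by_chrom) {
    if (nrow(blk) > 1 && any(blk$start[-1] < blk$end[-nrow(blk)])) {
      abort("LD blocks overlap within a chromosome",
            class = "pleioscan_config_error")
    }
  }
  df$block_id <- .block_id(df$chrom, df$start, df$end)
  class(df) <- c("ld_blocks", class(df))
  df
}

.block_id <- function(chrom, start, end) {
  sprintf("%s:%.0f-%.0f", chrom, start, end)
}

#' Write LD blocks as BED3
#'
#' @param blocks An `ld_blocks` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_blocks <- function(blocks, path) {
  readr::write_tsv(blocks[, c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Assign genomic positions to LD blocks
#'
#' A 1-based position `pos` falls in the block whose half-open BED interval
#' contains `pos - 1`; the non-overlap invariant guarantees at most one such
#' block.
#'
#' @param chrom,pos Character and numeric vectors (recycled) of 1-based
#'   coordinates.
#' @param blocks An `ld_blocks` tibble.
#' @return Character vector of `block_id`s, `NA` where no block covers the
#'   position.
#' @examples
#' blocks <- ld_block_set(tibble::tibble(chrom = "chr1",
#'                                       start = c(100, 200), end = c(200, 300)))
#' assign_block("chr1", c(150, 200, 201), blocks)
#' @export
assign_block <- function(chrom, pos, blocks) {
  n <- max(length(chrom), length(pos))
  chrom <- .norm_chrom(rep_len(chrom, n))
  pos <- rep_len(pos, n)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(blocks$chrom,
                              IRanges::IRanges(blocks$start + 1L, blocks$end))
  hit <- suppressWarnings(GenomicRanges::findOverlaps(q, s, select = "first"))
  blocks$block_id[hit]
}
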