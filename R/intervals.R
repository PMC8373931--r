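peaks_to_granges <- function(peaks) {
  check_features(peaks)
  chrom <- if ("chrom" %in% names(peaks)) peaks$chrom else "chrU"
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1, end = peaks$end)
  )
}

granges_to_peaks <- function(gr) {
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1,
         end = GenomicRanges::end(gr))
}

#' Merge overlapping or near-adjacent intervals
#'
#' Collapses a peak set into maximal merged intervals, joining intervals
#' that overlap, are book-ended, or lie within `max_gap` bp of each other
#' (bedtools-merge semantics). Idempotent.
#'
#' @param peaks Tibble with `chrom` (optional for single-chromosome sets),
#'   `start`, `end` (0-based half-open).
#' @param max_gap Maximum gap (bp) across which intervals are still merged.
#' @return A tibble with `chrom`, `start`, `end`, sorted.
#' @export
merge_intervals <- function(peaks, max_gap = 0) {
  if (nrow(peaks) == 0) return(tibble(chrom = character(), start = double(),
                                      end = double()))
  gr <- peaks_to_granges(peaks)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1)
  arrange(granges_to_peaks(merged), .data$chrom, .data$start)
}

#' Strand-aware promoter windows
#'
#' Builds the promoter interval of each gene: `[TSS - upstream,
#' TSS + downstream)` on the `+` strand and the mirror
#' `[TSS - downstream, TSS + upstream)` on the `-` strand, clipped to the
#' chromosome bounds.
#'
#' @param genes Tibble with `tss` and `strand` (and optionally `name`,
#'   `chrom`).
#' @param upstream,downstream Window extent in bp (defaults 1000 / 100).
#' @param chrom_length Optional right clipping bound.
#' @return A tibble with `chrom` (if present), `name` (if present),
#'   `start`, `end`.
#' @export
promoter_windows <- function(genes, upstream = 1000, downstream = 100,
                             chrom_length = NULL) {
  check_features(genes, need = c("tss", "strand"))
  plus <- genes$strand != "-"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  start <- pmax(start, 0)
  if (!is.null(chrom_length)) end <- pmin(end, chrom_length)
  out <- tibble(start = start, end = end)
  if ("chrom" %in% names(genes)) out <- bind_cols(
    tibble(chrom = genes$chrom), out
  )
  if ("name" %in% names(genes)) out$name <- genes$name
  out
}

#' Consensus peaks across two replicates
#'
#' Keeps the reference-replicate peaks that have at least 1 bp of overlap
#' with a peak in the other replicate — the replicate-consensus rule for
#' retaining binding sites called significant in both experiments.
#'
#' @param rep1,rep2 Peak tibbles (`chrom` optional, `start`, `end`).
#'   `rep1` is the reference: its intervals are returned.
#' @return The consensus subset of `rep1`, with attribute
#'   `reference = "rep1"`.
#' @export
consensus_replicates <- function(rep1, rep2) {
  if (nrow(rep1) == 0 || nrow(rep2) == 0) {
    out <- rep1[0, , drop = FALSE]
    attr(out, "reference") <- "rep1"
    return(out)
  }
  hits <- IRanges::overlapsAny(peaks_to_granges(rep1), peaks_to_granges(rep2))
  out <- rep1[hits, , drop = FALSE]
  attr(out, "reference") <- "rep1"
  out
}

#' Remove peaks overlapping exclusion regions
#'
#' Drops every peak with at least 1 bp of overlap with any exclusion
#' interval (e.g. gene bodies or a region between two genes that should not
#' contribute to a binding-site comparison).
#'
#' @param peaks,exclusions Peak tibbles (`chrom` optional, `start`, `end`).
#' @return The retained subset of `peaks`.
#' @export
filter_exclude <- function(peaks, exclusions) {
  if (nrow(peaks) == 0 || nrow(exclusions) == 0) return(peaks)
  hits <- IRanges::overlapsAny(peaks_to_granges(peaks),
                               peaks_to_granges(exclusions))
  peaks[!hits, , drop = FALSE]
}

#' Integer overlap percentage, rounded half up
#'
#' `round_half_up(100 * count / total)`: the rounding used when reporting
#' what percentage of one peak set overlaps another.
#'
#' @param count Number of overlapping peaks (`0 <= count <= total`).
#' @param total Peak-set size (> 0).
#' @return Integer percent in `[0, 100]`.
#' @examples
#' overlap_percentage(6182, 16740) # 37
#' overlap_percentage(1359, 1955) # 70
#' @export
overlap_percentage <- function(count, total) {
  stopifnot(total > 0, count >= 0, count <= total)
  as.integer(round_half_up(100 * count / total))
}

#' Overlap accounting between two or three peak sets
#'
#' Computes directional overlap counts (peaks of one set with >= 1 bp
#' overlap in the other), the merged-union overlap count (merged intervals
#' of the union containing peaks from both sets), derived percentages, and
#' — when a third set is supplied — the seven Euler cell counts of merged
#' union intervals by membership pattern.
#'
#' @param A,B Peak tibbles. `C` optional.
#' @param C Optional third peak set.
#' @param names Labels for the sets in the report.
#' @return An object of class `overlap_report`. `tidy()` returns the
#'   directional counts and percentages as a tibble; `glance()` a one-row
#'   summary.
#' @export
overlap_report <- function(A, B, C = NULL,
                           names = c("A", "B", "C")[seq_len(2 + !is.null(C))]) {
  sets <- list(A, B)
  if (!is.null(C)) sets <- c(sets, list(C))
  grs <- map(sets, peaks_to_granges)
  n <- map_int(grs, length)

  directional <- list()
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i == j) next
      cnt <- sum(IRanges::overlapsAny(grs[[i]], grs[[j]]))
      directional[[length(directional) + 1]] <- tibble(
        set = names[i], other = names[j], n_set = n[i],
        n_overlapping = cnt,
        percent = overlap_percentage(cnt, max(n[i], 1L))
      )
    }
  }
  directional <- list_rbind(directional)

  union_merged <- GenomicRanges::reduce(do.call(c, unname(grs)))
  membership <- vapply(grs, function(g) {
    IRanges::overlapsAny(union_merged, g)
  }, logical(length(union_merged)))
  membership <- matrix(membership, ncol = length(grs))
  merged_overlap_AB <- sum(membership[, 1] & membership[, 2])

  euler <- NULL
  if (!is.null(C)) {
    pattern <- apply(membership, 1, function(m) {
      paste(names[m], collapse = "&")
    })
    euler <- as_tibble(table(pattern), .name_repair = ~c("cell", "n_regions"))
  }

  structure(list(n = setNames(as.integer(n), names),
                 directional = directional,
                 merged_overlap_AB = merged_overlap_AB,
                 euler = euler, names = names),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> sets:",
      paste(sprintf("%s (n=%d)", x$names, x$n), collapse = ", "), "\n")
  print(x$directional)
  cat("merged union intervals containing", x$names[1], "and", x$names[2],
      "peaks:", x$merged_overlap_AB, "\n")
  if (!is.null(x$euler)) print(x$euler)
  invisible(x)
}

#' @export
tidy.overlap_report <- function(x, ...) x$directional

#' @export
glance.overlap_report <- function(x, ...) {
  tibble(
    n_A = x$n[1], n_B = x$n[2],
    a_in_b = x$directional$n_overlapping[x$directional$set == x$names[1] &
                                           x$directional$other == x$names[2]],
    b_in_a = x$directional$n_overlapping[x$directional$set == x$names[2] &
                                           x$directional$other == x$names[1]],
    merged_overlap = x$merged_overlap_AB
  )
}
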