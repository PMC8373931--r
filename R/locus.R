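#' A deterministic toy HoxD-like locus
#'
#' Builds a ~10x scaled-down model of the mouse *HoxD* locus on a 400 kb
#' chromosome at 1 kb working resolution. The fixture encodes the features
#' that drive the regulatory-reallocation analysis:
#'
#' * genes `Lnpk`, `Evx2`, `Hoxd13` ... `Hoxd1`, `Mtx2` (cluster genes on
#'   the `-` strand);
#' * distal (C-DOM) enhancers `GCR`, `IslandA` centromeric of the inversion
#'   breakpoint plus `Prox` adjacent to `Hoxd13` inside it, and proximal
#'   (T-DOM) enhancers `CS39`, `CS65`, `CS68`, `PLE01`–`PLE05`, with the
#'   PLE group and `CS68` placed telomeric of the inversion breakpoint so
#'   they are never inverted;
#' * five CTCF boundary groups `B1`–`B5` ordered left to right, with
#'   `B2`/`B3` the bidirectional intra-cluster pair, `B1` forward-biased
#'   and `B4`/`B5` reverse-biased;
#' * breakpoint pairs for the two inversion alleles: `inv2` (5' breakpoint
#'   telomeric of `Lnpk`, 3' breakpoint immediately telomeric of `CS65`)
#'   and `ulnaless` (5' breakpoint inside the `Lnpk` body, 3' breakpoint
#'   centromeric of `CS65`).
#'
#' All coordinates are 0-based half-open and are fixture constants defined
#' in this one function.
#'
#' @return An object of class `toy_locus`: a list with `chrom`, `length`,
#'   `resolution`, tibbles `genes`, `enhancers`, `ctcf_sites`, and a
#'   `breakpoints` list.
#' @examples
#' locus <- make_toy_hoxd_locus()
#' locus$enhancers
#' @export
make_toy_hoxd_locus <- function() {
  genes <- tibble(
    name = c("Lnpk", "Evx2", "Hoxd13", "Hoxd12", "Hoxd11", "Hoxd10",
             "Hoxd9", "Hoxd8", "Hoxd4", "Hoxd3", "Hoxd1", "Mtx2"),
    tss = c(80000, 165000, 170000, 175000, 180000, 184000,
            188000, 191000, 195000, 198000, 202000, 370000),
    strand = c("+", rep("-", 10), "+"),
    start = c(70000, 164000, 169000, 174000, 179000, 183000,
              187000, 190000, 194000, 197000, 201000, 370000),
    end = c(95000, 166000, 171000, 176000, 181000, 185000,
            189000, 192000, 196000, 199000, 203000, 385000)
  )
  enhancers <- tibble(
    name = c("GCR", "IslandA", "Prox",
             "CS39", "CS65", "CS68",
             paste0("PLE0", 1:5)),
    start = c(40000, 60000, 150000, 225000, 240000, 270000,
              280000, 286000, 292000, 298000, 304000),
    end = c(41000, 61000, 151000, 226000, 241000, 271000,
            281000, 287000, 293000, 299000, 305000),
    class = c("distal", "distal", "distal",
              rep("proximal", 8))
  )
  ctcf <- tibble(
    position = c(19200, 20000, 20800,
                 176200, 177000, 177800, 178600,
                 192200, 193000, 193800, 194600,
                 209200, 210000,
                 329200, 330000, 330800),
    orientation = c("+", "+", "+",
                    "+", "-", "+", "-",
                    "+", "-", "+", "-",
                    "-", "-",
                    "-", "-", "-"),
    weight = c(1, 1, 1,
               1, 1, 1, 1,
               1, 1, 1, 1,
               0.8, 0.8,
               1, 1, 1),
    group = rep(c("B1", "B2", "B3", "B4", "B5"), times = c(3, 4, 4, 2, 3))
  )
  structure(list(
    chrom = "chrS",
    length = 400000,
    resolution = 1000,
    genes = genes,
    enhancers = enhancers,
    ctcf_sites = ctcf,
    breakpoints = list(inv2 = c(100000, 260000),
                       ulnaless = c(85000, 230000))
  ), class = "toy_locus")
}

#' @export
print.toy_locus <- function(x, ...) {
  cat("<toy_locus> ", x$chrom, ", ", x$length, " bp at ", x$resolution,
      " bp resolution: ", nrow(x$genes), " genes, ", nrow(x$enhancers),
      " enhancers, ", nrow(x$ctcf_sites), " CTCF sites\n", sep = "")
  invisible(x)
}

#' Compile the rearrangement of a named toy allele
#'
#' @param locus A [make_toy_hoxd_locus()] fixture.
#' @param allele `"inv2"` or `"ulnaless"`, or supply explicit 0-based
#'   `breakpoints = c(start, end)` of the inverted segment.
#' @param breakpoints Optional explicit breakpoints overriding `allele`.
#' @return A [segment_map][compile_rearrangement].
#' @export
toy_rearrangement <- function(locus, allele = c("inv2", "ulnaless"),
                              breakpoints = NULL) {
  stopifnot(inherits(locus, "toy_locus"))
  if (is.null(breakpoints)) {
    allele <- match.arg(allele)
    breakpoints <- locus$breakpoints[[allele]]
  }
  spec <- rearrangement_spec(
    locus$chrom, op_inversion(breakpoints[1], breakpoints[2])
  )
  compile_rearrangement(spec, locus$length)
}

#' Lift a toy locus onto a mutant coordinate system
#'
#' Lifts gene TSSs (and the body piece containing each lifted TSS),
#' enhancers and CTCF sites through a segment map, flipping strands and
#' orientations inside inverted blocks.
#'
#' @param locus A [make_toy_hoxd_locus()] fixture (wild-type coordinates).
#' @param map A [segment_map][compile_rearrangement] from those coordinates.
#' @return A `toy_locus` on the mutant axis.
#' @export
lift_locus <- function(locus, map) {
  stopifnot(inherits(locus, "toy_locus"), inherits(map, "segment_map"))
  tss_hit <- lift_position(map, locus$genes$tss)
  stopifnot(nrow(tss_hit) == nrow(locus$genes))
  genes <- locus$genes
  genes$tss <- tss_hit$position
  genes$strand <- ifelse(tss_hit$orientation == "flipped",
                         flip_strand(genes$strand), genes$strand)
  bodies <- lift_features(
    map, tibble(start = locus$genes$start, end = locus$genes$end,
                name = locus$genes$name, strand = locus$genes$strand),
    span_policy = "split"
  )
  base_name <- sub("/.*$", "", bodies$name)
  body_for <- function(gene, tss) {
    b <- bodies[base_name == gene &
                  bodies$start <= tss & tss < bodies$end, , drop = FALSE]
    if (nrow(b) == 0) c(NA_real_, NA_real_) else c(b$start[1], b$end[1])
  }
  picked <- map2(genes$name, genes$tss, body_for)
  genes$start <- map_dbl(picked, 1)
  genes$end <- map_dbl(picked, 2)

  enh <- lift_features(
    map, select(locus$enhancers, "start", "end", "name", "class"),
    span_policy = "split"
  )
  enhancers <- select(enh, "name", "start", "end", "class")

  ctcf_lift <- lift_features(
    map, tibble(start = locus$ctcf_sites$position,
                end = locus$ctcf_sites$position + 1,
                name = paste0("site_", seq_len(nrow(locus$ctcf_sites))),
                strand = locus$ctcf_sites$orientation,
                weight = locus$ctcf_sites$weight,
                group = locus$ctcf_sites$group),
    span_policy = "split"
  )
  ctcf <- tibble(position = ctcf_lift$start,
                 orientation = ctcf_lift$strand,
                 weight = ctcf_lift$weight,
                 group = ctcf_lift$group) |>
    arrange(.data$position)

  structure(list(
    chrom = locus$chrom,
    length = map$mut_length,
    resolution = locus$resolution,
    genes = arrange(genes, .data$tss),
    enhancers = arrange(enhancers, .data$start),
    ctcf_sites = ctcf,
    breakpoints = list()
  ), class = "toy_locus")
}

#' Model one allele of the toy locus end to end
#'
#' For the requested allele this compiles the rearrangement (if any), lifts
#' the locus features, clusters CTCF sites into boundary groups, predicts
#' the domain partition, and assigns enhancers to genes by shared domain.
#'
#' @param locus A [make_toy_hoxd_locus()] fixture.
#' @param allele `"wildtype"`, `"inv2"`, `"ulnaless"`, or any label when
#'   explicit `breakpoints` are supplied.
#' @param breakpoints Optional 0-based inversion breakpoints for custom
#'   alleles.
#' @param max_gap,min_weight_per_orientation Passed to [cluster_ctcf()];
#'   defaults scale with the locus resolution.
#' @param min_strength Passed to [predict_partition()].
#' @return An object of class `allele_model`: a list with `allele`, `locus`
#'   (on the allele's own coordinates), `map` (`NULL` for wild type),
#'   `clusters`, `partition` and `assignment`. `tidy()` returns the
#'   gene-to-enhancer assignment.
#' @examples
#' locus <- make_toy_hoxd_locus()
#' wt <- model_allele(locus, "wildtype")
#' enhancers_of(wt$assignment, "Hoxd13")
#' @export
model_allele <- function(locus, allele = "wildtype", breakpoints = NULL,
                         max_gap = 2 * locus$resolution,
                         min_weight_per_orientation = 1, min_strength = 1) {
  stopifnot(inherits(locus, "toy_locus"))
  if (allele == "wildtype" && is.null(breakpoints)) {
    map <- NULL
    allele_locus <- locus
    coord_system <- "wildtype"
  } else {
    map <- toy_rearrangement(locus, allele, breakpoints = breakpoints)
    allele_locus <- lift_locus(locus, map)
    coord_system <- paste0("mutant:", allele)
  }
  clusters <- cluster_ctcf(allele_locus$ctcf_sites, max_gap = max_gap,
                           min_weight_per_orientation =
                             min_weight_per_orientation)
  partition <- predict_partition(clusters, span = c(0, allele_locus$length),
                                 min_strength = min_strength,
                                 chrom = allele_locus$chrom,
                                 coord_system = coord_system)
  assignment <- assign_enhancers(partition, allele_locus$enhancers,
                                 allele_locus$genes)
  structure(list(allele = allele, locus = allele_locus, map = map,
                 clusters = clusters, partition = partition,
                 assignment = assignment),
            class = "allele_model")
}

#' @export
print.allele_model <- function(x, ...) {
  cat("<allele_model> ", x$allele, ": ", nrow(x$partition$boundaries),
      " boundaries, ", nrow(x$partition$domains), " domains\n", sep = "")
  d13 <- enhancers_of(x$assignment, "Hoxd13")
  if (length(d13) > 0) {
    cat("  Hoxd13 enhancers: ", paste(d13, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.allele_model <- function(x, ...) as_tibble(x$assignment)
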