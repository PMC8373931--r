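#' Cluster occupied CTCF sites into oriented boundary groups
#'
#' Single-linkage clustering of CTCF sites along the chromosome: sites whose
#' gap to the nearest neighbour is at most `max_gap` join one cluster.
#' A cluster is classed `bidirectional` when the summed occupancy weight of
#' each orientation reaches `min_weight_per_orientation`, mirroring the
#' notion of a concentration of occupied sites able to insulate in both
#' directions; otherwise it is biased toward the dominant orientation.
#'
#' @param sites Tibble with columns `position` (bp), `orientation`
#'   (`"+"`/`"-"` or `"forward"`/`"reverse"`) and optionally `weight`
#'   (defaults to 1).
#' @param max_gap Maximum gap (bp) between consecutive member sites.
#' @param min_weight_per_orientation Weight each orientation needs for a
#'   cluster to count as bidirectional.
#' @return A tibble of class `boundary_clusters` with one row per cluster:
#'   `cluster`, `start`, `end`, `midpoint`, `n_sites`, `fwd_weight`,
#'   `rev_weight`, `strength` and `class`, plus a `sites` list-column of
#'   member sites. Empty input gives zero rows.
#' @export
cluster_ctcf <- function(sites, max_gap = 20000,
                         min_weight_per_orientation = 1) {
  if (nrow(sites) == 0) {
    return(structure(
      tibble(cluster = integer(), start = double(), end = double(),
             midpoint = double(), n_sites = integer(), fwd_weight = double(),
             rev_weight = double(), strength = double(), class = character(),
             sites = list()),
      class = c("boundary_clusters", class(tibble()))))
  }
  check_features(sites, need = c("position", "orientation"))
  sites <- as_tibble(sites)
  if (!"weight" %in% names(sites)) sites$weight <- 1
  ori <- sites$orientation
  sites$orientation <- ifelse(ori %in% c("+", "forward", "F"), "+", "-")
  sites <- arrange(sites, .data$position)
  gap <- c(Inf, diff(sites$position))
  sites$cluster <- cumsum(gap > max_gap)
  out <- sites |>
    group_by(.data$cluster) |>
    summarise(
      start = min(.data$position),
      end = max(.data$position) + 1,
      midpoint = (min(.data$position) + max(.data$position) + 1) / 2,
      n_sites = n(),
      fwd_weight = sum(.data$weight[.data$orientation == "+"]),
      rev_weight = sum(.data$weight[.data$orientation == "-"]),
      strength = sum(.data$weight),
      sites = list(dplyr::pick("position", "orientation", "weight")),
      .groups = "drop"
    ) |>
    mutate(class = dplyr::case_when(
      .data$fwd_weight >= min_weight_per_orientation &
        .data$rev_weight >= min_weight_per_orientation ~ "bidirectional",
      .data$fwd_weight >= .data$rev_weight ~ "forward-biased",
      TRUE ~ "reverse-biased"
    )) |>
    select("cluster", "start", "end", "midpoint", "n_sites", "fwd_weight",
           "rev_weight", "strength", "class", "sites")
  structure(out, class = c("boundary_clusters", class(tibble())))
}

#' Predict the domain partition implied by boundary clusters
#'
#' Boundaries are the clusters whose strength reaches `min_strength`;
#' domains are the maximal intervals between consecutive boundary cluster
#' midpoints, with the span edges closing the first and last domain.
#' Each adjacent boundary pair is annotated `convergent` when the left
#' boundary carries forward-oriented sites facing the right boundary's
#' reverse-oriented sites — the configuration that favours loop/domain
#' formation between them.
#'
#' @param clusters A [boundary_clusters][cluster_ctcf] tibble (already on
#'   the target coordinate system; lift CTCF sites first for mutants).
#' @param span 0-based half-open bp interval `c(start, end)` to partition.
#' @param min_strength Minimum cluster strength to act as a boundary.
#' @param chrom,coord_system Labels recorded on the partition.
#' @return An object of class `domain_partition` with tibbles `domains`
#'   (`domain`, `start`, `end`) and `boundaries` (qualifying clusters with
#'   `midpoint` and `convergent_with_next`), plus `span`.
#' @export
predict_partition <- function(clusters, span, min_strength = 1,
                              chrom = "chrS", coord_system = "wildtype") {
  q <- clusters[clusters$strength >= min_strength &
                  clusters$midpoint > span[1] &
                  clusters$midpoint < span[2], , drop = FALSE]
  q <- arrange(as_tibble(q), .data$midpoint)
  edges <- c(span[1], q$midpoint, span[2])
  domains <- tibble(domain = seq_len(length(edges) - 1),
                    start = head(edges, -1), end = tail(edges, -1))
  convergent <- rep(NA, nrow(q))
  if (nrow(q) > 1) {
    for (k in seq_len(nrow(q) - 1)) {
      convergent[k] <- q$fwd_weight[k] > 0 && q$rev_weight[k + 1] > 0
    }
  }
  q$convergent_with_next <- convergent
  part <- structure(list(domains = domains, boundaries = q, span = span,
                         chrom = chrom, coord_system = coord_system),
                    class = "domain_partition")
  stopifnot(all(part$domains$end > part$domains$start),
            isTRUE(all.equal(sum(part$domains$end - part$domains$start),
                             span[2] - span[1])))
  part
}

#' @export
print.domain_partition <- function(x, ...) {
  cat("<domain_partition> ", x$chrom, " [", x$coord_system, "], span [",
      x$span[1], ", ", x$span[2], "), ", nrow(x$domains), " domain(s), ",
      nrow(x$boundaries), " boundary(ies)\n", sep = "")
  print(x$domains)
  invisible(x)
}

#' @export
tidy.domain_partition <- function(x, ...) x$domains

which_domain <- function(partition, position) {
  d <- partition$domains
  idx <- findInterval(position, c(d$start, d$end[nrow(d)]),
                      rightmost.closed = FALSE)
  idx[position < partition$span[1] | position >= partition$span[2]] <- NA
  idx
}

#' Assign enhancers to genes by shared domain
#'
#' An enhancer is assigned to a gene when the midpoints of both fall in the
#' same predicted domain — the same-domain accessibility rule that predicts
#' which regulatory inputs a promoter can sample after a rearrangement.
#'
#' @param partition A [domain_partition][predict_partition].
#' @param enhancers Tibble with `name` and either `start`/`end` or
#'   `position`; optional `class` column is carried through.
#' @param genes Tibble with `name` and `tss` (or `start`/`end`, whose
#'   midpoint is used).
#' @return A tibble of class `enhancer_assignment`: one row per
#'   (gene, enhancer) pair sharing a domain, with column `domain`. Features
#'   outside the span are excluded and counted in attribute `n_excluded`.
#' @export
assign_enhancers <- function(partition, enhancers, genes) {
  midpoint_of <- function(df) {
    if ("position" %in% names(df)) df$position
    else if ("tss" %in% names(df)) df$tss
    else (df$start + df$end) / 2
  }
  e_mid <- midpoint_of(enhancers)
  g_mid <- if ("tss" %in% names(genes)) genes$tss else midpoint_of(genes)
  e_dom <- which_domain(partition, e_mid)
  g_dom <- which_domain(partition, g_mid)
  n_excluded <- sum(is.na(e_dom)) + sum(is.na(g_dom))
  if (n_excluded > 0) {
    warn(paste(n_excluded, "feature(s) outside the partition span excluded"))
  }
  e_tab <- tibble(enhancer = enhancers$name, domain = e_dom,
                  class = enhancers$class %||% NA_character_)
  g_tab <- tibble(gene = genes$name, domain = g_dom)
  out <- g_tab |>
    filter(!is.na(.data$domain)) |>
    left_join(filter(e_tab, !is.na(.data$domain)), by = "domain",
              relationship = "many-to-many") |>
    filter(!is.na(.data$enhancer)) |>
    arrange(.data$gene, .data$enhancer) |>
    select("gene", "enhancer", "class", "domain")
  attr(out, "n_excluded") <- n_excluded
  structure(out, class = c("enhancer_assignment", class(tibble())))
}

#' Enhancers for one gene
#'
#' Convenience accessor over an [assign_enhancers()] result.
#'
#' @param assignment An `enhancer_assignment` tibble.
#' @param gene Gene name.
#' @return Character vector of enhancer names.
#' @export
enhancers_of <- function(assignment, gene) {
  sort(assignment$enhancer[assignment$gene == gene])
}

#' Difference between two enhancer assignments
#'
#' Reports, per gene, the enhancer–gene pairs gained and lost between two
#' assignments over the same gene universe — the summary used to describe
#' regulatory reallocation between alleles.
#'
#' @param before,after [enhancer_assignment][assign_enhancers] tibbles.
#' @return A tibble with columns `gene`, `enhancer`, `change`
#'   (`"gained"`/`"lost"`), sorted by gene. `diff_assignment(a, b)` gains
#'   equal `diff_assignment(b, a)` losses.
#' @export
diff_assignment <- function(before, after) {
  key <- c("gene", "enhancer")
  gained <- anti_join(after[key], before[key], by = key)
  lost <- anti_join(before[key], after[key], by = key)
  out <- bind_rows(
    mutate(gained, change = "gained"),
    mutate(lost, change = "lost")
  )
  arrange(out, .data$gene, .data$change, .data$enhancer)
}
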