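#' Simulate replicate peak sets with planted consensus structure
#'
#' Plants `n_consensus` non-overlapping peaks per factor and produces two
#' replicates of each: every replicate contains all planted peaks (jittered
#' by up to `jitter` bp) plus `n_extra_per_rep` replicate-private peaks.
#' With two factors, a fraction `cross_overlap` of the second factor's
#' planted peaks is placed overlapping first-factor peaks, the rest in
#' disjoint positions — a generative model for consensus/overlap statistics
#' between binding-site repertoires.
#'
#' @param n_consensus Planted (consensus) peaks per factor.
#' @param n_extra_per_rep Replicate-private extra peaks.
#' @param genome_length Chromosome length (bp).
#' @param peak_width Peak width (bp).
#' @param jitter Maximum absolute per-replicate shift of planted peaks (bp).
#' @param factors Character vector of factor labels (1 or 2).
#' @param cross_overlap Fraction of factor-2 planted peaks overlapping
#'   factor-1 peaks (only with two factors).
#' @param seed Integer seed.
#' @return A tibble with columns `factor`, `replicate` (`"rep1"`/`"rep2"`),
#'   `chrom`, `start`, `end`, `name`, `planted` (logical).
#' @export
simulate_peaksets <- function(n_consensus, n_extra_per_rep = 0,
                              genome_length = 1e6, peak_width = 400,
                              jitter = 0, factors = "A",
                              cross_overlap = 0, seed = 1) {
  stopifnot(length(factors) %in% c(1, 2), peak_width > 0)
  slot_width <- peak_width + 2 * jitter + 2
  n_slots <- floor(genome_length / slot_width)
  n_fac <- length(factors)
  needed <- n_fac * n_consensus
  if (needed > n_slots) abort("peaks do not fit in the genome without overlap")
  set.seed(seed)
  slots <- sample(n_slots, needed)
  slot_start <- function(s) (s - 1) * slot_width + jitter + 1

  planted <- list()
  idx <- 1
  for (f in seq_len(n_fac)) {
    take <- slots[idx:(idx + n_consensus - 1)]
    idx <- idx + n_consensus
    starts <- slot_start(take)
    if (f == 2 && cross_overlap > 0) {
      n_over <- rbinom(1, n_consensus, cross_overlap)
      if (n_over > 0) {
        # overlap the first factor's peaks, shifted by half a width
        donor <- sample(planted[[1]]$start, n_over)
        starts[seq_len(n_over)] <- donor + floor(peak_width / 2)
      }
    }
    planted[[f]] <- tibble(factor = factors[f],
                           start = starts, end = starts + peak_width,
                           name = sprintf("%s_cons_%05d", factors[f],
                                          seq_len(n_consensus)))
  }

  out <- list()
  for (f in seq_len(n_fac)) {
    for (r in 1:2) {
      shift <- if (jitter > 0) {
        sample(seq(-jitter, jitter), n_consensus, replace = TRUE)
      } else 0
      rep_peaks <- planted[[f]] |>
        mutate(start = .data$start + shift, end = .data$end + shift,
               replicate = paste0("rep", r), planted = TRUE)
      if (n_extra_per_rep > 0) {
        extra_start <- runif(n_extra_per_rep, 0, genome_length - peak_width)
        extra <- tibble(factor = factors[f],
                        start = floor(extra_start),
                        end = floor(extra_start) + peak_width,
                        name = sprintf("%s_rep%d_extra_%05d", factors[f], r,
                                       seq_len(n_extra_per_rep)),
                        replicate = paste0("rep", r), planted = FALSE)
        rep_peaks <- bind_rows(rep_peaks, extra)
      }
      out[[length(out) + 1]] <- rep_peaks
    }
  }
  list_rbind(out) |>
    mutate(chrom = "chrU") |>
    select("factor", "replicate", "chrom", "start", "end", "name",
           "planted") |>
    arrange(.data$factor, .data$replicate, .data$start)
}

#' Configuration for the UMI count simulator
#'
#' Defines the generative model behind [simulate_counts()]: per-cell depth
#' factors are log-normal, gene counts are negative binomial with mean
#' `depth * rate * fold` and gene-wise dispersion `theta`, and a planted
#' gene–gene correlation is induced by a shared per-cell latent factor that
#' multiplies one gene's rate and divides the other's (coupling 0 means
#' independence).
#'
#' The defaults emulate the dissected proximal-forelimb experiment the
#' package models: two genotypes (`wt`, `inv2`), two proximal-limb clusters
#' (`c1`, `c6`) with 500 cells per (cluster, genotype), four focal genes
#' plus background genes, a planted 2-fold gain of `Hoxd13` in the mutant
#' proximal clusters, and an anti-correlation between `Hoxd13` and `Hoxa11`.
#'
#' @param genes Tibble with `gene`, `rate` (expected UMIs per unit depth)
#'   and `theta` (NB dispersion; large values approach Poisson).
#' @param cells Tibble with `cluster`, `genotype`, `n` (cell counts).
#' @param fold_changes Tibble with `gene`, `cluster`, `genotype`, `fold`
#'   (multiplicative planted effects; absent combinations default to 1).
#' @param coupling Tibble with `gene1`, `gene2`, `coefficient` (latent
#'   factor scale; positive values anti-correlate the pair).
#' @param depth_meanlog,depth_sdlog Log-normal parameters of the per-cell
#'   depth factor.
#' @return An object of class `scrna_sim_config`.
#' @export
scrna_sim_config <- function(
    genes = tibble(
      gene = c("Hoxd13", "Hoxa11", "Hoxd11", "Hoxa13",
               paste0("bg", sprintf("%02d", 1:16))),
      rate = c(1.4e-4, 2.4e-4, 2.0e-4, 0.6e-4, rep(2e-3, 16)),
      theta = c(rep(2, 4), rep(5, 16))
    ),
    cells = tidyr::crossing(cluster = c("c1", "c6"),
                            genotype = c("wt", "inv2"), n = 500),
    fold_changes = tibble(gene = "Hoxd13",
                          cluster = c("c1", "c6"),
                          genotype = "inv2", fold = 2),
    coupling = tibble(gene1 = "Hoxd13", gene2 = "Hoxa11",
                      coefficient = 0.8),
    depth_meanlog = log(5000), depth_sdlog = 0.35) {
  stopifnot(all(genes$rate >= 0), all(genes$theta > 0), all(cells$n >= 0))
  structure(list(genes = genes, cells = cells, fold_changes = fold_changes,
                 coupling = coupling, depth_meanlog = depth_meanlog,
                 depth_sdlog = depth_sdlog),
            class = "scrna_sim_config")
}

#' Simulate a UMI count matrix
#'
#' Draws counts from the model described in [scrna_sim_config()].
#'
#' @param config An [scrna_sim_config()].
#' @param seed Integer seed.
#' @return A `count_matrix` object: a list with `counts` (sparse
#'   genes x cells [Matrix::dgCMatrix]) and `cells` metadata tibble
#'   (`cell_id`, `genotype`, `cluster`, `depth` — depth recomputed as the
#'   column sum).
#' @export
simulate_counts <- function(config = scrna_sim_config(), seed = 1) {
  stopifnot(inherits(config, "scrna_sim_config"))
  set.seed(seed)
  groups <- config$cells[config$cells$n > 0, , drop = FALSE]
  genes <- config$genes
  n_cells <- sum(groups$n)
  meta <- tibble(
    cluster = rep(groups$cluster, groups$n),
    genotype = rep(groups$genotype, groups$n)
  )
  meta$cell_id <- sprintf("cell_%05d", seq_len(n_cells))
  s_c <- rlnorm(n_cells, config$depth_meanlog, config$depth_sdlog)
  meta$depth_factor <- s_c # latent depth; realized depth is the column sum

  # per-gene per-cell fold multipliers from the planted effects
  mu <- outer(genes$rate, s_c) # genes x cells
  fc <- config$fold_changes
  if (!is.null(fc) && nrow(fc) > 0) {
    for (k in seq_len(nrow(fc))) {
      g <- match(fc$gene[k], genes$gene)
      cols <- which(meta$cluster == fc$cluster[k] &
                      meta$genotype == fc$genotype[k])
      mu[g, cols] <- mu[g, cols] * fc$fold[k]
    }
  }
  cp <- config$coupling
  if (!is.null(cp) && nrow(cp) > 0) {
    for (k in seq_len(nrow(cp))) {
      if (cp$coefficient[k] == 0) next
      g1 <- match(cp$gene1[k], genes$gene)
      g2 <- match(cp$gene2[k], genes$gene)
      lat <- exp(cp$coefficient[k] * rnorm(n_cells))
      mu[g1, ] <- mu[g1, ] * lat
      mu[g2, ] <- mu[g2, ] / lat
    }
  }
  counts <- matrix(
    rnbinom(length(mu), size = rep(genes$theta, times = n_cells), mu = mu),
    nrow = nrow(genes), ncol = n_cells,
    dimnames = list(genes$gene, meta$cell_id)
  )
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  meta$depth <- Matrix::colSums(counts)
  count_matrix(counts, meta)
}

#' Construct a count-matrix container
#'
#' @param counts Genes x cells integer matrix (dense or sparse; stored
#'   sparse). Row names are gene names, column names cell ids.
#' @param cells Tibble of per-cell metadata with `cell_id` matching the
#'   matrix columns; `depth` is recomputed from the column sums.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, cells) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")
  if (any(counts < 0)) abort("counts must be non-negative")
  stopifnot(identical(colnames(counts), cells$cell_id))
  cells$depth <- unname(Matrix::colSums(counts))
  structure(list(counts = counts, cells = as_tibble(cells)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells; median depth ", median(x$cells$depth), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.count_matrix <- function(x, ...) {
  tt <- Matrix::summary(x$counts)
  tibble(gene = rownames(x$counts)[tt$i],
         cell_id = colnames(x$counts)[tt$j],
         count = tt$x)
}
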