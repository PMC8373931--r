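cell_index <- function(M, cluster = NULL, genotype = NULL, cells = NULL) {
  keep <- rep(TRUE, nrow(M$cells))
  if (!is.null(cluster)) keep <- keep & M$cells$cluster %in% cluster
  if (!is.null(genotype)) keep <- keep & M$cells$genotype %in% genotype
  if (!is.null(cells)) keep <- keep & M$cells$cell_id %in% cells
  which(keep)
}

gene_counts <- function(M, gene, idx) {
  g <- match(gene, rownames(M$counts))
  if (is.na(g)) abort(paste0("gene '", gene, "' not found"))
  as.numeric(M$counts[g, idx])
}

subset_label <- function(cluster, genotype) {
  paste(c(if (!is.null(cluster)) paste0("cluster=",
                                        paste(cluster, collapse = "/")),
          if (!is.null(genotype)) paste0("genotype=",
                                         paste(genotype, collapse = "/")),
          if (is.null(cluster) && is.null(genotype)) "all cells"),
        collapse = ", ")
}

#' Zero-proportion detection summary for one gene
#'
#' In droplet scRNA-seq the fraction of cells with zero UMIs for a gene is
#' strongly anti-correlated with its mean expression, so the zero
#' proportion `p0` (and its complement, the detection proportion) serves as
#' an expression proxy. The confidence interval is the Wilson score
#' interval at the requested level.
#'
#' @param M A [count_matrix].
#' @param gene Gene name.
#' @param cluster,genotype,cells Optional cell filters (intersection).
#' @param conf_level CI level (default 0.95).
#' @return A one-row tibble of class `detection_summary`: `gene`, `subset`,
#'   `n_cells`, `p_zero`, `p_detected`, `ci_lo`, `ci_hi` (CI on
#'   `p_detected`).
#' @export
detection_summary <- function(M, gene, cluster = NULL, genotype = NULL,
                              cells = NULL, conf_level = 0.95) {
  idx <- cell_index(M, cluster, genotype, cells)
  if (length(idx) == 0) abort("empty cell subset")
  x <- gene_counts(M, gene, idx)
  n <- length(x)
  detected <- sum(x > 0)
  ci <- if (detected %in% c(0, n)) {
    # prop.test degenerates at the boundary; Wilson closed form still holds
    wilson_ci(detected, n, conf_level)
  } else {
    as.numeric(prop.test(detected, n, correct = FALSE,
                         conf.level = conf_level)$conf.int)
  }
  structure(
    tibble(gene = gene, subset = subset_label(cluster, genotype),
           n_cells = n, p_zero = 1 - detected / n,
           p_detected = detected / n, ci_lo = ci[1], ci_hi = ci[2]),
    class = c("detection_summary", class(tibble())))
}

wilson_ci <- function(x, n, conf_level) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}

#' Conditional detection of one gene given another
#'
#' Splits the cell subset by whether `geneA` is detected (count > 0) and
#' tests whether `geneB` detection differs between the two groups: the 2x2
#' contingency table, the two-sided Fisher exact p value and the
#' conditional odds ratio (0 and infinity are possible; a zero margin
#' flags the odds ratio undefined and yields p = 1).
#'
#' @param M A [count_matrix].
#' @param geneA,geneB Gene names; `geneA` defines the conditioning split.
#' @param cluster,genotype,cells Optional cell filters.
#' @return A list of class `conditional_detection` with `table` (2x2
#'   matrix, rows = A detected/not, columns = B detected/not), `p_value`,
#'   `odds_ratio`, `or_defined`, and the detection proportions of B in each
#'   A group.
#' @export
conditional_detection <- function(M, geneA, geneB, cluster = NULL,
                                  genotype = NULL, cells = NULL) {
  idx <- cell_index(M, cluster, genotype, cells)
  a <- gene_counts(M, geneA, idx) > 0
  b <- gene_counts(M, geneB, idx) > 0
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("A_detected", "A_not"),
                                c("B_detected", "B_not")))
  margin_zero <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (margin_zero) {
    p <- 1
    or <- NA_real_
  } else {
    ft <- fisher.test(tab)
    p <- ft$p.value
    # unconditional (sample) odds ratio so perfect association gives 0/Inf
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
  structure(list(
    geneA = geneA, geneB = geneB,
    subset = subset_label(cluster, genotype),
    table = tab, p_value = p, odds_ratio = or,
    or_defined = !margin_zero,
    p_B_given_A = tab[1, 1] / max(1, sum(tab[1, ])),
    p_B_given_notA = tab[2, 1] / max(1, sum(tab[2, ]))
  ), class = "conditional_detection")
}

#' @export
print.conditional_detection <- function(x, ...) {
  cat("<conditional_detection> ", x$geneB, " given ", x$geneA, " (",
      x$subset, ")\n", sep = "")
  print(x$table)
  cat(sprintf("P(%s+|%s+) = %.3f, P(%s+|%s-) = %.3f, OR = %s, p = %.3g\n",
              x$geneB, x$geneA, x$p_B_given_A, x$geneB, x$geneA,
              x$p_B_given_notA,
              if (x$or_defined) format(x$odds_ratio, digits = 3) else "NA",
              x$p_value))
  invisible(x)
}

#' @export
tidy.conditional_detection <- function(x, ...) {
  tibble(geneA = x$geneA, geneB = x$geneB, subset = x$subset,
         odds_ratio = x$odds_ratio, p_value = x$p_value,
         p_B_given_A = x$p_B_given_A, p_B_given_notA = x$p_B_given_notA)
}

#' Downsample every cell to a common depth
#'
#' Draws exactly `target_depth` UMIs per cell without replacement from the
#' cell's observed UMIs (a multivariate hypergeometric draw, realised by
#' sequential hypergeometric sampling over genes). Zero-proportion
#' statistics are only comparable at matched depth, so this is the
#' depth-bias correction used before comparing detection rates across
#' samples. Cells with fewer UMIs than the target are dropped and counted
#' in attribute `n_dropped_cells`.
#'
#' @param M A [count_matrix].
#' @param target_depth Desired per-cell total.
#' @param seed Integer seed.
#' @return A [count_matrix] whose column sums all equal `target_depth`.
#' @export
downsample_depth <- function(M, target_depth, seed = 1) {
  stopifnot(inherits(M, "count_matrix"))
  set.seed(seed)
  keep <- which(M$cells$depth >= target_depth)
  n_dropped <- ncol(M$counts) - length(keep)
  counts <- as.matrix(M$counts[, keep, drop = FALSE])
  for (j in seq_along(keep)) {
    x <- counts[, j]
    total <- sum(x)
    if (total == target_depth) next
    want <- target_depth
    remaining <- total
    nz <- which(x > 0)
    for (g in nz) {
      draw <- rhyper(1, m = x[g], n = remaining - x[g], k = want)
      remaining <- remaining - x[g]
      want <- want - draw
      x[g] <- draw
      if (want == 0 && g != nz[length(nz)]) {
        x[nz[nz > g]] <- 0
        break
      }
    }
    counts[, j] <- x
  }
  out <- count_matrix(counts, M$cells[keep, , drop = FALSE])
  attr(out, "n_dropped_cells") <- n_dropped
  out
}

# mean zero probability across cells: the observable the rate model inverts
zero_mass <- function(r, s, family, theta) {
  mu <- s * r
  if (family == "poisson") mean(exp(-mu))
  else mean((theta / (theta + mu))^theta)
}

#' Infer a relative expression rate from the zero proportion
#'
#' Deterministic inversion of the zero-proportion observable: solves for
#' the relative rate `r` in
#' `p0_obs = mean over cells of P0(depth_c * r)`, with
#' `P0(mu) = exp(-mu)` (Poisson) or `(theta / (theta + mu))^theta`
#' (negative binomial). The right-hand side is strictly decreasing in `r`,
#' so a bracketed root search converges to relative tolerance 1e-8.
#' `p0_obs = 1` returns `r = 0`; `p0_obs = 0` returns `r = Inf` with a
#' boundary flag.
#'
#' @param M A [count_matrix].
#' @param gene Gene name.
#' @param cluster,genotype,cells Optional cell filters.
#' @param family `"poisson"` or `"nb"`.
#' @param theta NB dispersion; `NULL` for a method-of-moments estimate from
#'   the subset's counts.
#' @return A list of class `rate_model` with `rate`, `family`, `theta`,
#'   `p_zero`, `n_cells`, `boundary` flag.
#' @export
infer_rate <- function(M, gene, cluster = NULL, genotype = NULL,
                       cells = NULL, family = c("poisson", "nb"),
                       theta = NULL) {
  family <- match.arg(family)
  idx <- cell_index(M, cluster, genotype, cells)
  if (length(idx) == 0) abort("empty cell subset")
  x <- gene_counts(M, gene, idx)
  s <- M$cells$depth[idx]
  fit <- fit_rate(x, s, family, theta)
  structure(c(list(gene = gene, subset = subset_label(cluster, genotype)),
              fit), class = "rate_model")
}

fit_rate <- function(x, s, family, theta = NULL) {
  p0 <- mean(x == 0)
  if (family == "nb" && is.null(theta)) {
    m <- mean(x)
    v <- var(x)
    theta <- if (v > m) m^2 / (v - m) else 1e4
  }
  if (family == "poisson") theta <- NA_real_
  if (p0 >= 1) {
    return(list(rate = 0, family = family, theta = theta, p_zero = p0,
                n_cells = length(x), boundary = TRUE))
  }
  if (p0 <= 0) {
    return(list(rate = Inf, family = family, theta = theta, p_zero = p0,
                n_cells = length(x), boundary = TRUE))
  }
  g <- function(r) zero_mass(r, s, family, theta) - p0
  hi <- 1 / median(s)
  while (g(hi) > 0) hi <- hi * 2
  root <- uniroot(g, lower = 0, upper = hi, tol = 1e-12)$root
  # refine on the log scale to the documented relative tolerance
  if (root > 0) {
    root <- exp(uniroot(function(lr) g(exp(lr)),
                        lower = log(root) - 1, upper = log(root) + 1,
                        tol = 1e-9)$root)
  }
  list(rate = root, family = family, theta = theta, p_zero = p0,
       n_cells = length(x), boundary = FALSE)
}

#' @export
print.rate_model <- function(x, ...) {
  cat("<rate_model> ", x$gene, " (", x$subset, "): rate = ",
      signif(x$rate, 4), " per unit depth [", x$family,
      if (x$family == "nb") paste0(", theta = ", signif(x$theta, 3)),
      "], p0 = ", signif(x$p_zero, 4), ", n = ", x$n_cells, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.rate_model <- function(x, ...) {
  tibble(gene = x$gene, subset = x$subset, rate = x$rate,
         family = x$family, theta = x$theta, p_zero = x$p_zero,
         n_cells = x$n_cells, boundary = x$boundary)
}

#' @export
glance.rate_model <- function(x, ...) {
  tibble(rate = x$rate, p_zero = x$p_zero, n_cells = x$n_cells)
}

#' Fold change between genotypes from zero-proportion rates
#'
#' Point estimate `r2 / r1` of the relative rates inferred by
#' [infer_rate()] within one cluster, with a percentile bootstrap CI from
#' resampling cells independently within each genotype.
#'
#' @param M A [count_matrix].
#' @param gene Gene name.
#' @param cluster Cluster restriction (optional).
#' @param genotype1,genotype2 The two genotype labels; the fold change is
#'   genotype2 over genotype1.
#' @param family,theta Passed to the rate model.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param conf_level CI level.
#' @return A list of class `fold_change_estimate` with `fold_change`,
#'   `ci_lo`, `ci_hi`, the two `rate_model` fits, `n_boot`, `seed`.
#' @export
fold_change <- function(M, gene, cluster = NULL, genotype1, genotype2,
                        family = c("poisson", "nb"), theta = NULL,
                        n_boot = 1000, seed = 1, conf_level = 0.95) {
  family <- match.arg(family)
  i1 <- cell_index(M, cluster, genotype1)
  i2 <- cell_index(M, cluster, genotype2)
  if (length(i1) == 0 || length(i2) == 0) abort("empty genotype subset")
  x1 <- gene_counts(M, gene, i1)
  x2 <- gene_counts(M, gene, i2)
  s1 <- M$cells$depth[i1]
  s2 <- M$cells$depth[i2]
  fit1 <- fit_rate(x1, s1, family, theta)
  fit2 <- fit_rate(x2, s2, family, theta)
  point <- fit2$rate / fit1$rate
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(k) {
    b1 <- sample.int(length(x1), replace = TRUE)
    b2 <- sample.int(length(x2), replace = TRUE)
    r1 <- fit_rate(x1[b1], s1[b1], family, theta)$rate
    r2 <- fit_rate(x2[b2], s2[b2], family, theta)$rate
    r2 / r1
  }, numeric(1))
  alpha <- (1 - conf_level) / 2
  finite <- boots[is.finite(boots)]
  ci <- unname(quantile(finite, c(alpha, 1 - alpha), type = 7))
  structure(list(gene = gene, cluster = cluster,
                 genotype1 = genotype1, genotype2 = genotype2,
                 fold_change = point, ci_lo = ci[1], ci_hi = ci[2],
                 fit1 = fit1, fit2 = fit2, n_boot = n_boot, seed = seed),
            class = "fold_change_estimate")
}

#' @export
print.fold_change_estimate <- function(x, ...) {
  cat("<fold_change_estimate> ", x$gene,
      if (!is.null(x$cluster)) paste0(" [", x$cluster, "]"), ": ",
      x$genotype2, " / ", x$genotype1, " = ", signif(x$fold_change, 3),
      " (", signif(x$ci_lo, 3), " - ", signif(x$ci_hi, 3), ", ",
      x$n_boot, " bootstraps)\n", sep = "")
  invisible(x)
}

#' @export
tidy.fold_change_estimate <- function(x, ...) {
  tibble(gene = x$gene,
         cluster = x$cluster %||% NA_character_,
         genotype1 = x$genotype1, genotype2 = x$genotype2,
         fold_change = x$fold_change, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
         rate1 = x$fit1$rate, rate2 = x$fit2$rate, n_boot = x$n_boot)
}

#' @export
glance.fold_change_estimate <- function(x, ...) {
  tibble(fold_change = x$fold_change, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
         covers_one = x$ci_lo <= 1 & 1 <= x$ci_hi)
}

#' Rank correlation of two genes with a bootstrap sign probability
#'
#' Spearman correlation of depth-normalised counts (`count / depth`) of two
#' genes across a cell subset, with a percentile bootstrap CI and
#' `p_opposite`: the fraction of bootstrap replicates whose correlation has
#' the opposite sign to the point estimate — a one-sided probability that
#' the reported correlation sign is wrong.
#'
#' @param M A [count_matrix].
#' @param geneA,geneB Gene names.
#' @param cluster,genotype,cells Optional cell filters (subset must hold at
#'   least 10 cells).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param conf_level CI level.
#' @return A list of class `correlation_report` with `rho`, `ci_lo`,
#'   `ci_hi`, `p_opposite`, `n_cells`.
#' @export
correlation_sign <- function(M, geneA, geneB, cluster = NULL,
                             genotype = NULL, cells = NULL, n_boot = 1000,
                             seed = 1, conf_level = 0.95) {
  idx <- cell_index(M, cluster, genotype, cells)
  if (length(idx) < 10) abort("subset must contain at least 10 cells")
  s <- M$cells$depth[idx]
  a <- gene_counts(M, geneA, idx) / s
  b <- gene_counts(M, geneB, idx) / s
  rho <- cor(a, b, method = "spearman")
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(k) {
    i <- sample.int(length(a), replace = TRUE)
    suppressWarnings(cor(a[i], b[i], method = "spearman"))
  }, numeric(1))
  boots <- boots[!is.na(boots)]
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha), type = 7))
  p_opp <- if (rho == 0) 0.5 else mean(sign(boots) == -sign(rho))
  structure(list(geneA = geneA, geneB = geneB,
                 subset = subset_label(cluster, genotype),
                 rho = rho, ci_lo = ci[1], ci_hi = ci[2],
                 p_opposite = p_opp, n_cells = length(idx),
                 n_boot = n_boot, seed = seed),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report> ", x$geneA, " vs ", x$geneB, " (", x$subset,
      "): rho = ", signif(x$rho, 3), " (", signif(x$ci_lo, 3), " - ",
      signif(x$ci_hi, 3), "), p(opposite sign) = ",
      signif(x$p_opposite, 3), ", n = ", x$n_cells, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.correlation_report <- function(x, ...) {
  tibble(geneA = x$geneA, geneB = x$geneB, subset = x$subset, rho = x$rho,
         ci_lo = x$ci_lo, ci_hi = x$ci_hi, p_opposite = x$p_opposite,
         n_cells = x$n_cells)
}
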