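#' Construct a binned contact matrix
#'
#' A thin container for a square symmetric matrix of contact counts on a
#' named, binned coordinate system. Signed matrices (differences between
#' genotypes) use the subclass `signed_contact_matrix`, for which entries
#' may be negative.
#'
#' @param mat Square numeric matrix (symmetric within tolerance).
#' @param bin_size Bin size in bp.
#' @param chrom Chromosome name.
#' @param coord_system Coordinate-system id, e.g. `"wildtype"` or
#'   `"mutant:inv2"`.
#' @param offset bp position of the left edge of the first bin.
#' @param signed Allow negative entries (difference maps).
#' @return An object of class `contact_matrix` (and `signed_contact_matrix`
#'   when `signed = TRUE`).
#' @export
contact_matrix <- function(mat, bin_size, chrom = "chrS",
                           coord_system = "wildtype", offset = 0,
                           signed = FALSE) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > 1e-9 * max(1, max(abs(mat)))) {
    abort("contact matrix must be symmetric")
  }
  if (!signed && any(mat < 0)) abort("contact counts must be non-negative")
  structure(list(mat = mat, bin_size = bin_size, chrom = chrom,
                 coord_system = coord_system, offset = offset),
            class = c(if (signed) "signed_contact_matrix", "contact_matrix"))
}

n_bins <- function(m) nrow(m$mat)

bin_starts <- function(m) m$offset + (seq_len(n_bins(m)) - 1) * m$bin_size

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<", class(x)[1], "> ", x$chrom, " [", x$coord_system, "], ",
      n_bins(x), " bins of ", x$bin_size, " bp, total ",
      signif(sum(x$mat), 6), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.contact_matrix <- function(x, ...) {
  starts <- bin_starts(x)
  idx <- which(upper.tri(x$mat, diag = TRUE), arr.ind = TRUE)
  tibble(bin1_start = starts[idx[, 1]], bin2_start = starts[idx[, 2]],
         count = x$mat[idx])
}

# bins (left-closed) overlapped by a 0-based half-open bp interval
interval_to_bins <- function(m, interval) {
  starts <- bin_starts(m)
  which(starts < interval[2] & starts + m$bin_size > interval[1])
}

#' Simulate a contact matrix with distance decay and boundary insulation
#'
#' Generates contacts under a power-law distance decay attenuated by
#' insulation boundaries: the expected count between bins `i` and `j` is
#' `C * (|i - j| + 1)^(-alpha)` times the product of the insulation factors
#' `f_b` of every boundary strictly between the two bins (the `+ 1` keeps
#' the diagonal finite). Boundaries are the internal domain edges of the
#' supplied partition. With `noise = "poisson"` each upper-triangle entry is
#' Poisson-sampled and mirrored; with `noise = "none"` the closed-form
#' expectation is returned.
#'
#' @param partition A [domain_partition][predict_partition] whose span tiles
#'   the binned axis exactly.
#' @param params A [contact_model_params] object.
#' @param n_bins Number of bins.
#' @param bin_size Bin size in bp.
#' @param seed Integer seed (used only when noise is Poisson).
#' @return A [contact_matrix].
#' @export
simulate_contact_matrix <- function(partition, params, n_bins, bin_size,
                                    seed = 1) {
  stopifnot(inherits(partition, "domain_partition"))
  span <- partition$span
  if (!isTRUE(all.equal(span[2] - span[1], n_bins * bin_size))) {
    abort("partition span does not tile the binned axis")
  }
  boundaries <- partition$boundaries$midpoint
  mat <- contact_expectation(n_bins, bin_size, span[1], boundaries, params)
  if (params$noise == "poisson") {
    set.seed(seed)
    up <- upper.tri(mat, diag = TRUE)
    mat[up] <- rpois(sum(up), mat[up])
    mat[lower.tri(mat)] <- t(mat)[lower.tri(mat)]
  }
  contact_matrix(mat, bin_size, chrom = partition$chrom,
                 coord_system = partition$coord_system, offset = span[1])
}

# closed-form expectation; exported through simulate_contact_matrix(noise =
# "none") and reused by tests as the oracle surface
contact_expectation <- function(n_bins, bin_size, offset, boundaries,
                                params) {
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  mat <- params$C * (d + 1)^(-params$alpha)
  if (length(boundaries) > 0) {
    f <- rep_len(params$f_b, length(boundaries))
    # boundary at bp position p separates bins across edge index k
    edges <- round((boundaries - offset) / bin_size)
    keep <- edges > 0 & edges < n_bins
    edges <- edges[keep]
    f <- f[keep]
    # cumulative log-attenuation per bin: product over boundaries between
    logf_at_bin <- vapply(seq_len(n_bins), function(i) {
      sum(log(f[edges <= i - 1]))
    }, numeric(1))
    mat <- mat * exp(-abs(outer(logf_at_bin, logf_at_bin, "-")))
  }
  mat
}

#' Parameters of the generative contact model
#'
#' @param C Expected count at distance 0 (one-bin separation convention).
#' @param alpha Distance-decay exponent (> 0).
#' @param f_b Per-boundary insulation factor(s) in (0, 1]; recycled over
#'   boundaries.
#' @param noise `"none"` for the closed form, `"poisson"` for sampled counts.
#' @return An object of class `contact_model_params`.
#' @export
contact_model_params <- function(C = 100, alpha = 1, f_b = 0.4,
                                 noise = c("none", "poisson")) {
  noise <- match.arg(noise)
  stopifnot(C > 0, alpha > 0, all(f_b > 0 & f_b <= 1))
  structure(list(C = C, alpha = alpha, f_b = f_b, noise = noise),
            class = "contact_model_params")
}

#' Scale a contact matrix to a target total
#'
#' Multiplies all entries by a constant so the matrix total equals
#' `target_sum`. Relative entry ratios and symmetry are preserved; the
#' operation is idempotent at a fixed target.
#'
#' @param A A [contact_matrix].
#' @param target_sum Desired total count mass.
#' @return A [contact_matrix].
#' @export
normalize_total <- function(A, target_sum = 1e6) {
  stopifnot(inherits(A, "contact_matrix"))
  s <- sum(A$mat)
  if (s <= 0) abort("cannot normalize a matrix with non-positive total")
  A$mat <- A$mat * (target_sum / s)
  A
}

#' Remap a mutant contact matrix onto wild-type coordinates
#'
#' Each mutant bin is assigned to the wild-type bin containing the lift of
#' its midpoint, and entry mass is moved accordingly — the standard trick
#' for displaying mutant-genome contacts on the reference chromosome. Bins
#' whose midpoints lift into deleted regions are dropped and their mass
#' reported in the `dropped_mass` attribute. When the bin mapping is a
#' bijection (e.g. an inversion with breakpoints on bin edges) total mass is
#' conserved exactly.
#'
#' @param M A [contact_matrix] on the mutant coordinate system.
#' @param map The [segment_map][compile_rearrangement] from wild type to
#'   that mutant.
#' @return A [contact_matrix] on the wild-type system, covering
#'   `[0, wt_length)`, with attribute `dropped_mass`.
#' @export
remap_to_reference <- function(M, map) {
  stopifnot(inherits(M, "contact_matrix"), inherits(map, "segment_map"))
  if (map$mut_length %% M$bin_size != 0 && map$wt_length %% M$bin_size != 0) {
    warn("chromosome lengths are not multiples of the bin size")
  }
  mid <- bin_starts(M) + M$bin_size / 2
  hits <- lift_position(map, floor(mid), direction = "mut_to_wt")
  target <- rep(NA_integer_, n_bins(M))
  target[match(hits$source, floor(mid))] <-
    floor(hits$position / M$bin_size) + 1
  n_out <- ceiling(map$wt_length / M$bin_size)
  keep <- which(!is.na(target))
  # assignment matrix: out = Z M Z'; collisions accumulate, drops lose mass
  Z <- matrix(0, n_out, n_bins(M))
  Z[cbind(target[keep], keep)] <- 1
  out <- Z %*% M$mat %*% t(Z)
  res <- contact_matrix(out, M$bin_size, chrom = map$chrom,
                        coord_system = "wildtype", offset = 0,
                        signed = inherits(M, "signed_contact_matrix"))
  attr(res, "dropped_mass") <- sum(M$mat) - sum(M$mat[keep, keep])
  res
}

#' Subtract two contact matrices after equal-total normalization
#'
#' Computes `normalize_total(A) - normalize_total(B)`, the signed difference
#' map used to visualise genotype-specific contact gains and losses. Both
#' matrices must already live on the same coordinate system (remap first).
#'
#' @param A,B [contact_matrix] objects of identical shape and system.
#' @param target_sum Total both matrices are scaled to before subtraction.
#' @return A `signed_contact_matrix`; positive entries are contacts more
#'   frequent in `A`.
#' @export
subtract_contacts <- function(A, B, target_sum = 1e6) {
  stopifnot(inherits(A, "contact_matrix"), inherits(B, "contact_matrix"))
  if (n_bins(A) != n_bins(B) || A$bin_size != B$bin_size) {
    abort("matrices have different shapes or bin sizes")
  }
  if (!identical(A$coord_system, B$coord_system)) {
    abort("matrices are on different coordinate systems; remap first")
  }
  S <- normalize_total(A, target_sum)$mat - normalize_total(B, target_sum)$mat
  out <- contact_matrix(S, A$bin_size, chrom = A$chrom,
                        coord_system = A$coord_system, offset = A$offset,
                        signed = TRUE)
  attr(out, "provenance") <- list(sum_A = sum(A$mat), sum_B = sum(B$mat),
                                  target_sum = target_sum)
  out
}

#' Diamond insulation score
#'
#' For each bin `i`, averages the contacts in the `w x w` diamond spanning
#' the bin: entries `(a, b)` with `i - w <= a < i <= b < i + w` (0-based bin
#' indices). Bins within `w` of either edge are masked (`NA`), not zeroed.
#' Low scores mark insulation boundaries.
#'
#' @param M A [contact_matrix].
#' @param window_w Diamond half-width in bins (>= 1).
#' @return A tibble of class `insulation_profile` with columns `bin`
#'   (1-based index), `start` (bp) and `score` (`NA` where masked).
#' @export
insulation_profile <- function(M, window_w = 5) {
  stopifnot(inherits(M, "contact_matrix"), window_w >= 1)
  n <- n_bins(M)
  if (2 * window_w > n) abort("window is larger than the matrix")
  score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- (i - window_w):(i - 1)
    b <- i:(i + window_w - 1)
    if (min(a) < 1 || max(b) > n) next
    score[i] <- mean(M$mat[a, b, drop = FALSE])
  }
  structure(
    tibble(bin = seq_len(n), start = bin_starts(M), score = score),
    class = c("insulation_profile", class(tibble())),
    bin_size = M$bin_size, chrom = M$chrom
  )
}

#' Call boundary bins from an insulation profile
#'
#' Finds local minima of the insulation score whose prominence (height of
#' the lower of the two enclosing walls above the minimum) reaches
#' `min_prominence`.
#'
#' @param profile An [insulation_profile].
#' @param min_prominence Minimum prominence, in score units.
#' @return Integer vector of boundary bin indices (1-based).
#' @export
call_boundary_bins <- function(profile, min_prominence = 0) {
  s <- profile$score
  ok <- which(!is.na(s))
  if (length(ok) < 3) return(integer())
  v <- s[ok]
  calls <- integer()
  for (k in 2:(length(v) - 1)) {
    if (!(v[k] < v[k - 1] && v[k] <= v[k + 1])) next
    left <- v[seq_len(k - 1)]
    right <- v[(k + 1):length(v)]
    lower_left <- which(left < v[k])
    wall_left <- if (length(lower_left) == 0) max(left)
    else max(left[(max(lower_left) + 1):(k - 1)])
    lower_right <- which(right < v[k])
    wall_right <- if (length(lower_right) == 0) max(right)
    else max(right[seq_len(min(lower_right) - 1)])
    if (min(wall_left, wall_right) - v[k] >= min_prominence) {
      calls <- c(calls, ok[k])
    }
  }
  calls
}

#' Virtual 4C profile of a viewpoint
#'
#' Extracts the mean contact profile of a viewpoint interval against all
#' bins: `profile(j)` is the mean over viewpoint bins `i` of `M[i, j]`.
#' Viewpoint bins are masked (`NA`) in the output.
#'
#' @param M A [contact_matrix].
#' @param viewpoint 0-based half-open bp interval `c(start, end)`.
#' @return A tibble with columns `bin`, `start`, `signal`.
#' @export
virtual_4c <- function(M, viewpoint) {
  vp <- interval_to_bins(M, viewpoint)
  if (length(vp) == 0) abort("viewpoint overlaps no bin")
  signal <- colMeans(M$mat[vp, , drop = FALSE])
  signal[vp] <- NA_real_
  tibble(bin = seq_len(n_bins(M)), start = bin_starts(M), signal = signal)
}

#' Contact gain of a viewpoint within a target region
#'
#' Sums a signed difference map over all (viewpoint bin, target bin) pairs
#' and attaches a percentile bootstrap confidence interval obtained by
#' resampling target bins. A positive score with a CI excluding zero is
#' evidence that the viewpoint gained contacts within the target region in
#' the first operand of the subtraction.
#'
#' @param S A [signed_contact_matrix][subtract_contacts].
#' @param viewpoint,target_region 0-based half-open bp intervals on `S`'s
#'   coordinate system.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param conf_level CI level.
#' @return A tibble of class `region_gain` with `score`, `ci_lo`, `ci_hi`,
#'   `n_viewpoint_bins`, `n_target_bins`, `n_boot`.
#' @export
region_gain <- function(S, viewpoint, target_region, n_boot = 1000,
                        seed = 1, conf_level = 0.95) {
  stopifnot(inherits(S, "signed_contact_matrix"))
  vp <- interval_to_bins(S, viewpoint)
  tg <- interval_to_bins(S, target_region)
  if (length(vp) == 0 || length(tg) == 0) {
    abort("viewpoint/target overlaps no bin")
  }
  per_target <- colSums(S$mat[vp, tg, drop = FALSE])
  score <- sum(per_target)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(k) {
    sum(sample(per_target, length(per_target), replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha), type = 7))
  structure(
    tibble(score = score, ci_lo = ci[1], ci_hi = ci[2],
           n_viewpoint_bins = length(vp), n_target_bins = length(tg),
           n_boot = n_boot),
    class = c("region_gain", class(tibble())))
}
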