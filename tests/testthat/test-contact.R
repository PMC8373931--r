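# a small one-boundary partition used throughout: 60 bins of 1 kb with a
# boundary planted at 30 kb
one_boundary_partition <- function(f_pos = 30000, span = c(0, 60000)) {
  sites <- tibble::tibble(position = c(f_pos - 500, f_pos + 499),
                          orientation = c("+", "-"), weight = 1)
  predict_partition(cluster_ctcf(sites, max_gap = 2000), span = span)
}

test_that("noise-free simulation equals the closed form entrywise", {
  part <- one_boundary_partition()
  params <- contact_model_params(C = 50, alpha = 1.2, f_b = 0.3)
  M <- simulate_contact_matrix(part, params, n_bins = 60, bin_size = 1000)
  oracle <- closed_form_contact(60, 1000, 0, part$boundaries$midpoint,
                                0.3, 50, 1.2)
  expect_equal(M$mat, oracle, tolerance = 1e-12)
  # no boundaries: pure power law
  flat <- predict_partition(cluster_ctcf(tibble::tibble(
    position = double(), orientation = character()
  ), 100), c(0, 60000))
  M0 <- simulate_contact_matrix(flat, params, 60, 1000)
  d <- abs(outer(1:60, 1:60, "-"))
  expect_equal(M0$mat, 50 * (d + 1)^(-1.2), tolerance = 1e-12)
})

test_that("Poisson noise respects the seeding contract", {
  part <- one_boundary_partition()
  params <- contact_model_params(C = 100, alpha = 1, f_b = 0.2,
                                 noise = "poisson")
  a <- simulate_contact_matrix(part, params, 60, 1000, seed = 11)
  b <- simulate_contact_matrix(part, params, 60, 1000, seed = 11)
  c <- simulate_contact_matrix(part, params, 60, 1000, seed = 12)
  expect_identical(a$mat, b$mat)
  expect_false(identical(a$mat, c$mat))
  expect_equal(a$mat, t(a$mat))
})

test_that("a mismatched partition is rejected", {
  part <- one_boundary_partition()
  expect_error(
    simulate_contact_matrix(part, contact_model_params(), 50, 1000),
    "tile"
  )
})

test_that("insulation profile equals brute-force diamond means", {
  part <- one_boundary_partition()
  params <- contact_model_params(C = 50, alpha = 1, f_b = 0.2)
  M <- simulate_contact_matrix(part, params, 60, 1000)
  prof <- insulation_profile(M, window_w = 5)
  expect_equal(prof$score, brute_diamond_means(M$mat, 5))
  # masked within w of the edges
  expect_true(all(is.na(prof$score[c(1:5, 57:60)])))
  # minimum at the first bin right of the planted boundary edge
  expect_equal(prof$bin[which.min(prof$score)], 31)
  expect_equal(call_boundary_bins(prof, min_prominence = 1), 31L)
  expect_error(insulation_profile(M, window_w = 40), "larger")
})

test_that("constant matrices have flat profiles and no boundaries", {
  M <- contact_matrix(matrix(3, 30, 30), 1000)
  prof <- insulation_profile(M, 4)
  expect_equal(unique(prof$score[!is.na(prof$score)]), 3)
  expect_length(call_boundary_bins(prof, min_prominence = 0.01), 0)
})

test_that("profiles are invariant to total-count rescaling up to a factor", {
  part <- one_boundary_partition()
  M <- simulate_contact_matrix(part, contact_model_params(), 60, 1000)
  M2 <- normalize_total(M, 5 * sum(M$mat))
  p1 <- insulation_profile(M, 5)$score
  p2 <- insulation_profile(M2, 5)$score
  expect_equal(p2, 5 * p1)
})

test_that("normalization scales totals and is idempotent", {
  M <- contact_matrix(matrix(c(4, 2, 2, 2), 2), 1000)
  N <- normalize_total(M, 100)
  expect_equal(sum(N$mat), 100)
  expect_equal(N$mat / sum(N$mat), M$mat / sum(M$mat))
  expect_equal(normalize_total(N, 100)$mat, N$mat)
})

test_that("subtraction is zero on identical inputs and antisymmetric", {
  part <- one_boundary_partition()
  A <- simulate_contact_matrix(part, contact_model_params(
    C = 100, alpha = 1, f_b = 0.3, noise = "poisson"), 60, 1000, seed = 1)
  B <- simulate_contact_matrix(part, contact_model_params(
    C = 80, alpha = 1, f_b = 0.6, noise = "poisson"), 60, 1000, seed = 2)
  expect_true(all(subtract_contacts(A, A)$mat == 0))
  S1 <- subtract_contacts(A, B)
  S2 <- subtract_contacts(B, A)
  expect_equal(S1$mat, -S2$mat)
  expect_s3_class(S1, "signed_contact_matrix")
  B_other <- B
  B_other$coord_system <- "mutant:x"
  expect_error(subtract_contacts(A, B_other), "coordinate")
})

test_that("bin-aligned inversion remap is a mass-conserving permutation", {
  locus <- make_toy_hoxd_locus()
  map <- toy_rearrangement(locus, "inv2") # breakpoints on 1 kb bin edges
  inv2 <- model_allele(locus, "inv2")
  M <- simulate_contact_matrix(
    inv2$partition, contact_model_params(C = 60, alpha = 1, f_b = 0.3,
                                         noise = "poisson"),
    n_bins = 400, bin_size = 1000, seed = 5
  )
  R <- remap_to_reference(M, map)
  expect_equal(sum(R$mat), sum(M$mat)) # exact conservation
  expect_equal(attr(R, "dropped_mass"), 0)
  expect_equal(sort(as.vector(R$mat)), sort(as.vector(M$mat)))

  # permutation oracle from lifting bin midpoints
  mid <- (seq_len(400) - 1) * 1000 + 500
  perm <- lift_position(map, mid, direction = "mut_to_wt")$position %/%
    1000 + 1
  expect_equal(R$mat[perm, perm], M$mat, ignore_attr = TRUE)

  # involution: remapping back through the inverse map recovers the input
  back <- remap_to_reference(R, invert_map(map))
  expect_equal(back$mat, M$mat, ignore_attr = TRUE)

  # identity map leaves the matrix unchanged
  id_map <- compile_rearrangement(
    rearrangement_spec(locus$chrom, op_inversion(0, 1)[0, ]), locus$length
  )
  wt <- model_allele(locus, "wildtype")
  W <- simulate_contact_matrix(wt$partition, contact_model_params(),
                               400, 1000)
  expect_equal(remap_to_reference(W, id_map)$mat, W$mat,
               ignore_attr = TRUE)
})

test_that("virtual 4C extracts rows and drops across boundaries by f_b", {
  part <- one_boundary_partition()
  params <- contact_model_params(C = 50, alpha = 1, f_b = 0.2)
  M <- simulate_contact_matrix(part, params, 60, 1000)
  one <- virtual_4c(M, c(10000, 11000)) # single-bin viewpoint = row 11
  row <- M$mat[11, ]
  row[11] <- NA
  expect_equal(one$signal, row)
  # crossing the boundary divides the expected signal by f_b, beyond the
  # distance decay: compare bins equidistant from the viewpoint
  near <- one$signal[30] # same side, bin distance 19 (d + 1 = 20)
  far <- one$signal[32] # across the boundary, bin distance 21 (d + 1 = 22)
  expect_equal(far / (50 * 22^-1), 0.2, tolerance = 1e-9)
  expect_equal(near / (50 * 20^-1), 1, tolerance = 1e-9)
})

test_that("region gain is zero on null input and detects planted gains", {
  part <- one_boundary_partition()
  M <- simulate_contact_matrix(part, contact_model_params(), 60, 1000)
  Z <- subtract_contacts(M, M)
  g0 <- region_gain(Z, c(10000, 11000), c(40000, 50000), n_boot = 100,
                    seed = 1)
  expect_equal(g0$score, 0)
  expect_equal(c(g0$ci_lo, g0$ci_hi), c(0, 0))

  # viewpoint row sums equalized by normalization: whole-axis gain ~ 0 for
  # an unstructured (single-domain, equal-parameter) pair
  flat <- predict_partition(cluster_ctcf(tibble::tibble(
    position = double(), orientation = character()), 100), c(0, 60000))
  A <- simulate_contact_matrix(flat, contact_model_params(), 60, 1000)
  S <- subtract_contacts(normalize_total(A, 1e6), normalize_total(A, 2e6))
  gg <- region_gain(S, c(10000, 11000), c(0, 60000), n_boot = 50, seed = 1)
  expect_equal(gg$score, 0, tolerance = 1e-9)
})

test_that("contact matrices survive a TSV round trip byte-identically", {
  part <- one_boundary_partition()
  M <- simulate_contact_matrix(part, contact_model_params(
    noise = "poisson"), 60, 1000, seed = 3)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_contact_tsv(M, f1)
  back <- read_contact_tsv(f1)
  expect_equal(back$mat, M$mat)
  expect_equal(back$bin_size, M$bin_size)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_contact_tsv(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})
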