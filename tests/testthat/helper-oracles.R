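# independent oracles and tiny fixture builders shared across test files

# quadratic all-pairs overlap count: rows of a with >= 1 bp overlap in b
brute_overlap_count <- function(a, b) {
  if (!"chrom" %in% names(a)) a$chrom <- "chrU"
  if (!"chrom" %in% names(b)) b$chrom <- "chrU"
  hits <- 0L
  for (i in seq_len(nrow(a))) {
    any_hit <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        any_hit <- TRUE
        break
      }
    }
    hits <- hits + any_hit
  }
  hits
}

# direct double-loop evaluation of the contact model expectation
closed_form_contact <- function(n_bins, bin_size, offset, boundaries, f_b,
                                C, alpha) {
  edges <- round((boundaries - offset) / bin_size)
  f <- rep_len(f_b, length(boundaries))
  mat <- matrix(0, n_bins, n_bins)
  for (i in seq_len(n_bins)) {
    for (j in seq_len(n_bins)) {
      between <- edges >= min(i, j) & edges <= max(i, j) - 1
      mat[i, j] <- C * (abs(i - j) + 1)^(-alpha) * prod(f[between])
    }
  }
  mat
}

# diamond means computed directly from a matrix (insulation oracle)
brute_diamond_means <- function(mat, w) {
  n <- nrow(mat)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- (i - w):(i - 1)
    b <- i:(i + w - 1)
    if (min(a) >= 1 && max(b) <= n) out[i] <- mean(mat[a, b])
  }
  out
}

# random non-overlapping rearrangement spec on a chromosome of length len
random_rearrangement <- function(len, n_ops = sample(1:3, 1)) {
  cuts <- sort(sample(0:len, 2 * n_ops))
  ops <- list()
  for (k in seq_len(n_ops)) {
    s <- cuts[2 * k - 1]
    e <- cuts[2 * k]
    if (e <= s) next
    type <- sample(c("inversion", "deletion", "duplication"), 1)
    ops[[length(ops) + 1]] <- switch(type,
      inversion = op_inversion(s, e),
      deletion = op_deletion(s, e),
      duplication = op_duplication(s, e, insert_after = e,
                                   inverted = sample(c(TRUE, FALSE), 1))
    )
  }
  if (length(ops) == 0) ops <- list(op_inversion(0, len))
  rearrangement_spec("chrT", dplyr::bind_rows(ops))
}

# track a uniquely marked base through build_mutant_sequence: the stated
# independent oracle for lift_position
marker_hits <- function(map, p) {
  s <- strrep("A", map$wt_length)
  substr(s, p + 1, p + 1) <- "C"
  mut <- build_mutant_sequence(s, map)
  chars <- strsplit(mut, "")[[1]]
  tibble::tibble(
    position = which(chars %in% c("C", "G")) - 1,
    orientation = as.character(ifelse(chars[chars %in% c("C", "G")] == "C",
                                      "same", "flipped"))
  )
}

# uniform random peak tibble (possibly self-overlapping)
random_peaks <- function(n, genome_length = 10000, width_max = 300) {
  start <- floor(runif(n, 0, genome_length - width_max))
  tibble::tibble(chrom = "chrU", start = start,
                 end = start + sample(width_max, n, replace = TRUE))
}
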