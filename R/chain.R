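#' Export a segment map as UCSC chain records
#'
#' Writes one chain per colinear run of blocks: consecutive same-orientation
#' blocks whose wild-type intervals increase (gaps, i.e. deletions, become
#' `dt` entries) are merged into one chain; each flipped block becomes its
#' own chain on the `-` strand of the target-genome query, with query
#' coordinates counted from the reversed strand as the chain format
#' requires. The reference (chain "target") is the wild-type axis and the
#' chain "query" is the mutant axis, so the records drive a wild-type to
#' mutant liftover.
#'
#' @param map A [segment_map][compile_rearrangement].
#' @param query_name Sequence name used for the mutant axis; defaults to
#'   `<chrom>_mut`.
#' @return A character scalar holding the chain-format text.
#' @seealso [read_chain()] for the inverse operation.
#' @export
write_chain <- function(map, query_name = paste0(map$chrom, "_mut")) {
  stopifnot(inherits(map, "segment_map"))
  b <- map$blocks
  # group blocks into colinear runs on the mutant axis
  run_id <- integer(nrow(b))
  current <- 1L
  for (i in seq_len(nrow(b))) {
    if (i == 1) {
      run_id[i] <- current
      next
    }
    colinear <- b$strand[i] == "+" && b$strand[i - 1] == "+" &&
      b$wt_start[i] >= b$wt_end[i - 1]
    if (!colinear) current <- current + 1L
    run_id[i] <- current
  }
  chains <- character()
  for (r in unique(run_id)) {
    rb <- b[run_id == r, , drop = FALSE]
    strand <- rb$strand[1]
    score <- sum(rb$wt_end - rb$wt_start)
    if (strand == "+") {
      header <- paste("chain", score, map$chrom, map$wt_length, "+",
                      rb$wt_start[1], rb$wt_end[nrow(rb)],
                      query_name, map$mut_length, "+",
                      rb$mut_start[1], rb$mut_end[nrow(rb)], r)
      sizes <- rb$wt_end - rb$wt_start
      dt <- c(rb$wt_start[-1] - rb$wt_end[-nrow(rb)], NA)
      dq <- c(rb$mut_start[-1] - rb$mut_end[-nrow(rb)], NA)
      body <- c(
        if (nrow(rb) > 1) {
          paste(sizes[-nrow(rb)], dt[-nrow(rb)], dq[-nrow(rb)])
        },
        as.character(sizes[nrow(rb)])
      )
    } else {
      stopifnot(nrow(rb) == 1)
      header <- paste("chain", score, map$chrom, map$wt_length, "+",
                      rb$wt_start, rb$wt_end,
                      query_name, map$mut_length, "-",
                      map$mut_length - rb$mut_end,
                      map$mut_length - rb$mut_start, r)
      body <- as.character(rb$wt_end - rb$wt_start)
    }
    chains <- c(chains, header, body, "")
  }
  paste0(paste(chains, collapse = "\n"), "\n")
}

#' Parse chain text back into a segment map
#'
#' Reads UCSC chain records written by [write_chain()] (wild-type target,
#' mutant query) and reconstructs an equivalent [segment_map]: blocks from
#' the alignment lines, deletions from wild-type intervals covered by no
#' block, duplications from wild-type intervals covered more than once.
#'
#' @param text Chain-format text (a single string or character vector of
#'   lines).
#' @return A `segment_map`.
#' @export
read_chain <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]]
  else text
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^chain\\b", lines)
  stopifnot(length(headers) > 0)
  bounds <- c(headers, length(lines) + 1L)
  blocks <- list()
  chrom <- NULL
  wt_length <- NULL
  mut_length <- NULL
  for (h in seq_along(headers)) {
    fields <- strsplit(lines[headers[h]], "\\s+")[[1]]
    chrom <- fields[3]
    wt_length <- as.numeric(fields[4])
    t_start <- as.numeric(fields[6])
    mut_length <- as.numeric(fields[9])
    q_strand <- fields[10]
    q_start <- as.numeric(fields[11])
    body <- lines[(headers[h] + 1):(bounds[h + 1] - 1)]
    t_pos <- t_start
    q_pos <- q_start
    for (line in body) {
      nums <- as.numeric(strsplit(trimws(line), "\\s+")[[1]])
      size <- nums[1]
      if (q_strand == "+") {
        mut_start <- q_pos
        mut_end <- q_pos + size
        strand <- "+"
      } else {
        mut_start <- mut_length - (q_pos + size)
        mut_end <- mut_length - q_pos
        strand <- "-"
      }
      blocks[[length(blocks) + 1]] <- tibble(
        wt_start = t_pos, wt_end = t_pos + size,
        mut_start = mut_start, mut_end = mut_end, strand = strand
      )
      t_pos <- t_pos + size + if (length(nums) >= 2) nums[2] else 0
      q_pos <- q_pos + size + if (length(nums) >= 3) nums[3] else 0
    }
  }
  blocks <- arrange(list_rbind(blocks), .data$mut_start)

  # wild-type coverage: gaps are deletions, double coverage is duplication
  ir <- IRanges::IRanges(start = blocks$wt_start + 1, end = blocks$wt_end)
  cov <- IRanges::coverage(ir, width = wt_length)
  zero <- IRanges::slice(cov, lower = 0, upper = 0, rangesOnly = TRUE)
  multi <- IRanges::slice(cov, lower = 2, rangesOnly = TRUE)
  map <- structure(list(
    chrom = chrom,
    blocks = blocks,
    deleted = tibble(start = IRanges::start(zero) - 1,
                     end = IRanges::end(zero)),
    duplicated = tibble(start = IRanges::start(multi) - 1,
                        end = IRanges::end(multi)),
    wt_length = wt_length,
    mut_length = mut_length
  ), class = "segment_map")
  validate_segment_map(map)
  map
}
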