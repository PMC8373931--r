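#' Describe a chromosomal rearrangement
#'
#' A rearrangement specification is an ordered set of operations
#' (inversions, deletions, duplications) on one wild-type chromosome. The
#' operations must occupy disjoint wild-type intervals; nested or overlapping
#' rearrangements are rejected at compile time.
#'
#' @param chrom Chromosome name.
#' @param operations A data frame with columns `op`
#'   (`"inversion"`, `"deletion"` or `"duplication"`), `start`, `end`, and for
#'   duplications `insert_after` (wild-type position after which the extra
#'   copy is inserted) and `inverted` (logical). Usually built by binding
#'   [op_inversion()], [op_deletion()], [op_duplication()] rows.
#' @param convention Coordinate convention of `start`/`end`:
#'   `"bed"` (default) for 0-based half-open intervals, or `"paper"` for
#'   1-based printed breakpoint coordinates such as
#'   `chr2: 74477755-75441001`, interpreted as the two positions flanking the
#'   rearranged segment so that the segment is `[start - 1, end - 1)` in
#'   0-based coordinates and its length is `end - start`.
#' @return An object of class `rearrangement_spec`.
#' @examples
#' inv2_like <- rearrangement_spec(
#'   "chr2", op_inversion(74477755, 75441001), convention = "paper"
#' )
#' @export
rearrangement_spec <- function(chrom, operations,
                               convention = c("bed", "paper")) {
  convention <- match.arg(convention)
  ops <- as_tibble(operations)
  check_features(ops, need = c("op", "start", "end"))
  if (!all(ops$op %in% c("inversion", "deletion", "duplication"))) {
    abort("operations must be inversion, deletion or duplication")
  }
  if (!"insert_after" %in% names(ops)) ops$insert_after <- NA_real_
  if (!"inverted" %in% names(ops)) ops$inverted <- FALSE
  if (convention == "paper") {
    ops$start <- ops$start - 1
    ops$end <- ops$end - 1
    ops$insert_after <- ifelse(is.na(ops$insert_after), NA_real_,
                               ops$insert_after - 1)
  }
  if (any(ops$start >= ops$end)) abort("operation start must be < end")
  structure(list(chrom = chrom, operations = ops), class = "rearrangement_spec")
}

#' @rdname rearrangement_spec
#' @param start,end Operation interval (interpreted per `convention`).
#' @export
op_inversion <- function(start, end) {
  tibble(op = "inversion", start = start, end = end,
         insert_after = NA_real_, inverted = FALSE)
}

#' @rdname rearrangement_spec
#' @export
op_deletion <- function(start, end) {
  tibble(op = "deletion", start = start, end = end,
         insert_after = NA_real_, inverted = FALSE)
}

#' @rdname rearrangement_spec
#' @param insert_after Wild-type position after which the extra copy lands.
#'   Defaults to `end` (tandem duplication).
#' @param inverted Should the extra copy be reverse-complemented?
#' @export
op_duplication <- function(start, end, insert_after = end, inverted = FALSE) {
  tibble(op = "duplication", start = start, end = end,
         insert_after = insert_after, inverted = inverted)
}

#' @export
print.rearrangement_spec <- function(x, ...) {
  cat("<rearrangement_spec> ", x$chrom, ", ",
      nrow(x$operations), " operation(s)\n", sep = "")
  print(x$operations)
  invisible(x)
}

#' Compile a rearrangement into a segment map
#'
#' Turns a [rearrangement_spec] into a block-wise correspondence between the
#' wild-type and mutant coordinate axes. Each block carries a wild-type
#' interval, the mutant interval it maps to, and an orientation; the mutant
#' blocks tile `[0, mutant_length)` without gaps or overlaps. Deleted and
#' duplicated wild-type intervals are recorded alongside.
#'
#' @param spec A [rearrangement_spec].
#' @param chrom_length Wild-type chromosome length in bp.
#' @return An object of class `segment_map` with element `blocks` (a tibble
#'   with `wt_start`, `wt_end`, `mut_start`, `mut_end`, `strand`), `deleted`
#'   and `duplicated` interval tibbles, and lengths for both axes.
#' @examples
#' map <- compile_rearrangement(
#'   rearrangement_spec("chr", op_inversion(10, 20)), 100
#' )
#' map$blocks
#' @export
compile_rearrangement <- function(spec, chrom_length) {
  stopifnot(inherits(spec, "rearrangement_spec"))
  ops <- arrange(spec$operations, .data$start)
  if (any(ops$start < 0 | ops$end > chrom_length)) {
    abort("operation coordinates out of chromosome bounds")
  }
  if (nrow(ops) > 1 && any(ops$start[-1] < ops$end[-nrow(ops)])) {
    abort("operations overlap on the wild-type axis; nesting is unsupported")
  }
  ins <- ops$insert_after[ops$op == "duplication"]
  if (any(!is.na(ins) & (ins < 0 | ins > chrom_length))) {
    abort("duplication insert_after out of bounds")
  }
  for (p in ins) {
    inside <- ops$start < p & p < ops$end
    if (any(inside)) abort("insert_after may not fall inside an operation")
  }

  # segment the wild-type axis at every operation edge and insertion point
  cuts <- sort(unique(c(0, chrom_length, ops$start, ops$end,
                        ins[!is.na(ins)])))
  seg <- tibble(wt_start = head(cuts, -1), wt_end = tail(cuts, -1))

  # emit blocks in mutant order: walk wt segments, flipping/deleting as
  # instructed, and splice duplication copies in at their insertion points
  blocks <- list()
  emit <- function(ws, we, strand) {
    blocks[[length(blocks) + 1]] <<- tibble(
      wt_start = ws, wt_end = we, strand = strand
    )
  }
  emit_insertions_at <- function(p) {
    dups <- ops[ops$op == "duplication" & !is.na(ops$insert_after) &
                  ops$insert_after == p, , drop = FALSE]
    for (k in seq_len(nrow(dups))) {
      emit(dups$start[k], dups$end[k], if (dups$inverted[k]) "-" else "+")
    }
  }
  emit_insertions_at(0)
  for (i in seq_len(nrow(seg))) {
    ws <- seg$wt_start[i]
    we <- seg$wt_end[i]
    hit <- which(ops$start <= ws & we <= ops$end)
    if (length(hit) == 0) {
      emit(ws, we, "+")
    } else {
      op <- ops$op[hit[1]]
      if (op == "inversion") emit(ws, we, "-")
      if (op == "duplication") emit(ws, we, "+") # original copy stays
      # deletions emit nothing
    }
    emit_insertions_at(we)
  }
  blocks <- list_rbind(blocks)
  len <- blocks$wt_end - blocks$wt_start
  blocks$mut_end <- cumsum(len)
  blocks$mut_start <- blocks$mut_end - len
  blocks <- select(blocks, "wt_start", "wt_end", "mut_start", "mut_end",
                   "strand")

  map <- structure(list(
    chrom = spec$chrom,
    blocks = blocks,
    deleted = select(filter(ops, .data$op == "deletion"), "start", "end"),
    duplicated = select(filter(ops, .data$op == "duplication"),
                        "start", "end"),
    wt_length = chrom_length,
    mut_length = max(blocks$mut_end)
  ), class = "segment_map")
  validate_segment_map(map)
  map
}

validate_segment_map <- function(map) {
  b <- map$blocks
  stopifnot(
    all(b$wt_end - b$wt_start == b$mut_end - b$mut_start),
    all(b$mut_start == c(0, head(b$mut_end, -1))),
    max(b$mut_end) == map$mut_length
  )
  expected <- map$wt_length -
    sum(map$deleted$end - map$deleted$start) +
    sum(map$duplicated$end - map$duplicated$start)
  stopifnot(map$mut_length == expected)
  invisible(map)
}

#' @export
print.segment_map <- function(x, ...) {
  cat("<segment_map> ", x$chrom, ": wild type ", x$wt_length,
      " bp -> mutant ", x$mut_length, " bp, ",
      nrow(x$blocks), " block(s)\n", sep = "")
  print(x$blocks)
  invisible(x)
}

#' @export
tidy.segment_map <- function(x, ...) x$blocks

#' Build the mutant chromosome sequence
#'
#' Concatenates the wild-type substring of each segment-map block, reverse
#' complementing flipped blocks, to produce the rearranged chromosome exactly
#' as a breakpoint-aware genome reconstruction would.
#'
#' @param wt_sequence Wild-type chromosome sequence, a single character
#'   string or [Biostrings::DNAString].
#' @param map A [segment_map][compile_rearrangement].
#' @return A character string (or `DNAString` if one was supplied) of length
#'   `map$mut_length`.
#' @examples
#' map <- compile_rearrangement(
#'   rearrangement_spec("chr", op_inversion(2, 6)), 8
#' )
#' build_mutant_sequence("AACGTTAC", map)
#' @export
build_mutant_sequence <- function(wt_sequence, map) {
  stopifnot(inherits(map, "segment_map"))
  was_char <- is.character(wt_sequence)
  dna <- if (was_char) Biostrings::DNAString(wt_sequence) else wt_sequence
  if (length(dna) != map$wt_length) {
    abort("sequence length does not match the map's wild-type length")
  }
  # one reverse-complement of the whole chromosome, then plain substring
  # assembly: flipped block [ws, we) reads the revcomp at the mirrored slice
  fwd <- as.character(dna)
  rev <- as.character(Biostrings::reverseComplement(dna))
  L <- map$wt_length
  b <- map$blocks
  pieces <- character(nrow(b))
  for (i in seq_len(nrow(b))) {
    pieces[i] <- if (b$strand[i] == "+") {
      substr(fwd, b$wt_start[i] + 1, b$wt_end[i])
    } else {
      substr(rev, L - b$wt_end[i] + 1, L - b$wt_start[i])
    }
  }
  out <- paste(pieces, collapse = "")
  if (was_char) out else Biostrings::DNAString(out)
}

blocks_for_direction <- function(map, direction) {
  b <- map$blocks
  if (direction == "wt_to_mut") {
    tibble(src_start = b$wt_start, src_end = b$wt_end,
           dst_start = b$mut_start, dst_end = b$mut_end, strand = b$strand)
  } else {
    tibble(src_start = b$mut_start, src_end = b$mut_end,
           dst_start = b$wt_start, dst_end = b$wt_end, strand = b$strand)
  }
}

#' Lift a position between wild-type and mutant coordinates
#'
#' Maps a 0-based position through the segment map. Positions inside deleted
#' intervals return zero hits; positions inside duplicated intervals return
#' one hit per copy when lifting wild type to mutant. Flipped blocks use the
#' mirror formula `dst = dst_start + (src_end - 1 - position)`.
#'
#' @param map A [segment_map][compile_rearrangement].
#' @param position 0-based position(s) on the source axis.
#' @param direction `"wt_to_mut"` or `"mut_to_wt"`.
#' @return A tibble with columns `source`, `position`, `orientation`
#'   (`"same"`/`"flipped"`); zero rows for deleted positions.
#' @export
lift_position <- function(map, position,
                          direction = c("wt_to_mut", "mut_to_wt")) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "segment_map"))
  src_len <- if (direction == "wt_to_mut") map$wt_length else map$mut_length
  if (any(position < 0 | position >= src_len)) {
    abort("position out of bounds on the source axis")
  }
  b <- blocks_for_direction(map, direction)
  res <- map(position, function(p) {
    hit <- b[b$src_start <= p & p < b$src_end, , drop = FALSE]
    if (nrow(hit) == 0) {
      return(tibble(source = double(), position = double(),
                    orientation = character()))
    }
    out <- ifelse(hit$strand == "+",
                  hit$dst_start + (p - hit$src_start),
                  hit$dst_start + (hit$src_end - 1 - p))
    tibble(source = p, position = sort(out),
           orientation = ifelse(hit$strand[order(out)] == "+",
                                "same", "flipped"))
  })
  list_rbind(res)
}

flip_strand <- function(strand) {
  ifelse(strand == "+", "-", ifelse(strand == "-", "+", strand))
}

#' Lift BED-like features between coordinate systems
#'
#' Lifts a feature table through a segment map. Features wholly inside one
#' block are translated (and strand-flipped inside inverted blocks); features
#' crossing a block junction are either split into sub-features
#' (`span_policy = "split"`, suffixing names) or dropped and counted
#' (`span_policy = "drop"`). Features inside duplicated regions lift to one
#' feature per copy.
#'
#' @param map A [segment_map][compile_rearrangement].
#' @param features Tibble with `start`, `end` and optionally `name`,
#'   `strand`, plus any other columns (carried through).
#' @param direction `"wt_to_mut"` or `"mut_to_wt"`.
#' @param span_policy How to treat features crossing block junctions.
#' @return The lifted features, re-sorted on the target axis, with an
#'   attribute `report`: a list with `n_dropped`, `dropped_names` and
#'   `n_split`.
#' @export
lift_features <- function(map, features,
                          direction = c("wt_to_mut", "mut_to_wt"),
                          span_policy = c("split", "drop")) {
  direction <- match.arg(direction)
  span_policy <- match.arg(span_policy)
  check_features(features)
  features <- as_tibble(features)
  if (!"name" %in% names(features)) {
    features$name <- paste0("feature_", seq_len(nrow(features)))
  }
  if (!"strand" %in% names(features)) features$strand <- "*"
  b <- blocks_for_direction(map, direction)

  n_dropped <- 0L
  dropped_names <- character()
  n_split <- 0L
  out <- list()
  for (i in seq_len(nrow(features))) {
    f <- features[i, , drop = FALSE]
    hit <- b[b$src_start < f$end & f$start < b$src_end, , drop = FALSE]
    if (nrow(hit) == 0) {
      n_dropped <- n_dropped + 1L
      dropped_names <- c(dropped_names, f$name)
      next
    }
    contained <- hit[hit$src_start <= f$start & f$end <= hit$src_end, ,
                     drop = FALSE]
    if (nrow(contained) > 0) {
      pieces <- contained
      clip_start <- rep(f$start, nrow(pieces))
      clip_end <- rep(f$end, nrow(pieces))
      suffix <- rep("", nrow(pieces))
    } else {
      if (span_policy == "drop") {
        n_dropped <- n_dropped + 1L
        dropped_names <- c(dropped_names, f$name)
        next
      }
      n_split <- n_split + 1L
      pieces <- hit
      clip_start <- pmax(f$start, hit$src_start)
      clip_end <- pmin(f$end, hit$src_end)
      suffix <- paste0("/", seq_len(nrow(pieces)))
    }
    for (k in seq_len(nrow(pieces))) {
      p <- pieces[k, ]
      if (p$strand == "+") {
        new_start <- p$dst_start + (clip_start[k] - p$src_start)
        new_end <- p$dst_start + (clip_end[k] - p$src_start)
        new_strand <- f$strand
      } else {
        new_start <- p$dst_start + (p$src_end - clip_end[k])
        new_end <- p$dst_start + (p$src_end - clip_start[k])
        new_strand <- flip_strand(f$strand)
      }
      g <- f
      g$start <- new_start
      g$end <- new_end
      g$strand <- new_strand
      g$name <- paste0(f$name, suffix[k])
      out[[length(out) + 1]] <- g
    }
  }
  lifted <- if (length(out) > 0) {
    arrange(list_rbind(out), .data$start, .data$end)
  } else {
    features[0, , drop = FALSE]
  }
  attr(lifted, "report") <- list(n_dropped = n_dropped,
                                 dropped_names = dropped_names,
                                 n_split = n_split)
  lifted
}

#' Invert a segment map
#'
#' Returns the map from the mutant axis back to the wild type. Only defined
#' for maps made of inversions alone, where the block correspondence is a
#' bijection between two axes of equal length.
#'
#' @param map A [segment_map][compile_rearrangement].
#' @return A `segment_map` with the axes swapped.
#' @export
invert_map <- function(map) {
  stopifnot(inherits(map, "segment_map"))
  if (nrow(map$duplicated) > 0 || nrow(map$deleted) > 0) {
    abort("only maps made of inversions alone can be inverted")
  }
  b <- map$blocks
  inv_blocks <- arrange(
    tibble(wt_start = b$mut_start, wt_end = b$mut_end,
           mut_start = b$wt_start, mut_end = b$wt_end, strand = b$strand),
    .data$wt_start
  )
  out <- structure(list(
    chrom = map$chrom,
    blocks = inv_blocks,
    deleted = tibble(start = double(), end = double()),
    duplicated = tibble(start = double(), end = double()),
    wt_length = map$mut_length,
    mut_length = map$wt_length
  ), class = "segment_map")
  validate_segment_map(out)
  out
}
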