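# Genomic context of a variant: window extraction around a SNP, feature
# overlap with flanking-distance reporting, strand-aware transcript
# coordinates, and percent identity of pre-aligned sequences.

#' Extract a genomic window centred on a position
#'
#' Returns the subsequence spanning `[position - floor(width/2),
#' position + ceiling(width/2) - 1]` (1-based inclusive), truncated at the
#' genome ends; truncation is flagged. For even widths this convention keeps
#' the window length exactly `width` away from the ends.
#'
#' @param bundle A `genome_bundle`.
#' @param position 1-based genomic position (must lie in the genome).
#' @param width Window width in bp (>= 1).
#' @return A list: `sequence`, `start`, `end` (absolute 1-based inclusive),
#'   `truncated` (logical).
#' @export
extract_window <- function(bundle, position, width) {
  stopifnot(inherits(bundle, "genome_bundle"))
  L <- nchar(bundle$sequence)
  position <- as.integer(position)
  width <- as.integer(width)
  if (position < 1L || position > L)
    stop("range error: position ", position, " outside the genome [1, ", L, "]")
  if (width < 1L) stop("width must be >= 1")
  want_start <- position - width %/% 2L
  want_end <- position + (width + 1L) %/% 2L - 1L
  start <- max(1L, want_start)
  end <- min(L, want_end)
  list(sequence = substring(bundle$sequence, start, end),
       start = start, end = end,
       truncated = (want_start < 1L || want_end > L))
}

#' Features overlapping a genomic position
#'
#' All annotated features containing the position (start <= position <= end;
#' an empty result means the position is intergenic), together with the
#' nearest non-overlapping feature on each side and its signed distance
#' (negative = feature ends upstream of the position, positive = feature
#' starts downstream).
#'
#' @param bundle A `genome_bundle`.
#' @param position 1-based genomic position.
#' @return A list: `overlapping` (data frame of features, possibly empty),
#'   `upstream` and `downstream` (each a list with `feature` — a one-row
#'   data frame or `NULL` — and `distance`).
#' @export
overlapping_features <- function(bundle, position) {
  stopifnot(inherits(bundle, "genome_bundle"))
  position <- as.integer(position)
  f <- bundle$features
  hit <- f$start <= position & f$end >= position
  up <- f[f$end < position, , drop = FALSE]
  down <- f[f$start > position, , drop = FALSE]
  upstream <- list(feature = NULL, distance = NA_integer_)
  if (nrow(up)) {
    i <- which.max(up$end)
    upstream <- list(feature = up[i, , drop = FALSE],
                     distance = up$end[i] - position)   # negative
  }
  downstream <- list(feature = NULL, distance = NA_integer_)
  if (nrow(down)) {
    i <- which.min(down$start)
    downstream <- list(feature = down[i, , drop = FALSE],
                       distance = down$start[i] - position)  # positive
  }
  list(overlapping = f[hit, , drop = FALSE],
       upstream = upstream, downstream = downstream)
}

#' Strand-aware transcript coordinate of a genomic position
#'
#' Maps a genomic position inside a feature to its 1-based offset from the
#' feature's 5' end: `position - start + 1` on the plus strand and
#' `end - position + 1` on the minus strand. The hit is tagged as lying in
#' the 5' or 3' half of the transcript, splitting at the feature midpoint.
#'
#' @param feature A list or one-row data frame with `start`, `end`, `strand`
#'   (and optionally `id`).
#' @param position 1-based genomic position inside the feature.
#' @return A `transcript_hit` list: `feature_id`, `strand`,
#'   `transcript_position`, `feature_length`, `region_tag` (`"5prime_half"`
#'   or `"3prime_half"`).
#' @export
transcript_position <- function(feature, position) {
  start <- as.integer(feature$start)
  end <- as.integer(feature$end)
  strand <- as.character(feature$strand)
  position <- as.integer(position)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (position < start || position > end)
    stop("range error: position ", position, " outside the feature [",
         start, ", ", end, "]")
  len <- end - start + 1L
  offset <- if (strand == "+") position - start + 1L else end - position + 1L
  structure(
    list(feature_id = if (!is.null(feature$id)) as.character(feature$id)
                      else NA_character_,
         strand = strand,
         transcript_position = offset,
         feature_length = len,
         region_tag = if (offset > len / 2) "3prime_half" else "5prime_half"),
    class = "transcript_hit"
  )
}

#' @export
print.transcript_hit <- function(x, ...) {
  cat(sprintf("transcript_hit: %s (%s strand), position %d of %d bp (%s)\n",
              x$feature_id, x$strand, x$transcript_position,
              x$feature_length, x$region_tag))
  invisible(x)
}

#' Genomic position of a transcript coordinate
#'
#' Inverse of [transcript_position()]: maps a 1-based offset from a
#' feature's 5' end back to the genomic coordinate.
#'
#' @inheritParams transcript_position
#' @param offset 1-based transcript offset (1 = 5' end).
#' @return The 1-based genomic position.
#' @export
genomic_position <- function(feature, offset) {
  start <- as.integer(feature$start)
  end <- as.integer(feature$end)
  offset <- as.integer(offset)
  len <- end - start + 1L
  if (offset < 1L || offset > len)
    stop("range error: offset outside [1, ", len, "]")
  if (as.character(feature$strand) == "+") start + offset - 1L
  else end - offset + 1L
}

#' Percent identity of two aligned sequences
#'
#' Column-wise identity of two pre-aligned sequences of equal length, with
#' `-` as the gap character: 100 x (columns where both sequences carry the
#' same non-gap base) / (columns where at least one sequence is non-gap).
#' No alignment is performed here; sequences must already be aligned.
#'
#' @param seq_a,seq_b Aligned sequences (equal-length character strings).
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(seq_a, seq_b) {
  a <- toupper(as.character(seq_a))
  b <- toupper(as.character(seq_b))
  if (nchar(a) != nchar(b))
    stop("alignment-required error: sequences have unequal lengths")
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  informative <- av != "-" | bv != "-"
  if (!any(informative)) stop("no non-gap columns")
  matches <- av == bv & av != "-"
  100 * sum(matches) / sum(informative)
}
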