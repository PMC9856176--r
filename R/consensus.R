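# Per-group consensus profiling and subfamily-discriminating ("unique")
# residue calling.
#
# The consensus score of a column is the percentage of non-gap characters in
# that column carrying the column's modal residue. The unique residue score of
# a column is the arithmetic mean of two groups' consensus scores there; a
# column is called when the two consensus residues differ and the unique score
# clears a threshold (90% is the customary subfamily-level cut-off, 80% the
# family-level one).

#' Build a per-column consensus profile for one group
#'
#' Gaps are excluded from both numerator and denominator of the consensus
#' score. Ambiguity codes (`X`, `B`, `Z`) count toward the column depth but
#' are never eligible as the consensus residue. Ties on the modal residue are
#' broken alphabetically and flagged.
#'
#' @param alignment A [grouped_alignment()].
#' @param group Group label with at least one member.
#' @param ambiguity Characters counted in depth but excluded from the modal
#'   candidate set.
#' @return A `consensus_profile` data frame with one row per alignment column:
#'   `column` (1-based), `consensus_residue` (`NA` when depth is 0 or only
#'   ambiguity codes are present), `consensus_score` (percent), `gap_fraction`,
#'   `depth` (non-gap count) and `tie`.
#' @export
build_consensus <- function(alignment, group, ambiguity = c("X", "B", "Z")) {
  ids <- group_members(alignment, group)
  m <- aln_matrix(alignment)[ids, , drop = FALSE]
  L <- ncol(m)
  n <- nrow(m)
  res <- rep(NA_character_, L)
  score <- numeric(L)
  gapf <- numeric(L)
  depth <- integer(L)
  tie <- logical(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    nongap <- col[col != "-"]
    d <- length(nongap)
    depth[j] <- d
    gapf[j] <- 1 - d / n
    if (d == 0L) next
    cand <- nongap[!nongap %in% ambiguity]
    if (!length(cand)) next
    tab <- table(cand)
    mx <- max(tab)
    winners <- sort(names(tab)[tab == mx])
    res[j] <- winners[[1L]]
    tie[j] <- length(winners) > 1L
    score[j] <- 100 * mx / d
  }
  out <- data.frame(column = seq_len(L), consensus_residue = res,
                    consensus_score = score, gap_fraction = gapf,
                    depth = depth, tie = tie, stringsAsFactors = FALSE)
  attr(out, "group_label") <- group
  class(out) <- c("consensus_profile", "data.frame")
  out
}

#' Per-column unique residue scores for two groups
#'
#' The unique residue score at a column is the arithmetic mean of the two
#' groups' consensus scores there. The result is symmetric in argument order
#' up to the a/b residue labels.
#'
#' @param profile_a,profile_b [build_consensus()] profiles built on the same
#'   alignment columns.
#' @return Data frame with one row per column: `column`, `residue_a`,
#'   `score_a`, `gap_fraction_a`, `residue_b`, `score_b`, `gap_fraction_b`,
#'   `unique_score`. Attributes `group_a`/`group_b` carry the group labels.
#' @export
unique_residue_scores <- function(profile_a, profile_b) {
  if (nrow(profile_a) != nrow(profile_b)) {
    stop("profiles cover different numbers of columns (",
         nrow(profile_a), " vs ", nrow(profile_b), ")")
  }
  out <- data.frame(
    column = profile_a$column,
    residue_a = profile_a$consensus_residue,
    score_a = profile_a$consensus_score,
    gap_fraction_a = profile_a$gap_fraction,
    residue_b = profile_b$consensus_residue,
    score_b = profile_b$consensus_score,
    gap_fraction_b = profile_b$gap_fraction,
    stringsAsFactors = FALSE)
  out$unique_score <- (out$score_a + out$score_b) / 2
  attr(out, "group_a") <- attr(profile_a, "group_label")
  attr(out, "group_b") <- attr(profile_b, "group_label")
  out
}

#' Call subfamily-discriminating residues
#'
#' A column is called when both groups have a defined consensus residue, the
#' residues differ, the unique score clears `threshold_pct`, and neither
#' group's gap fraction exceeds `max_gap_fraction` (majority-gap columns have
#' no meaningful consensus). Each call is labelled `different` or `similar`
#' according to the chemistry classes of the two residues.
#'
#' @param scores Output of [unique_residue_scores()].
#' @param threshold_pct Percentage threshold in (0, 100]; default 90.
#' @param chemistry Residue class map, see [chemistry_classes()].
#' @param strict If `TRUE` (default) a call requires `unique_score >
#'   threshold_pct`; if `FALSE`, `>=`.
#' @param max_gap_fraction Columns where either group's gap fraction exceeds
#'   this value are excluded; `NULL` disables the filter.
#' @return Data frame of calls sorted by column: `column`, `residue_a`,
#'   `score_a`, `residue_b`, `score_b`, `unique_score`, `chemistry`.
#' @export
call_unique_residues <- function(scores, threshold_pct = 90,
                                 chemistry = chemistry_classes(),
                                 strict = TRUE, max_gap_fraction = 0.5) {
  stopifnot(threshold_pct > 0, threshold_pct <= 100)
  keep <- !is.na(scores$residue_a) & !is.na(scores$residue_b) &
    scores$residue_a != scores$residue_b
  keep <- keep & if (strict) scores$unique_score > threshold_pct else
    scores$unique_score >= threshold_pct
  if (!is.null(max_gap_fraction)) {
    keep <- keep & scores$gap_fraction_a <= max_gap_fraction &
      scores$gap_fraction_b <= max_gap_fraction
  }
  out <- scores[keep, c("column", "residue_a", "score_a", "residue_b",
                        "score_b", "unique_score"), drop = FALSE]
  out$chemistry <- chemistry_relation(out$residue_a, out$residue_b, chemistry)
  out <- out[order(out$column), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "group_a") <- attr(scores, "group_a")
  attr(out, "group_b") <- attr(scores, "group_b")
  attr(out, "threshold_pct") <- threshold_pct
  out
}

#' Count discriminating residues a query sequence shares with one group
#'
#' For each call, the query's character at the called column is compared with
#' the chosen side's consensus residue; a gap in the query never matches.
#'
#' @param alignment A [grouped_alignment()] containing the query row.
#' @param query_id Sequence id of the query.
#' @param calls Non-empty output of [call_unique_residues()].
#' @param side `"a"` or `"b"`: which group's consensus residues to match.
#' @return List with `n_shared` and `n_total`.
#' @export
shared_unique_residues <- function(alignment, query_id, calls,
                                   side = c("a", "b")) {
  side <- match.arg(side)
  stopifnot(inherits(alignment, "grouped_alignment"))
  if (!query_id %in% alignment$records$sequence_id) {
    stop("query id not in alignment: ", query_id)
  }
  if (!nrow(calls)) stop("empty call set")
  q <- strsplit(alignment$sequences[[query_id]], "", fixed = TRUE)[[1]]
  cons <- if (side == "a") calls$residue_a else calls$residue_b
  qc <- q[calls$column]
  list(n_shared = sum(qc != "-" & qc == cons), n_total = nrow(calls))
}

#' Ungapped lengths of an alignment column span, per sequence and per group
#'
#' Used e.g. to profile loop-region lengths (such as the M-loop, long in some
#' subfamilies and only a few residues in others) across a grouped alignment.
#'
#' @param alignment A [grouped_alignment()].
#' @param first_col,last_col 1-based inclusive column span.
#' @return List with `per_sequence` (data frame `sequence_id`, `group_label`,
#'   `ungapped_length`) and `by_group` (data frame `group_label`, `n`, `min`,
#'   `median`, `max`).
#' @export
region_lengths <- function(alignment, first_col, last_col) {
  stopifnot(inherits(alignment, "grouped_alignment"))
  if (!(first_col >= 1 && first_col <= last_col &&
        last_col <= alignment$length)) {
    stop("column span out of range: ", first_col, "..", last_col,
         " for an alignment of ", alignment$length, " columns")
  }
  m <- aln_matrix(alignment)[, first_col:last_col, drop = FALSE]
  lens <- rowSums(m != "-")
  per_seq <- data.frame(sequence_id = alignment$records$sequence_id,
                        group_label = alignment$records$group_label,
                        ungapped_length = as.integer(lens),
                        stringsAsFactors = FALSE)
  split_lens <- split(per_seq$ungapped_length, per_seq$group_label)
  by_group <- data.frame(
    group_label = names(split_lens),
    n = vapply(split_lens, length, integer(1)),
    min = vapply(split_lens, min, numeric(1)),
    median = vapply(split_lens, stats::median, numeric(1)),
    max = vapply(split_lens, max, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(by_group) <- NULL
  list(per_sequence = per_seq, by_group = by_group)
}
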