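# Seeded generator for grouped alignments with planted discriminating columns.
# Background columns share one modal residue across both groups (so the false
# positive rate of discriminating-residue calling can be measured against a
# null); planted columns give each group its own residue at a stated
# conservation probability. No substitution model or indel evolution is
# simulated.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Specification for a synthetic grouped alignment
#'
#' @param n_a,n_b Group sizes.
#' @param length Number of alignment columns.
#' @param planted Optional data frame of planted columns with columns
#'   `column`, `residue_a`, `residue_b`, `conservation_a`, `conservation_b`.
#'   When `NULL`, `n_different_chemistry` + `n_similar_chemistry` columns are
#'   drawn at simulation time.
#' @param n_different_chemistry,n_similar_chemistry Numbers of planted columns
#'   whose group-a/group-b residues have different / similar chemistry (used
#'   when `planted` is `NULL`).
#' @param planted_conservation Conservation probability for drawn planted
#'   columns (both groups).
#' @param background_conservation Probability that a background cell carries
#'   its column's modal residue.
#' @param gap_rate Per-cell gap probability.
#' @param seed Integer seed; generation is bit-reproducible given the spec.
#' @param group_a,group_b Group labels.
#' @param chemistry Residue class map used when drawing planted residue pairs.
#' @return An `alignment_sim_spec` list.
#' @export
alignment_sim_spec <- function(n_a, n_b, length, planted = NULL,
                               n_different_chemistry = 0L,
                               n_similar_chemistry = 0L,
                               planted_conservation = 1.0,
                               background_conservation = 0.5,
                               gap_rate = 0.02, seed = 1L,
                               group_a = "group_a", group_b = "group_b",
                               chemistry = chemistry_classes()) {
  stopifnot(n_a >= 1, n_b >= 1, length >= 1,
            background_conservation >= 0, background_conservation <= 1,
            planted_conservation >= 0, planted_conservation <= 1,
            gap_rate >= 0, gap_rate <= 1)
  if (!is.null(planted)) {
    stopifnot(all(c("column", "residue_a", "residue_b",
                    "conservation_a", "conservation_b") %in% names(planted)))
    if (anyDuplicated(planted$column)) stop("planted columns must be distinct")
    if (any(planted$column < 1 | planted$column > length)) {
      stop("planted column outside the alignment")
    }
    if (any(planted$conservation_a < 0 | planted$conservation_a > 1 |
            planted$conservation_b < 0 | planted$conservation_b > 1)) {
      stop("planted conservation probabilities must lie in [0, 1]")
    }
  } else if (n_different_chemistry + n_similar_chemistry > length) {
    stop("more planted columns than alignment columns")
  }
  structure(list(n_a = n_a, n_b = n_b, length = as.integer(length),
                 planted = planted,
                 n_different_chemistry = as.integer(n_different_chemistry),
                 n_similar_chemistry = as.integer(n_similar_chemistry),
                 planted_conservation = planted_conservation,
                 background_conservation = background_conservation,
                 gap_rate = gap_rate, seed = as.integer(seed),
                 group_a = group_a, group_b = group_b,
                 chemistry = chemistry),
            class = "alignment_sim_spec")
}

# Draw a residue pair with the requested chemistry relation.
draw_residue_pair <- function(relation, chemistry) {
  classes <- split(names(chemistry), unname(chemistry))
  if (relation == "similar") {
    big <- classes[vapply(classes, length, integer(1)) >= 2]
    cls <- big[[sample.int(length(big), 1)]]
    pair <- sample(cls, 2)
  } else {
    two <- sample.int(length(classes), 2)
    pair <- c(sample(classes[[two[1]]], 1), sample(classes[[two[2]]], 1))
  }
  pair
}

draw_column <- function(n, consensus, p) {
  out <- rep(consensus, n)
  miss <- stats::runif(n) >= p
  k <- sum(miss)
  if (k) out[miss] <- sample(setdiff(AA20, consensus), k, replace = TRUE)
  out
}

#' Simulate a grouped alignment with planted discriminating columns
#'
#' @param spec An [alignment_sim_spec()].
#' @return List with `alignment` (a [grouped_alignment()]) and `truth`: the
#'   planted column table including the intended `chemistry` relation of each
#'   planted residue pair.
#' @export
simulate_subfamily_alignment <- function(spec) {
  stopifnot(inherits(spec, "alignment_sim_spec"))
  withr::with_seed(spec$seed, {
    planted <- spec$planted
    if (is.null(planted)) {
      n_pl <- spec$n_different_chemistry + spec$n_similar_chemistry
      cols <- if (n_pl) sort(sample.int(spec$length, n_pl)) else integer(0)
      relation <- sample(c(rep("different", spec$n_different_chemistry),
                           rep("similar", spec$n_similar_chemistry)))
      pairs <- t(vapply(relation, draw_residue_pair, character(2),
                        chemistry = spec$chemistry))
      planted <- data.frame(column = cols,
                            residue_a = if (n_pl) unname(pairs[, 1]) else character(0),
                            residue_b = if (n_pl) unname(pairs[, 2]) else character(0),
                            conservation_a = rep(spec$planted_conservation, n_pl),
                            conservation_b = rep(spec$planted_conservation, n_pl),
                            stringsAsFactors = FALSE)
    }
    planted$chemistry <- chemistry_relation(planted$residue_a,
                                            planted$residue_b, spec$chemistry)
    n <- spec$n_a + spec$n_b
    rows_a <- seq_len(spec$n_a)
    rows_b <- spec$n_a + seq_len(spec$n_b)
    mat <- matrix("", n, spec$length)
    modal <- sample(AA20, spec$length, replace = TRUE)
    for (j in seq_len(spec$length)) {
      mat[, j] <- draw_column(n, modal[j], spec$background_conservation)
    }
    for (i in seq_len(nrow(planted))) {
      j <- planted$column[i]
      mat[rows_a, j] <- draw_column(spec$n_a, planted$residue_a[i],
                                    planted$conservation_a[i])
      mat[rows_b, j] <- draw_column(spec$n_b, planted$residue_b[i],
                                    planted$conservation_b[i])
    }
    if (spec$gap_rate > 0) {
      mat[stats::runif(length(mat)) < spec$gap_rate] <- "-"
    }
    ids <- c(sprintf("%s_%03d", spec$group_a, seq_len(spec$n_a)),
             sprintf("%s_%03d", spec$group_b, seq_len(spec$n_b)))
    labels <- c(rep(spec$group_a, spec$n_a), rep(spec$group_b, spec$n_b))
    aln <- grouped_alignment(ids, labels,
                             apply(mat, 1, paste, collapse = ""))
    list(alignment = aln, truth = planted)
  })
}
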