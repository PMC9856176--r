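# Deterministic construction of a species phenotype table realising a set of
# planted co-occurrence counts exactly; used to emulate appendix-style species
# tables when validating the tally operations.

#' Simulate a species phenotype table with exact planted tallies
#'
#' Builds a table whose [tally_cooccurrence()] output equals the planted
#' counts exactly. Species are assigned to subfamily categories (both,
#' CetZ1-only, CetZ2-only, neither), then rod and motility reports are
#' distributed: first to the "both" category (`n_rod_and_both`,
#' `n_motile_and_both`), then to CetZ1-only (`n_rod_and_cetz1_only`,
#' `n_motile_and_cetz1_only`), and any remainder to CetZ2-only then neither.
#'
#' @param n Number of species.
#' @param planted Named list/vector of counts: `n_both`, `n_cetz1_only`,
#'   `n_neither` (and optionally `n_cetz2_only`, default 0) must sum to `n`;
#'   `n_rod`, `n_rod_and_both`, `n_motile`, `n_motile_and_both` and optionally
#'   `n_rod_and_cetz1_only`, `n_motile_and_cetz1_only` (default 0) must
#'   satisfy the obvious consistency bounds.
#' @param seed Integer seed (controls species-name shuffling and the
#'   uninformative `n_other_cetz` column only; the tallies are deterministic).
#' @return Data frame of species records, as from [read_species_table()].
#' @export
simulate_species_table <- function(n, planted, seed = 1L) {
  p <- as.list(planted)
  default0 <- function(nm) if (is.null(p[[nm]])) 0L else as.integer(p[[nm]])
  n_both <- default0("n_both")
  n_c1 <- default0("n_cetz1_only")
  n_c2 <- default0("n_cetz2_only")
  n_nei <- default0("n_neither")
  n_rod <- default0("n_rod")
  n_rod_both <- default0("n_rod_and_both")
  n_rod_c1 <- default0("n_rod_and_cetz1_only")
  n_mot <- default0("n_motile")
  n_mot_both <- default0("n_motile_and_both")
  n_mot_c1 <- default0("n_motile_and_cetz1_only")

  if (n_both + n_c1 + n_c2 + n_nei != n) {
    stop("subfamily categories must sum to n (",
         n_both + n_c1 + n_c2 + n_nei, " != ", n, ")")
  }
  check <- function(cond, msg) if (!cond) stop("inconsistent counts: ", msg)
  check(n_rod_both <= min(n_rod, n_both), "n_rod_and_both")
  check(n_mot_both <= min(n_mot, n_both), "n_motile_and_both")
  check(n_rod_c1 <= min(n_rod - n_rod_both, n_c1), "n_rod_and_cetz1_only")
  check(n_mot_c1 <= min(n_mot - n_mot_both, n_c1), "n_motile_and_cetz1_only")
  rod_rest <- n_rod - n_rod_both - n_rod_c1
  mot_rest <- n_mot - n_mot_both - n_mot_c1
  check(rod_rest >= 0 && rod_rest <= n_c2 + n_nei, "n_rod remainder")
  check(mot_rest >= 0 && mot_rest <= n_c2 + n_nei, "n_motile remainder")

  category <- rep(c("both", "cetz1_only", "cetz2_only", "neither"),
                  c(n_both, n_c1, n_c2, n_nei))
  has1 <- category %in% c("both", "cetz1_only")
  has2 <- category %in% c("both", "cetz2_only")
  mark <- function(n_in_both, n_in_c1, rest) {
    flag <- rep(FALSE, n)
    flag[which(category == "both")[seq_len(n_in_both)]] <- TRUE
    flag[which(category == "cetz1_only")[seq_len(n_in_c1)]] <- TRUE
    tail_idx <- which(category %in% c("cetz2_only", "neither"))
    flag[tail_idx[seq_len(rest)]] <- TRUE
    flag
  }
  rod <- mark(n_rod_both, n_rod_c1, rod_rest)
  mot <- mark(n_mot_both, n_mot_c1, mot_rest)

  withr::with_seed(seed, {
    ord <- sample.int(n)
    data.frame(
      species = sprintf("synthetic_species_%03d", seq_len(n)),
      taxon_order = rep(c("OrderA", "OrderB", "OrderC"), length.out = n),
      has_cetz1 = has1[ord],
      has_cetz2 = has2[ord],
      n_other_cetz = sample(0:4, n, replace = TRUE),
      motility_reported = mot[ord],
      rods_reported = rod[ord],
      stringsAsFactors = FALSE)
  })
}
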