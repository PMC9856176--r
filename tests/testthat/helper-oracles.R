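# Independent brute-force oracles and small fixture builders. The oracles
# recompute quantities by direct enumeration, sharing no code with the
# implementation paths they check.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Per-column consensus by direct counting over the full residue alphabet.
oracle_consensus <- function(alignment, group, ambiguity = c("X", "B", "Z")) {
  ids <- alignment$records$sequence_id[alignment$records$group_label == group]
  rows <- strsplit(unname(alignment$sequences[ids]), "", fixed = TRUE)
  L <- alignment$length
  res <- rep(NA_character_, L)
  score <- numeric(L)
  depth <- integer(L)
  for (j in seq_len(L)) {
    chars <- vapply(rows, function(r) r[[j]], character(1))
    d <- 0L
    for (ch in chars) if (ch != "-") d <- d + 1L
    depth[j] <- d
    if (d == 0L) next
    best <- NA_character_
    best_n <- 0L
    for (r in sort(AA_ALPHABET)) {   # alphabetical scan => alphabetical ties
      n_r <- sum(chars == r)
      if (n_r > best_n) {
        best <- r
        best_n <- n_r
      }
    }
    if (best_n == 0L) next           # only gaps/ambiguity present
    res[j] <- best
    score[j] <- 100 * best_n / d
  }
  list(consensus = res, score = score, depth = depth)
}

# A random grouped alignment (with gaps and occasional ambiguity codes) for
# equivalence and monotonicity checks.
random_alignment <- function(n_a, n_b, L, gap_rate = 0.1, amb_rate = 0.02) {
  n <- n_a + n_b
  chars <- sample(AA_ALPHABET, n * L, replace = TRUE)
  amb <- stats::runif(n * L) < amb_rate
  chars[amb] <- sample(c("X", "B", "Z"), sum(amb), replace = TRUE)
  mat <- matrix(chars, n, L)
  mat[stats::runif(n * L) < gap_rate] <- "-"
  grouped_alignment(sprintf("s%03d", seq_len(n)),
                    rep(c("ga", "gb"), c(n_a, n_b)),
                    apply(mat, 1, paste, collapse = ""))
}

# Brute-force neighbourhood membership via the doubled-sequence construction:
# duplicate all features at +L, place the focal copy so that the whole window
# fits in linear coordinates, and collect every feature overlapping it.
oracle_neighborhood_members <- function(annotation, focal_locus, flank_bp) {
  feats <- annotation$features
  f <- feats[feats$locus_id == focal_locus, ]
  contig <- annotation$contigs[annotation$contigs$contig_id == f$contig_id, ]
  L <- contig$length_bp
  on_contig <- feats[feats$contig_id == f$contig_id, ]
  if (!contig$is_circular) {
    ws <- max(1, f$start_bp - flank_bp)
    we <- min(L, f$end_bp + flank_bp)
    hit <- on_contig$start_bp <= we & on_contig$end_bp >= ws
    return(sort(on_contig$locus_id[hit]))
  }
  unrolled <- do.call(rbind, lapply(0:2, function(k) {
    data.frame(locus_id = on_contig$locus_id,
               start = on_contig$start_bp + k * L,
               end = on_contig$end_bp + k * L)
  }))
  fs <- f$start_bp + L   # focal copy in the middle repeat: window always fits
  fe <- f$end_bp + L
  ws <- fs - flank_bp
  we <- fe + flank_bp
  if (fe + flank_bp - (fs - flank_bp) + 1 >= L) {
    return(sort(on_contig$locus_id))   # window covers the whole contig
  }
  hit <- unrolled$start <= we & unrolled$end >= ws
  sort(unique(unrolled$locus_id[hit]))
}

# Annotated neighbourhood regions for every genome of a simulate_genomes()
# result.
regions_from_sim <- function(sim, flank_bp = 20000) {
  lapply(sim$genomes, function(g) {
    suppressMessages(annotate_region(
      extract_neighborhood(g$annotation, g$focal_locus, flank_bp),
      g$assignments))
  })
}

# Synthetic pili cassette and its regulon definition (pilC has no published
# arCOG id, so the cassette uses a clearly synthetic stand-in id).
test_cassette <- function() {
  c(pilB = "arCOG01818", pilC = "arCOG90001",
    "arCOG05787", "arCOG05789", "arCOG03821", "arCOG03822",
    "arCOG05790", "arCOG05786", "arCOG05788")
}

test_regulon <- function() {
  regulon_definition(anchor_arcogs = c("arCOG01818", "arCOG90001"))
}

# Planted co-occurrence counts matching the published 55-species tabulation.
paper_venn_counts <- function() {
  list(n_both = 45, n_cetz1_only = 7, n_neither = 3,
       n_rod = 40, n_rod_and_both = 37, n_rod_and_cetz1_only = 2,
       n_motile = 26, n_motile_and_both = 24, n_motile_and_cetz1_only = 1)
}
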