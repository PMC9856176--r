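# Window extraction (linear clipping and circular wrap), arCOG tallies,
# conservation calling, pili-regulon classification, genome-wide placement
# and synteny orientation.

linear_genome <- function(features, len = 3e6, circular = FALSE,
                          species = "spX") {
  genome_annotation(data.frame(contig_id = "c1", length_bp = len,
                               is_circular = circular),
                    cbind(contig_id = "c1", features), species = species)
}

test_that("windows use gene boundaries, clip on linear contigs, wrap on circular", {
  feats <- data.frame(start_bp = 100000, end_bp = 101000, strand = "+",
                      locus_id = "focal")
  r <- extract_neighborhood(linear_genome(feats), "focal", 20000)
  expect_equal(r$window, data.frame(start = 80000, end = 121000))

  # clipping: window cannot leave the contig
  feats2 <- data.frame(start_bp = 500, end_bp = 900, strand = "+",
                       locus_id = "focal")
  r2 <- extract_neighborhood(linear_genome(feats2, len = 10000), "focal", 20000)
  expect_equal(r2$window, data.frame(start = 1, end = 10000))

  # circular wrap across the origin: two intervals
  feats3 <- data.frame(start_bp = 5000, end_bp = 6000, strand = "+",
                       locus_id = "focal")
  r3 <- extract_neighborhood(linear_genome(feats3, len = 2e6, circular = TRUE),
                             "focal", 20000)
  expect_equal(r3$window, data.frame(start = c(1985000, 1), end = c(2e6, 26000)))
  expect_error(extract_neighborhood(linear_genome(feats), "nope"),
               "unknown focal locus")
})

test_that("window membership matches the brute-force doubled-sequence oracle", {
  sim <- simulate_genomes(genome_sim_spec(
    n_species = 40, contig_length = 60000, circular_fraction = 0.5,
    n_distal_genes = 3, seed = 31))
  for (g in sim$genomes) {
    r <- extract_neighborhood(g$annotation, g$focal_locus, 20000)
    expect_setequal(r$members$locus_id,
                    oracle_neighborhood_members(g$annotation, g$focal_locus,
                                                20000))
    # every reported member genuinely overlaps the window
    ok <- overlaps <- mapply(function(s, e) {
      any(s <= r$window$end & e >= r$window$start)
    }, r$members$start_bp, r$members$end_bp)
    expect_true(all(ok))
    expect_true(g$focal_locus %in% r$members$locus_id)
  }
})

test_that("arCOG labelling and occurrence/presence tallies are exact", {
  mk_region <- function(species, arcogs) {
    n <- length(arcogs)
    feats <- data.frame(start_bp = seq(1000, by = 2000, length.out = n),
                        end_bp = seq(2000, by = 2000, length.out = n),
                        strand = "+",
                        locus_id = sprintf("%s_g%d", species, seq_len(n)))
    ann <- linear_genome(feats, species = species)
    asn <- data.frame(locus_id = feats$locus_id, arcog_id = arcogs,
                      cog_category = "", annotation = "",
                      stringsAsFactors = FALSE)
    suppressMessages(annotate_region(
      extract_neighborhood(ann, feats$locus_id[1], 20000), asn))
  }
  r1 <- mk_region("s1", c("X", "X", "Y"))
  r2 <- mk_region("s2", c("X", NA, "Z"))
  r3 <- mk_region("s3", c("Q", "Z", NA))
  expect_equal(sum(is.na(r2$members$arcog_id)), 1)   # explicit unassigned
  tab <- tally_arcogs(list(r1, r2, r3))
  expect_equal(attr(tab, "n_regions"), 3L)
  expect_equal(tab$occurrences[tab$arcog_id == "X"], 3L)
  expect_equal(tab$presence[tab$arcog_id == "X"], 2L)
  expect_equal(tab$presence[tab$arcog_id == "Z"], 2L)
  expect_equal(attr(tab, "n_unassigned"), 2L)
  expect_true(all(tab$presence <= tab$occurrences))
  # conservation threshold, defaults and monotonicity
  expect_equal(as.character(conserved_arcogs(tab, 2)), c("X", "Z"))
  expect_equal(as.character(conserved_arcogs(tab)), c("X", "Z"))  # majority = 2
  expect_equal(as.character(conserved_arcogs(tab, 3)), character(0))
  for (m in 1:2) {
    expect_true(all(conserved_arcogs(tab, m + 1) %in% conserved_arcogs(tab, m)))
  }
  expect_error(conserved_arcogs(tab, 4), "min_presence")
})

test_that("presence thresholds behave at the published majority boundary", {
  # 20 regions; one arCOG present in 10, one in 9 -> only the first survives
  regions <- lapply(1:20, function(i) {
    arcogs <- c("focalCOG", if (i <= 10) "X", if (i <= 9) "Y")
    n <- length(arcogs)
    feats <- data.frame(start_bp = seq(1000, by = 2000, length.out = n),
                        end_bp = seq(2000, by = 2000, length.out = n),
                        strand = "+", locus_id = sprintf("s%d_g%d", i, 1:n))
    ann <- linear_genome(feats, species = paste0("s", i))
    asn <- data.frame(locus_id = feats$locus_id, arcog_id = arcogs,
                      cog_category = "", annotation = "")
    annotate_region(extract_neighborhood(ann, feats$locus_id[1], 20000), asn)
  })
  cons <- conserved_arcogs(tally_arcogs(regions), 10)
  expect_true("X" %in% cons)
  expect_false("Y" %in% cons)
})

test_that("pili-regulon classification needs both anchors and contiguity", {
  reg <- test_regulon()
  mk_region <- function(arcogs) {
    n <- length(arcogs)
    feats <- data.frame(start_bp = seq(30000, by = 2000, length.out = n),
                        end_bp = seq(31000, by = 2000, length.out = n),
                        strand = "+", locus_id = sprintf("g%d", seq_len(n)))
    ann <- linear_genome(feats)
    asn <- data.frame(locus_id = feats$locus_id, arcog_id = arcogs,
                      cog_category = "", annotation = "")
    suppressMessages(annotate_region(
      extract_neighborhood(ann, "g1", 20000), asn))
  }
  # adjacent pilB + pilC + five pilins -> associated
  full <- mk_region(c("arCOG02202", "arCOG01818", "arCOG90001", "arCOG05787",
                      "arCOG05789", "arCOG03821", "arCOG03822", "arCOG05790"))
  cl <- classify_pili_association(full, reg)
  expect_true(cl$is_pili_associated)
  expect_equal(sum(cl$matched_loci$role == "anchor"), 2)
  expect_equal(sum(cl$matched_loci$role == "accessory"), 5)
  # pilB without pilC -> not associated at min_anchors 2
  expect_false(classify_pili_association(
    mk_region(c("arCOG02202", "arCOG01818", "arCOG05787")), reg)$is_pili_associated)
  # both anchors but separated by more than max_gene_gap non-regulon genes
  spread <- mk_region(c("arCOG02202", "arCOG01818", "b1", "b2", "b3", "b4",
                        "arCOG90001"))
  expect_false(classify_pili_association(spread, reg)$is_pili_associated)
  # a gap of exactly max_gene_gap is tolerated
  near <- mk_region(c("arCOG02202", "arCOG01818", "b1", "b2", "b3",
                      "arCOG90001"))
  expect_true(classify_pili_association(near, reg)$is_pili_associated)
  expect_error(regulon_definition("arCOG01818", min_anchors = 2),
               "exceeds the number of anchors")
})

test_that("cassette carriers are recovered exactly and deterministically", {
  sim <- simulate_genomes(genome_sim_spec(
    n_species = 22, cassette = test_cassette(), n_carriers = 12,
    contig_length = 3e5, n_distal_genes = 2, seed = 17))
  regions <- regions_from_sim(sim)
  reg <- test_regulon()
  hits <- vapply(regions, function(r) {
    classify_pili_association(r, reg)$is_pili_associated
  }, logical(1))
  expect_equal(sort(names(hits)[hits]), sim$truth$carriers)
  expect_equal(sum(hits), 12L)
  hits2 <- vapply(regions, function(r) {
    classify_pili_association(r, reg)$is_pili_associated
  }, logical(1))
  expect_identical(hits, hits2)   # classification is deterministic
})

test_that("genome-wide placement walks its category ladder in order", {
  reg <- test_regulon()
  sim <- simulate_genomes(genome_sim_spec(
    n_species = 1, contig_length = 1e6, n_distal_genes = 0,
    distal_arcogs = data.frame(arcog_id = "arCOGtarget", offset_bp = 100000),
    seed = 23))
  g <- sim$genomes[[1]]
  r <- suppressMessages(regions_from_sim(sim))[[1]]
  # the focal arCOG itself sits inside the focal window
  expect_equal(genome_wide_arcog_placement(g$annotation, g$assignments,
                                           "arCOG02202", r, reg),
               "in_focal_region")
  # a target planted 100 kb away with no regulon near it
  expect_equal(genome_wide_arcog_placement(g$annotation, g$assignments,
                                           "arCOGtarget", r, reg),
               "elsewhere_alone")
  expect_equal(genome_wide_arcog_placement(g$annotation, g$assignments,
                                           "arCOGabsent", r, reg),
               "absent")
  # distal cassette next to the target -> elsewhere_with_regulon
  sim2 <- simulate_genomes(genome_sim_spec(
    n_species = 1, contig_length = 1e6, n_distal_genes = 0,
    cassette = test_cassette(), n_carriers = 1,
    cassette_location = "distal", seed = 23))
  g2 <- sim2$genomes[[1]]
  r2 <- suppressMessages(regions_from_sim(sim2))[[1]]
  expect_equal(genome_wide_arcog_placement(g2$annotation, g2$assignments,
                                           "arCOG05787", r2, reg),
               "elsewhere_with_regulon")
})

test_that("synteny offsets are strand-normalised and labels collapsed", {
  feats <- data.frame(start_bp = c(50000, 56000, 44000),
                      end_bp = c(51000, 57000, 45000),
                      strand = c("-", "+", "-"),
                      locus_id = c("focal", "down", "up"))
  ann <- linear_genome(feats)
  asn <- data.frame(locus_id = feats$locus_id,
                    arcog_id = c("arCOG02202", "consA", NA),
                    cog_category = "", annotation = "")
  r <- suppressMessages(annotate_region(
    extract_neighborhood(ann, "focal", 20000), asn))
  syn <- synteny_table(list(r), conserved = c("arCOG02202", "consA"))
  # focal on '-': gene at larger coordinates maps to negative offsets
  expect_equal(syn$offset_bp[syn$locus_id == "focal"], 0L)
  expect_equal(syn$offset_bp[syn$locus_id == "down"], -6000L)
  expect_equal(syn$offset_bp[syn$locus_id == "up"], 6000L)
  expect_equal(syn$strand[syn$locus_id == "focal"], "+")  # mirrored
  expect_equal(syn$label[syn$locus_id == "up"], "unassigned")
  # identical regions give identical synteny rows
  syn2 <- synteny_table(list(r, r), conserved = c("arCOG02202", "consA"))
  half <- nrow(syn2) / 2
  expect_equal(syn2$offset_bp[1:half], syn2$offset_bp[(half + 1):nrow(syn2)])
  # non-conserved arCOGs collapse to "other"
  syn3 <- synteny_table(list(r), conserved = "arCOG02202")
  expect_equal(syn3$label[syn3$locus_id == "down"], "other")
  p <- plot_synteny(syn)
  expect_s3_class(p, "ggplot")
})
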