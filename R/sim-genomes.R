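# Seeded generator for annotated genomes with a focal gene, planted conserved
# neighbourhood arCOGs, an optional type IV pili cassette, and background
# filler genes. Ground truth (which arCOGs were placed where, which species
# carry the cassette) is returned alongside the genomes so every neighbourhood
# operation can be validated against known answers.

#' Specification for a set of synthetic annotated genomes
#'
#' Each genome holds one focal gene on a single contig. The focal
#' neighbourhood (focal gene +/- `flank_bp`) is packed with genes: planted
#' core-pool arCOGs, an optional contiguous pili cassette adjacent to the
#' focal gene, and unique background filler genes occupying the remaining
#' slots. A few background genes are also placed outside the window.
#'
#' @param n_species Number of genomes.
#' @param core_pool Data frame with column `arcog_id` plus either
#'   `retention_prob` (per-genome placement probability) or `n_present`
#'   (exact number of genomes that receive the arCOG, membership drawn at
#'   random) and optionally `n_double` (how many of the receiving genomes
#'   carry two copies).
#' @param cassette Ordered character vector of cassette arCOG ids (e.g. pilB,
#'   pilC and pilins); empty for no cassette.
#' @param n_carriers Exact number of cassette-carrying genomes (drawn at
#'   random); overrides `insertion_prob`.
#' @param insertion_prob Per-genome cassette probability when `n_carriers` is
#'   `NULL`.
#' @param cassette_location `"adjacent"` inserts the cassette immediately
#'   downstream of the focal gene; `"distal"` places it far outside the
#'   window (to exercise genome-wide placement categories).
#' @param n_second_focal Number of genomes given a second copy of the focal
#'   arCOG inside the window.
#' @param n_distal_genes Background genes placed outside the window.
#' @param distal_arcogs Optional data frame (`arcog_id`, `offset_bp`) of
#'   single genes planted at a fixed offset from the focal gene (outside the
#'   window when `|offset_bp| > flank_bp`).
#' @param gene_length,intergenic Uniform ranges (bp) for gene lengths and
#'   intergenic gaps.
#' @param contig_length Contig length in bp; must comfortably exceed the
#'   window.
#' @param circular_fraction Fraction of genomes on a circular contig.
#' @param flank_bp Neighbourhood flank (default 20000).
#' @param focal_arcog arCOG id assigned to the focal gene.
#' @param unassigned_rate Fraction of filler genes left without an arCOG.
#' @param seed Integer seed; generation is bit-reproducible given the spec.
#' @return A `genome_sim_spec` list.
#' @export
genome_sim_spec <- function(n_species = 20L, core_pool = NULL,
                            cassette = character(), n_carriers = NULL,
                            insertion_prob = 0,
                            cassette_location = c("adjacent", "distal"),
                            n_second_focal = 0L, n_distal_genes = 5L,
                            distal_arcogs = NULL,
                            gene_length = c(600L, 1500L),
                            intergenic = c(50L, 400L),
                            contig_length = 3e6, circular_fraction = 0.5,
                            flank_bp = 20000L, focal_arcog = "arCOG02202",
                            unassigned_rate = 0.05, seed = 1L) {
  cassette_location <- match.arg(cassette_location)
  if (is.null(core_pool)) {
    core_pool <- data.frame(arcog_id = character(), retention_prob = numeric())
  }
  core_pool <- as.data.frame(core_pool, stringsAsFactors = FALSE)
  stopifnot("arcog_id" %in% names(core_pool))
  nc <- nrow(core_pool)
  if (is.null(core_pool$retention_prob)) {
    core_pool$retention_prob <- rep(NA_real_, nc)
  }
  if (is.null(core_pool$n_present)) core_pool$n_present <- rep(NA_integer_, nc)
  if (is.null(core_pool$n_double)) core_pool$n_double <- rep(0L, nc)
  bad <- is.na(core_pool$retention_prob) & is.na(core_pool$n_present)
  if (any(bad)) {
    stop("core pool entries need retention_prob or n_present: ",
         paste(core_pool$arcog_id[bad], collapse = ", "))
  }
  p <- core_pool$retention_prob
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("retention probabilities must lie in [0, 1]")
  }
  if (insertion_prob < 0 || insertion_prob > 1) {
    stop("insertion_prob must lie in [0, 1]")
  }
  if (contig_length < 2 * (flank_bp + 2000) + gene_length[2]) {
    stop("contig too short to hold a neighbourhood window")
  }
  structure(list(n_species = as.integer(n_species), core_pool = core_pool,
                 cassette = as.character(cassette), n_carriers = n_carriers,
                 insertion_prob = insertion_prob,
                 cassette_location = cassette_location,
                 n_second_focal = as.integer(n_second_focal),
                 n_distal_genes = as.integer(n_distal_genes),
                 distal_arcogs = distal_arcogs,
                 gene_length = as.integer(gene_length),
                 intergenic = as.integer(intergenic),
                 contig_length = as.integer(contig_length),
                 circular_fraction = circular_fraction,
                 flank_bp = as.integer(flank_bp),
                 focal_arcog = focal_arcog,
                 unassigned_rate = unassigned_rate,
                 seed = as.integer(seed)),
            class = "genome_sim_spec")
}

runif_int <- function(n, range) {
  sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate annotated genomes with planted neighbourhood structure
#'
#' @param spec A [genome_sim_spec()].
#' @return List with `genomes` (named by species; each element holds
#'   `annotation` ([genome_annotation()]), `assignments` (arCOG table) and
#'   `focal_locus`) and `truth` (`core_arcogs`, logical `presence` matrix of
#'   species x core arCOG, `carriers`, `second_focal` species).
#' @export
simulate_genomes <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  withr::with_seed(spec$seed, {
    ns <- spec$n_species
    species <- sprintf("sp%03d", seq_len(ns))
    core <- spec$core_pool
    presence <- matrix(FALSE, ns, nrow(core),
                       dimnames = list(species, core$arcog_id))
    doubles <- matrix(FALSE, ns, nrow(core),
                      dimnames = list(species, core$arcog_id))
    for (k in seq_len(nrow(core))) {
      idx <- if (!is.na(core$n_present[k])) {
        sample.int(ns, core$n_present[k])
      } else {
        which(stats::runif(ns) < core$retention_prob[k])
      }
      presence[idx, k] <- TRUE
      if (core$n_double[k] > 0) {
        doubles[sample(idx, core$n_double[k]), k] <- TRUE
      }
    }
    carriers <- if (length(spec$cassette) == 0) integer(0) else
      if (!is.null(spec$n_carriers)) sample.int(ns, spec$n_carriers) else
        which(stats::runif(ns) < spec$insertion_prob)
    second_focal <- if (spec$n_second_focal > 0) {
      sample.int(ns, spec$n_second_focal)
    } else integer(0)
    circ <- stats::runif(ns) < spec$circular_fraction
    reserved <- unique(c(core$arcog_id, spec$cassette, spec$focal_arcog,
                         spec$distal_arcogs$arcog_id))
    filler_env <- new.env()
    filler_env$counter <- 0L
    genomes <- vector("list", ns)
    names(genomes) <- species
    for (s in seq_len(ns)) {
      genomes[[s]] <- simulate_one_genome(
        spec, species[s], circ[s],
        core_here = rep(core$arcog_id, times = presence[s, ] + doubles[s, ]),
        carrier = s %in% carriers,
        extra_focal = s %in% second_focal,
        reserved = reserved, filler_env = filler_env)
    }
    list(genomes = genomes,
         truth = list(core_arcogs = core$arcog_id,
                      presence = presence,
                      carriers = species[sort(carriers)],
                      second_focal = species[sort(second_focal)]))
  })
}

next_filler_id <- function(filler_env, reserved) {
  repeat {
    filler_env$counter <- filler_env$counter + 1L
    id <- sprintf("arCOG8%04d", filler_env$counter)
    if (!id %in% reserved) return(id)
  }
}

simulate_one_genome <- function(spec, sp, is_circular, core_here, carrier,
                                extra_focal, reserved, filler_env) {
  L <- spec$contig_length
  flank <- spec$flank_bp
  flen <- runif_int(1, spec$gene_length)
  if (is_circular) {
    fstart <- sample.int(L, 1)
    if (fstart + flen - 1 > L) fstart <- L - flen + 1
  } else {
    fstart <- sample(seq(flank + 2000, L - flank - 2000 - flen), 1)
  }
  fend <- fstart + flen - 1

  # gene slots outward from the focal gene, in raw coordinates
  down <- list()
  pos <- fend
  repeat {
    st <- pos + runif_int(1, spec$intergenic)
    if (st > fend + flank) break
    en <- st + runif_int(1, spec$gene_length) - 1
    down[[length(down) + 1L]] <- c(st, en)
    pos <- en
  }
  up <- list()
  pos <- fstart
  repeat {
    en <- pos - runif_int(1, spec$intergenic)
    if (en < fstart - flank) break
    st <- en - runif_int(1, spec$gene_length) + 1
    up[[length(up) + 1L]] <- c(st, en)
    pos <- st
  }
  wrap <- function(slots) {
    out <- list()
    for (sl in slots) {
      st <- sl[1]; en <- sl[2]
      if (is_circular) {
        st_m <- ((st - 1) %% L) + 1
        en_m <- ((en - 1) %% L) + 1
        if (en_m >= st_m) out[[length(out) + 1L]] <- c(st_m, en_m)
        # genes that would span the origin after wrapping are dropped
      } else if (st >= 1 && en <= L) {
        out[[length(out) + 1L]] <- c(st, en)
      }
    }
    out
  }
  down <- wrap(down)
  up <- wrap(up)
  n_slots <- length(down) + length(up)

  cass <- spec$cassette
  adjacent_cassette <- carrier && spec$cassette_location == "adjacent"
  if (adjacent_cassette && length(cass) > length(down)) {
    stop("region capacity exceeded: cassette of ", length(cass),
         " genes does not fit downstream of the focal gene in ", sp)
  }
  slot_ids <- c(sprintf("d%03d", seq_along(down)),
                sprintf("u%03d", seq_along(up)))
  slot_pos <- c(down, up)
  names(slot_pos) <- slot_ids
  assignment <- stats::setNames(rep(NA_character_, n_slots), slot_ids)
  free <- slot_ids
  if (adjacent_cassette) {
    cass_slots <- sprintf("d%03d", seq_along(cass))
    assignment[cass_slots] <- cass
    free <- setdiff(free, cass_slots)
  }
  n_extra <- length(core_here) + as.integer(extra_focal)
  if (n_extra > length(free)) {
    stop("region capacity exceeded: ", n_extra,
         " planted genes for ", length(free), " free slots in ", sp)
  }
  planted_slots <- if (n_extra) sample(free, n_extra) else character(0)
  assignment[planted_slots] <- c(core_here,
                                 if (extra_focal) spec$focal_arcog)
  free <- setdiff(free, planted_slots)
  for (f in free) {
    assignment[f] <- if (stats::runif(1) < spec$unassigned_rate)
      NA_character_ else next_filler_id(filler_env, reserved)
  }

  genes <- data.frame(
    start_bp = vapply(slot_pos, `[`, numeric(1), 1),
    end_bp = vapply(slot_pos, `[`, numeric(1), 2),
    arcog = unname(assignment),
    stringsAsFactors = FALSE)
  genes <- rbind(genes, data.frame(start_bp = fstart, end_bp = fend,
                                   arcog = spec$focal_arcog))
  focal_row <- nrow(genes)
  genes$is_focal <- seq_len(nrow(genes)) == focal_row

  # distal genes outside the window
  win <- window_intervals(fstart - flank, fend + flank, L, is_circular)
  place_distal <- function(arcog, offset = NULL) {
    for (try in 1:50) {
      len <- runif_int(1, spec$gene_length)
      st <- if (!is.null(offset)) fstart + offset else sample.int(L - len, 1)
      if (is_circular) st <- ((st - 1) %% L) + 1
      en <- st + len - 1
      if (en > L) next
      if (any(overlaps_any(st, en, win$intervals))) {
        if (!is.null(offset)) stop("distal offset falls inside the window")
        next
      }
      return(data.frame(start_bp = st, end_bp = en, arcog = arcog,
                        is_focal = FALSE, stringsAsFactors = FALSE))
    }
    stop("could not place a distal gene outside the window in ", sp)
  }
  if (spec$n_distal_genes > 0) {
    for (i in seq_len(spec$n_distal_genes)) {
      genes <- rbind(genes,
                     place_distal(next_filler_id(filler_env, reserved)))
    }
  }
  if (carrier && spec$cassette_location == "distal") {
    base <- fend + 5L * flank
    pos <- base
    for (a in cass) {
      len <- runif_int(1, spec$gene_length)
      st <- if (is_circular) ((pos - 1) %% L) + 1 else pos
      en <- st + len - 1
      if (en > L) stop("distal cassette does not fit on the contig in ", sp)
      genes <- rbind(genes, data.frame(start_bp = st, end_bp = en, arcog = a,
                                       is_focal = FALSE))
      pos <- pos + len + runif_int(1, spec$intergenic)
    }
  }
  if (!is.null(spec$distal_arcogs)) {
    for (i in seq_len(nrow(spec$distal_arcogs))) {
      genes <- rbind(genes, place_distal(spec$distal_arcogs$arcog_id[i],
                                         spec$distal_arcogs$offset_bp[i]))
    }
  }

  genes <- genes[order(genes$start_bp, genes$end_bp), , drop = FALSE]
  genes$locus_id <- sprintf("%s_g%03d", sp, seq_len(nrow(genes)))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  contig <- paste0(sp, "_c1")
  annotation <- genome_annotation(
    contigs = data.frame(contig_id = contig, length_bp = L,
                         is_circular = is_circular),
    features = data.frame(contig_id = contig, start_bp = genes$start_bp,
                          end_bp = genes$end_bp, strand = genes$strand,
                          locus_id = genes$locus_id,
                          product = ifelse(genes$is_focal,
                                           "tubulin superfamily protein", ""),
                          stringsAsFactors = FALSE),
    species = sp)
  assignments <- data.frame(
    locus_id = genes$locus_id,
    arcog_id = genes$arcog,
    cog_category = "",
    annotation = ifelse(genes$is_focal, "tubulin-like cytoskeletal protein",
                        ""),
    stringsAsFactors = FALSE)
  assignments$unassigned <- is.na(assignments$arcog_id)
  list(annotation = annotation, assignments = assignments,
       focal_locus = genes$locus_id[genes$is_focal])
}
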